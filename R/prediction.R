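#' Dysglycemia label from fasting and 2-h plasma glucose
#'
#' Composite definition: fasting plasma glucose strictly above
#' \code{fpg_gt} (default 100 mg/dL) or 2-h plasma glucose strictly above
#' \code{pg2h_gt} (default 140 mg/dL). Values exactly at a threshold are
#' not dysglycemic. Vectorised; a missing value in either input yields NA
#' (callers exclude and log such records).
#'
#' @param fpg fasting plasma glucose, mg/dL.
#' @param pg2h 2-h plasma glucose, mg/dL.
#' @param fpg_gt,pg2h_gt thresholds, mg/dL.
#' @return logical vector.
#' @examples
#' label_dysglycemia(c(95, 100, 101, 95), c(120, 140, 120, 141))
#' # FALSE FALSE TRUE TRUE
#' @export
label_dysglycemia <- function(fpg, pg2h, fpg_gt = 100, pg2h_gt = 140) {
  fpg > fpg_gt | pg2h > pg2h_gt
}

#' Paired baseline vs follow-up change tests
#'
#' Wilcoxon signed-rank tests for paired continuous variables (FPG, 2hrPG,
#' HbA1c, BMI percentile) and McNemar's test for the change in dysglycemia
#' rate. Degenerate cases are handled explicitly: identical baseline and
#' follow-up values give statistic 0 and p = 1; the McNemar p-value is the
#' exact binomial test on discordant pairs when fewer than 25 are
#' discordant (so 10-vs-10 discordance gives p = 1 exactly) and the
#' chi-square form without continuity correction otherwise.
#'
#' @param baseline data.frame of baseline values.
#' @param followup data.frame with the same column names.
#' @param dysglycemia optional 2-column logical data.frame/matrix
#'   (baseline, follow-up) tested with McNemar.
#' @return data.frame: variable, test, n, statistic, p.
#' @export
paired_change_tests <- function(baseline, followup, dysglycemia = NULL) {
  stopifnot(identical(names(baseline), names(followup)))
  res <- lapply(names(baseline), function(v) {
    b <- baseline[[v]]; f <- followup[[v]]
    ok <- is.finite(b) & is.finite(f)
    if (!any(ok)) stop(sprintf("no complete pairs for %s", v))
    d <- f[ok] - b[ok]
    if (all(d == 0)) {
      stat <- 0; p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(f[ok], b[ok], paired = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(variable = v, test = "wilcoxon-signed-rank", n = sum(ok),
               statistic = stat, p = p, stringsAsFactors = FALSE)
  })
  if (!is.null(dysglycemia)) {
    db <- dysglycemia[[1]]; df <- dysglycemia[[2]]
    ok <- !is.na(db) & !is.na(df)
    res[[length(res) + 1L]] <- data.frame(
      variable = "dysglycemia", test = "mcnemar", n = sum(ok),
      statistic = NA_real_, p = mcnemar_p(db[ok], df[ok]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# exact binomial form for < 25 discordant pairs, chi-square (no continuity
# correction) otherwise
mcnemar_p <- function(before, after) {
  b <- sum(before & !after)
  c_ <- sum(!before & after)
  if (b + c_ == 0L) return(1)
  if (b + c_ < 25L) {
    stats::binom.test(b, b + c_, 0.5)$p.value
  } else {
    stats::pchisq((b - c_)^2 / (b + c_), df = 1, lower.tail = FALSE)
  }
}

#' ROC curve and AUC by the Mann-Whitney concordance
#'
#' AUC is the Mann-Whitney U statistic scaled by n_pos x n_neg, counting
#' tied score pairs 1/2 — computed through average ranks, so identical
#' scores give exactly 0.5. The ROC staircase is produced by sweeping the
#' unique score thresholds from high to low.
#'
#' @param scores numeric risk scores or probabilities (higher = riskier).
#' @param labels logical (or 0/1) outcome labels; both classes must be
#'   present.
#' @return list of class \code{ogtt_roc}: \code{auc}, \code{roc}
#'   (data.frame threshold, fpr, tpr), \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both outcome classes must be present")
  r <- rank(scores)   # average ranks handle ties as 1/2
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  structure(list(auc = auc,
                 roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 n_pos = n_pos, n_neg = n_neg),
            class = "ogtt_roc")
}

#' @export
print.ogtt_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d events / %d non-events)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Seven-predictor logistic comparison for future dysglycemia
#'
#' Fits one unpenalized maximum-likelihood logistic regression per
#' predictor set — FPG; 2hrPG; HbA1c; shape classification (biphasic and
#' monotonically-increasing dummies against a monophasic reference);
#' glucose FPCs; insulin FPCs; glucose + insulin FPCs — with dysglycemia at
#' follow-up as the outcome, and compares them by in-sample ROC/AUC (no
#' train/test split; the design targets small event counts). Complete
#' separation is detected from the fitted probabilities and flagged; the
#' AUC of the separating score is still valid and reported.
#'
#' Single-variable sets are ranked by the raw marker in its conventional
#' risk direction (higher value = riskier), making their AUC the raw
#' variable's AUC — identical to the fitted-probability AUC whenever the
#' maximum-likelihood slope is positive, and immune to the optimistic
#' sign-fitting fold that in-sample fits exhibit at very small event
#' counts. Multi-variable sets are ranked by the fitted probability.
#'
#' @param data data.frame for the longitudinal subset with columns
#'   \code{fpg}, \code{pg2h}, \code{hba1c}, \code{shape} (factor; rows with
#'   inconclusive shape are dropped for the shape model only),
#'   \code{g_z1_std..g_z3_std}, \code{i_z1_std..i_z3_std} and logical
#'   \code{outcome}.
#' @return list of class \code{ogtt_prediction}: per-set fits (name,
#'   coefficients, probabilities, roc, auc, n, events, separation flag) and
#'   a \code{summary} data.frame.
#' @export
fit_predictor_models <- function(data) {
  stopifnot(is.data.frame(data), "outcome" %in% names(data))
  if (sum(data$outcome, na.rm = TRUE) < 1L) stop("no events in the longitudinal subset")
  sets <- list(
    FPG = "fpg",
    `2hrPG` = "pg2h",
    HbA1c = "hba1c",
    shape = c("shape_biphasic", "shape_monotonic"),
    `glucose FPCs` = paste0("g_z", 1:3, "_std"),
    `insulin FPCs` = paste0("i_z", 1:3, "_std"),
    `glucose+insulin FPCs` = c(paste0("g_z", 1:3, "_std"), paste0("i_z", 1:3, "_std")))

  d <- data
  d$shape_biphasic <- as.integer(d$shape == "biphasic")
  d$shape_monotonic <- as.integer(d$shape == "monotonically_increasing")
  d$shape_biphasic[d$shape == "inconclusive"] <- NA_integer_
  d$shape_monotonic[d$shape == "inconclusive"] <- NA_integer_

  fits <- lapply(names(sets), function(nm) {
    vars <- sets[[nm]]
    dd <- d[stats::complete.cases(d[c("outcome", vars)]), c("outcome", vars)]
    # drop constant predictors (e.g. no monotonic shapes sampled) rather
    # than fitting an aliased column
    keep <- vars[vapply(dd[vars], function(v) stats::sd(v) > 0, logical(1))]
    fml <- stats::as.formula(paste(
      "outcome ~", if (length(keep)) paste(keep, collapse = " + ") else "1"))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, family = stats::binomial(), data = dd),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    prob <- stats::fitted(fit)
    # single-variable sets are ranked by the raw marker in its conventional
    # risk direction (higher value = riskier), so their AUC equals the raw
    # variable's AUC under the monotone link; multi-variable sets are ranked
    # by the fitted probability
    score <- if (length(keep) == 1L) dd[[keep]] else prob
    roc <- roc_auc(score, dd$outcome)
    list(name = nm, variables = keep, coefficients = stats::coef(fit),
         probabilities = prob, roc = roc, auc = roc$auc, n = nrow(dd),
         events = sum(dd$outcome), separation = sep)
  })
  names(fits) <- names(sets)
  summary <- data.frame(
    predictor = names(sets),
    auc = vapply(fits, `[[`, numeric(1), "auc"),
    n = vapply(fits, `[[`, integer(1), "n"),
    events = vapply(fits, function(f) as.integer(f$events), integer(1)),
    separation = vapply(fits, `[[`, logical(1), "separation"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fits = fits, summary = summary), class = "ogtt_prediction")
}

#' @export
print.ogtt_prediction <- function(x, ...) {
  cat("Dysglycemia prediction, seven predictor sets (in-sample AUC):\n")
  s <- x$summary[order(-x$summary$auc), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-22s AUC = %.3f  (n = %d, events = %d)%s\n",
                s$predictor[i], s$auc[i], s$n[i], s$events[i],
                if (s$separation[i]) "  [separation]" else ""))
  }
  invisible(x)
}
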