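#' Spearman correlation matrix with Bonferroni control
#'
#' Rank correlations between curve-shape features (shape indicator columns
#' and standardized FPC scores) and measured targets (timed glucose and
#' insulin values, metabolic labs), each pair on its complete cases.
#' P-values come from the exact null distribution when n <= 10 and the
#' data are tie-free, and from the t approximation otherwise. A pair is
#' flagged significant when p < alpha / n_comparisons; pairs with a
#' constant column or fewer than 3 complete cases are returned with
#' \code{undefined = TRUE} and no flag.
#'
#' @param features data.frame of feature columns (numeric).
#' @param targets data.frame of target columns (numeric), same rows.
#' @param alpha nominal significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 171, the planned
#'   feature-by-target inventory: 9 features x 19 targets).
#' @return tidy data.frame: feature, target, n, rho, p, significant,
#'   undefined.
#' @export
spearman_matrix <- function(features, targets, alpha = 0.05, n_comparisons = 171L) {
  stopifnot(nrow(features) == nrow(targets))
  res <- vector("list", ncol(features) * ncol(targets))
  k <- 0L
  for (f in names(features)) {
    for (tg in names(targets)) {
      k <- k + 1L
      x <- features[[f]]; y <- targets[[tg]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      row <- data.frame(feature = f, target = tg, n = n, rho = NA_real_,
                        p = NA_real_, significant = FALSE, undefined = TRUE,
                        stringsAsFactors = FALSE)
      if (n >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        has_ties <- anyDuplicated(x[ok]) > 0 || anyDuplicated(y[ok]) > 0
        ct <- suppressWarnings(stats::cor.test(
          x[ok], y[ok], method = "spearman",
          exact = n <= 10L && !has_ties))
        row$rho <- unname(ct$estimate)
        row$p <- ct$p.value
        row$significant <- is.finite(ct$p.value) && ct$p.value < alpha / n_comparisons
        row$undefined <- FALSE
      }
      res[[k]] <- row
    }
  }
  do.call(rbind, res)
}

#' Differences in demographics and labs across shape classes
#'
#' Kruskal-Wallis tests for continuous variables and Fisher's exact test
#' for categorical ones, across the glucose shape classes.
#'
#' @param variables data.frame of variables to test.
#' @param groups factor of group labels (e.g. shape classes), same length.
#' @return data.frame: variable, test, statistic, p, n.
#' @export
group_difference_tests <- function(variables, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  res <- lapply(names(variables), function(v) {
    x <- variables[[v]]
    ok <- !is.na(x) & !is.na(groups)
    if (is.numeric(x)) {
      kt <- stats::kruskal.test(x[ok], droplevels(groups[ok]))
      data.frame(variable = v, test = "kruskal-wallis",
                 statistic = unname(kt$statistic), p = kt$p.value,
                 n = sum(ok), stringsAsFactors = FALSE)
    } else {
      tab <- table(droplevels(factor(x[ok])), droplevels(groups[ok]))
      if (nrow(tab) < 2L || ncol(tab) < 2L) {
        # constant variable (or single represented group): no contrast to test
        data.frame(variable = v, test = "fisher-exact (degenerate)",
                   statistic = NA_real_, p = NA_real_, n = sum(ok),
                   stringsAsFactors = FALSE)
      } else {
        ft <- tryCatch(stats::fisher.test(tab),
                       error = function(e) stats::fisher.test(tab, simulate.p.value = TRUE,
                                                              B = 1e4))
        data.frame(variable = v, test = "fisher-exact", statistic = NA_real_,
                   p = ft$p.value, n = sum(ok), stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, res)
}

#' Demographic-adjusted linear models of FPC scores on metabolic exposures
#'
#' For each (score, exposure) pair, fits the ordinary least-squares model
#' \code{score ~ exposure + age + sex + race + ethnicity} on the pair's
#' complete cases and reports the exposure coefficient. A rank-deficient
#' design (an aliased exposure or covariate) is an error naming the
#' offending columns.
#'
#' @param scores data.frame of standardized FPC score columns.
#' @param exposures data.frame of metabolic exposure columns.
#' @param covariates data.frame with columns age, sex, race, ethnicity.
#' @param drop_single_level drop factor covariates with fewer than two
#'   observed levels instead of erroring (used by the pipeline on small
#'   cohorts where e.g. a single ethnicity may be represented).
#' @return data.frame: score, exposure, estimate, se, p, n.
#' @export
adjusted_fpc_models <- function(scores, exposures, covariates,
                                drop_single_level = FALSE) {
  need <- c("age", "sex", "race", "ethnicity")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop(sprintf("missing covariate(s): %s", paste(miss, collapse = ", ")))
  res <- list()
  for (sc in names(scores)) {
    for (ex in names(exposures)) {
      d <- data.frame(y = scores[[sc]], x = exposures[[ex]],
                      covariates[need], stringsAsFactors = TRUE)
      d <- d[stats::complete.cases(d), , drop = FALSE]
      d <- droplevels(d)
      covs <- need
      if (drop_single_level) {
        covs <- need[vapply(d[need], function(v) length(unique(v)) > 1L, logical(1))]
      }
      fml <- stats::as.formula(paste(c("y ~ x", covs), collapse = " + "))
      fit <- tryCatch(
        stats::lm(fml, data = d),
        error = function(e) stop(sprintf(
          "rank-deficient design for %s ~ %s: single-level factor covariate (%s)",
          sc, ex, conditionMessage(e)), call. = FALSE))
      if (anyNA(stats::coef(fit))) {
        stop(sprintf("rank-deficient design for %s ~ %s: aliased term(s) %s",
                     sc, ex,
                     paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                           collapse = ", ")))
      }
      sm <- summary(fit)$coefficients
      res[[length(res) + 1L]] <- data.frame(
        score = sc, exposure = ex, estimate = sm["x", 1], se = sm["x", 2],
        p = sm["x", 4], n = nrow(d), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
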