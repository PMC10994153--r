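#' Classify a five-point OGTT glucose profile by curve shape
#'
#' Applies the standard rule set for glucose response morphology on the raw
#' measurements at 0/30/60/90/120 min, with decision threshold \code{delta}
#' (default 4.5 mg/dL). Rules are applied in a fixed order that makes the
#' classes mutually exclusive and exhaustive:
#' \enumerate{
#'   \item \emph{inconclusive} — no rise above the fasting (0-min) value at
#'     30 or 60 min;
#'   \item \emph{monotonically_increasing} — no point falls more than
#'     \code{delta} below the running maximum (strict ">" reading of
#'     "a drop of more than 4.5 mg/dL");
#'   \item \emph{biphasic} — after an initial peak, a drop of at least
#'     \code{delta}, followed by a later rise of at least \code{delta} from
#'     the post-drop minimum;
#'   \item \emph{monophasic} — a drop of at least \code{delta} after the
#'     maximum with no subsequent rise of at least \code{delta}.
#' }
#' Plateaus (equal consecutive values) count as neither rise nor drop.
#'
#' @param glucose numeric vector of 5 finite glucose values (mg/dL).
#' @param delta decision threshold in mg/dL.
#' @return An object of class \code{ogtt_shape}: list with \code{label}
#'   (factor level) and \code{evidence} (peak index, drop and re-rise
#'   magnitudes used in the decision).
#' @examples
#' classify_shape(c(85, 130, 110, 125, 120))$label   # biphasic
#' classify_shape(c(83, 120, 140, 130, 125))$label   # monophasic
#' @export
classify_shape <- function(glucose, delta = 4.5) {
  g <- as.numeric(glucose)
  if (length(g) != 5L || any(!is.finite(g))) {
    stop("`glucose` must be 5 finite values")
  }
  lv <- shape_levels()
  out <- function(label, peak = NA_integer_, drop = NA_real_, rerise = NA_real_) {
    structure(list(label = factor(label, levels = lv),
                   evidence = list(peak_index = peak, drop = drop, rerise = rerise)),
              class = "ogtt_shape")
  }
  # (a) no rise above fasting by 60 min
  if (g[2] <= g[1] && g[3] <= g[1]) return(out("inconclusive"))
  runmax <- cummax(g)
  drops <- runmax - g
  # (b) never falls more than delta below the running maximum
  if (max(drops) <= delta) {
    return(out("monotonically_increasing", peak = which.max(g),
               drop = max(drops), rerise = 0))
  }
  # (c) initial peak, drop >= delta, re-rise >= delta from post-drop minimum
  for (m in 2:4) {
    p <- which.max(g[seq_len(m)])
    if (p < m && g[p] - g[m] >= delta) {
      for (q in (m + 1):5) {
        if (g[q] - g[m] >= delta) {
          return(out("biphasic", peak = p, drop = g[p] - g[m],
                     rerise = g[q] - g[m]))
        }
      }
    }
  }
  # (d) drop >= delta after the maximum, no qualifying re-rise
  p <- which.max(g)
  post <- g[p:5]
  trough <- which.min(post) + p - 1L
  rerise <- if (trough < 5L) max(g[(trough + 1L):5]) - g[trough] else 0
  out("monophasic", peak = p, drop = g[p] - min(post), rerise = max(rerise, 0))
}

shape_levels <- function() {
  c("biphasic", "monophasic", "monotonically_increasing", "inconclusive")
}

#' @export
print.ogtt_shape <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf("OGTT shape: %s (peak at point %s, drop %.1f, re-rise %.1f)\n",
              as.character(x$label), ev$peak_index, ev$drop, ev$rerise))
  invisible(x)
}

#' Classify every glucose profile in a matrix
#'
#' @param G numeric matrix of glucose series, participants in rows, the 5
#'   time points in columns.
#' @param delta decision threshold in mg/dL.
#' @return factor of shape labels, one per row, with an \code{"evidence"}
#'   attribute holding the per-row peak/drop/re-rise data.frame.
#' @export
classify_shapes <- function(G, delta = 4.5) {
  G <- as.matrix(G)
  res <- apply(G, 1L, classify_shape, delta = delta, simplify = FALSE)
  labels <- factor(vapply(res, function(r) as.character(r$label), character(1)),
                   levels = shape_levels())
  ev <- data.frame(
    peak_index = vapply(res, function(r) as.integer(r$evidence$peak_index), integer(1)),
    drop = vapply(res, function(r) as.numeric(r$evidence$drop), numeric(1)),
    rerise = vapply(res, function(r) as.numeric(r$evidence$rerise), numeric(1)))
  attr(labels, "evidence") <- ev
  labels
}

#' Dichotomous indicator coding of shape classes
#'
#' Expands classified shapes into three 0/1 columns (biphasic, monophasic,
#' monotonically_increasing) for use as association features. Profiles with
#' an inconclusive shape carry no class and are dropped; the number dropped
#' is reported via a message and the \code{"n_excluded"} attribute.
#'
#' @param labels factor or character vector of shape labels.
#' @return data.frame of three indicator columns, rows summing to 1, with
#'   attribute \code{n_excluded} and row names preserved from \code{labels}
#'   names where present.
#' @export
shape_dummies <- function(labels) {
  labels <- factor(as.character(labels), levels = shape_levels())
  if (anyNA(labels)) stop("unknown shape label(s)")
  keep <- labels != "inconclusive"
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message(sprintf("shape_dummies: excluded %d participant(s) with inconclusive shape", n_excl))
  }
  out <- data.frame(
    biphasic = as.integer(labels[keep] == "biphasic"),
    monophasic = as.integer(labels[keep] == "monophasic"),
    monotonically_increasing = as.integer(labels[keep] == "monotonically_increasing"))
  if (!is.null(names(labels))) rownames(out) <- names(labels)[keep]
  attr(out, "n_excluded") <- n_excl
  out
}
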