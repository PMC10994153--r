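#' Pipeline configuration
#'
#' Collects every tunable of the OGTT analysis pipeline in one validated
#' object: basis size, number of FPCs, the smoothing-parameter search grid,
#' quadrature resolution, the Bonferroni correction (nominal alpha over 171
#' planned comparisons), the dysglycemia thresholds (fasting glucose > 100
#' mg/dL or 2-h glucose > 140 mg/dL) and the 4.5 mg/dL shape-rule
#' threshold.
#'
#' @param n_basis number of B-spline basis functions (default 7).
#' @param n_fpc number of principal components retained (default 3).
#' @param lambda_grid positive candidate smoothing parameters; default 25
#'   log-spaced values on 1e-4..1e4.
#' @param quadrature_step quadrature grid step in minutes.
#' @param seed integer seed used by synthetic generation inside
#'   [run_pipeline()].
#' @param bonferroni_alpha nominal significance level.
#' @param n_comparisons number of planned comparisons for the Bonferroni
#'   correction.
#' @param fpg_gt,pg2h_gt dysglycemia thresholds in mg/dL (strict ">").
#' @param shape_delta shape-rule threshold in mg/dL.
#' @return list of class \code{ogtt_config}.
#' @export
ogtt_config <- function(n_basis = 7L, n_fpc = 3L,
                        lambda_grid = 10^seq(-4, 4, length.out = 25),
                        quadrature_step = 1, seed = 1L,
                        bonferroni_alpha = 0.05, n_comparisons = 171L,
                        fpg_gt = 100, pg2h_gt = 140, shape_delta = 4.5) {
  if (n_fpc < 1L) stop("`n_fpc` must be >= 1")
  if (n_basis < n_fpc + 1L) stop("`n_basis` must be >= n_fpc + 1")
  if (length(lambda_grid) == 0L || any(lambda_grid <= 0)) {
    stop("`lambda_grid` must be non-empty and positive")
  }
  if (fpg_gt <= 0 || pg2h_gt <= 0 || shape_delta <= 0) {
    stop("thresholds must be positive")
  }
  if (bonferroni_alpha <= 0 || bonferroni_alpha >= 1) {
    stop("`bonferroni_alpha` must be in (0, 1)")
  }
  structure(
    list(n_basis = as.integer(n_basis), n_fpc = as.integer(n_fpc),
         lambda_grid = as.numeric(lambda_grid),
         quadrature_step = quadrature_step, seed = as.integer(seed),
         bonferroni_alpha = bonferroni_alpha,
         n_comparisons = as.integer(n_comparisons),
         fpg_gt = fpg_gt, pg2h_gt = pg2h_gt, shape_delta = shape_delta),
    class = "ogtt_config")
}

#' @export
print.ogtt_config <- function(x, ...) {
  cat(sprintf(paste0(
    "OGTT pipeline config: %d basis functions, %d FPCs, %d-point lambda grid,\n",
    "  Bonferroni %.3g/%d, dysglycemia FPG > %g or 2hrPG > %g mg/dL, shape delta %g\n"),
    x$n_basis, x$n_fpc, length(x$lambda_grid), x$bonferroni_alpha,
    x$n_comparisons, x$fpg_gt, x$pg2h_gt, x$shape_delta))
  invisible(x)
}

# rolling polynomial hash over a character representation, for run manifests
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(unclass(x)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
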