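#' Functional principal component analysis of smoothed OGTT curves
#'
#' Decomposes the variation of a cohort of smoothed curves (one analyte)
#' into orthonormal eigenfunctions \eqn{\xi_k} of the sample covariance
#' operator. Working in the B-spline coefficient space: with Gram matrix
#' \eqn{J_{kl} = \int \phi_k \phi_l} and coefficient covariance \eqn{S},
#' eigenfunctions are \eqn{\xi = \Phi J^{-1/2} u} for eigenvectors \eqn{u}
#' of \eqn{J^{1/2} S J^{1/2}}, which enforces \eqn{\int \xi_k^2 = 1} and
#' \eqn{\int \xi_j \xi_k = 0} for \eqn{j \ne k}. Eigenvalues equal the
#' variances of the component scores, and variance-explained fractions are
#' taken over the full operator spectrum.
#'
#' Curves are mean-centred before decomposition; centring only shifts raw
#' scores by a constant, which standardisation removes. The sign of each
#' eigenfunction is fixed so that \eqn{\int \xi_k \ge 0} (falling back to
#' \eqn{\xi_k(0) > 0} when the integral vanishes), making results
#' reproducible across platforms.
#'
#' @param curves an \code{ogtt_curveset} from [fit_curves()].
#' @param n_components number of leading components to retain (default 3).
#' @return An object of class \code{ogtt_fpca}: analyte, mean-function
#'   coefficients, eigenfunction coefficients (basis x component), the full
#'   eigenvalue vector, \code{variance_explained} for the retained
#'   components, and the shared basis.
#' @export
fit_fpca <- function(curves, n_components = 3L) {
  stopifnot(inherits(curves, "ogtt_curveset"))
  C <- curves$coefficients
  n <- nrow(C)
  if (n < n_components + 1L) {
    stop(sprintf("need at least %d curves to extract %d components",
                 n_components + 1L, n_components))
  }
  basis <- curves$basis
  mean_coef <- colMeans(C)
  Cc <- sweep(C, 2L, mean_coef)
  S <- crossprod(Cc) / (n - 1)
  if (sum(diag(basis$J %*% S)) < 1e-12) {
    stop("degenerate input: all curves are identical (zero covariance operator)")
  }
  eJ <- eigen(basis$J, symmetric = TRUE)
  if (min(eJ$values) <= 0) stop("Gram matrix is not positive definite")
  Jh <- eJ$vectors %*% (sqrt(eJ$values) * t(eJ$vectors))
  Jih <- eJ$vectors %*% ((1 / sqrt(eJ$values)) * t(eJ$vectors))
  A <- Jh %*% S %*% Jh
  eA <- eigen((A + t(A)) / 2, symmetric = TRUE)
  values <- pmax(eA$values, 0)
  B <- Jih %*% eA$vectors[, seq_len(n_components), drop = FALSE]
  # deterministic sign: integral of each eigenfunction >= 0
  phi0 <- splines::splineDesign(basis$knots, basis$times[1], ord = basis$order)
  for (k in seq_len(n_components)) {
    s <- sum(basis$weights * drop(basis$Phi_grid %*% B[, k]))
    if (abs(s) < 1e-9) s <- drop(phi0 %*% B[, k])
    if (s < 0) B[, k] <- -B[, k]
  }
  structure(
    list(analyte = curves$analyte, mean_coef = mean_coef,
         ef_coef = B, eigenvalues = values,
         variance_explained = values[seq_len(n_components)] / sum(values),
         n_components = n_components, n = n, basis = basis),
    class = "ogtt_fpca")
}

#' @export
print.ogtt_fpca <- function(x, ...) {
  cat(sprintf("FPCA of %d %s curves: first %d components explain %s%% (%s)\n",
              x$n, x$analyte, x$n_components,
              format(100 * sum(x$variance_explained), digits = 4),
              paste(format(100 * x$variance_explained, digits = 3),
                    collapse = " / ")))
  invisible(x)
}

#' Compute raw FPC scores for curves under a fitted model
#'
#' The k-th raw score of a curve is the inner product of its mean-centred
#' version with the k-th eigenfunction,
#' \eqn{z_k = \int \xi_k(t)\,(x_i(t) - \bar x(t))\,dt}, evaluated through
#' the basis Gram matrix (identical to trapezoid quadrature on the model's
#' grid, since both curve and eigenfunction live in the basis span).
#'
#' @param model an \code{ogtt_fpca}.
#' @param curves an \code{ogtt_curveset} (or single \code{ogtt_curve}) of
#'   the same analyte and basis.
#' @return matrix of raw scores, one row per curve, columns z1..zK, with
#'   participant ids as row names where available.
#' @export
fpc_scores <- function(model, curves) {
  stopifnot(inherits(model, "ogtt_fpca"))
  if (inherits(curves, "ogtt_curve")) {
    C <- matrix(curves$coefficients, nrow = 1L)
    ids <- NULL
    analyte <- curves$analyte
  } else {
    stopifnot(inherits(curves, "ogtt_curveset"))
    C <- curves$coefficients
    ids <- curves$ids
    analyte <- curves$analyte
  }
  if (!is.na(model$analyte) && !is.na(analyte) && !identical(model$analyte, analyte)) {
    stop(sprintf("analyte mismatch: model is %s, curves are %s", model$analyte, analyte))
  }
  if (ncol(C) != length(model$mean_coef)) stop("basis dimension mismatch")
  Z <- sweep(C, 2L, model$mean_coef) %*% model$basis$J %*% model$ef_coef
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  rownames(Z) <- ids
  Z
}

#' Standardize cohort FPC scores to mean 0, SD 1
#'
#' Each component is centred and scaled by the sample standard deviation
#' (denominator n - 1), the form used when scores enter association and
#' prediction models as unitless covariates.
#'
#' @param scores matrix of raw scores from [fpc_scores()].
#' @return matrix of the same shape with columns z1_std..zK_std.
#' @export
standardize_scores <- function(scores) {
  Z <- as.matrix(scores)
  if (nrow(Z) < 2L) stop("standardization needs at least 2 participants")
  sds <- apply(Z, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance component(s): %s",
                 paste(colnames(Z)[sds == 0], collapse = ", ")))
  }
  Zs <- scale(Z, center = TRUE, scale = sds)
  dimnames(Zs) <- list(rownames(Z), paste0(colnames(Z), "_std"))
  attr(Zs, "scaled:center") <- NULL
  attr(Zs, "scaled:scale") <- NULL
  Zs
}

#' Mean fitted curves by FPC-score quantile group
#'
#' Reporting utility: participants are binned by quartile (or top/bottom
#' decile) of each component's score, and the mean fitted curve of each bin
#' is evaluated on the model grid. Ties at a bin boundary go to the lower
#' bin.
#'
#' @param model an \code{ogtt_fpca}.
#' @param scores score matrix from [fpc_scores()] for the same curves.
#' @param curves the \code{ogtt_curveset} the scores were computed from.
#' @param type "quartile" for 4 bins, "decile" for the bottom and top 10\%
#'   only.
#' @return long data.frame with columns component, bin, time, value.
#' @export
quartile_curves <- function(model, scores, curves, type = c("quartile", "decile")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "ogtt_fpca"), inherits(curves, "ogtt_curveset"))
  Z <- as.matrix(scores)
  if (nrow(Z) < 4L) stop("need at least 4 participants")
  X <- curves$coefficients %*% t(model$basis$Phi_grid)   # n x grid
  out <- vector("list", ncol(Z))
  for (k in seq_len(ncol(Z))) {
    z <- Z[, k]
    if (type == "quartile") {
      qs <- stats::quantile(z, c(.25, .5, .75), names = FALSE)
      bin <- 1L + (z > qs[1]) + (z > qs[2]) + (z > qs[3])
      labs <- paste0("Q", 1:4)
    } else {
      qs <- stats::quantile(z, c(.10, .90), names = FALSE)
      bin <- ifelse(z <= qs[1], 1L, ifelse(z > qs[2], 2L, NA_integer_))
      labs <- c("bottom 10%", "top 10%")
    }
    keep <- !is.na(bin)
    means <- rowsum(X[keep, , drop = FALSE], bin[keep]) /
      as.vector(table(bin[keep]))
    out[[k]] <- data.frame(
      component = colnames(Z)[k],
      bin = rep(labs[as.integer(rownames(means))], each = ncol(X)),
      time = rep(model$basis$grid, times = nrow(means)),
      value = as.vector(t(means)))
  }
  do.call(rbind, out)
}
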