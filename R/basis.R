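#' Cubic B-spline basis with curvature penalty for OGTT curves
#'
#' Builds the basis system used to represent a participant's glucose or
#' insulin response as a smooth function of time. With the five standard
#' OGTT sampling times (0, 30, 60, 90, 120 min) as knots, a cubic (order-4)
#' B-spline basis has 3 interior knots + 4 = 7 basis functions. The
#' roughness penalty matrix contains the integrated products of the basis
#' functions' second derivatives, computed by composite-trapezoid quadrature
#' on a fine time grid, so that \eqn{c^T R c} measures the curvature of the
#' fitted curve with coefficients \eqn{c}.
#'
#' @param times numeric vector of strictly increasing measurement times in
#'   minutes; the default is the standard OGTT schedule.
#' @param n_basis number of basis functions; must equal
#'   \code{length(times) - 2 + order}.
#' @param order B-spline order (4 = cubic).
#' @param quadrature_step grid step in minutes for the quadrature used for
#'   the penalty, Gram and evaluation grids.
#' @return An object of class \code{ogtt_basis}: a list with the design
#'   matrix \code{Phi} (times x basis), penalty matrix \code{R}, Gram matrix
#'   \code{J} of integrated basis products, the quadrature \code{grid},
#'   trapezoid \code{weights}, and \code{Phi_grid}, the basis evaluated on
#'   the grid.
#' @examples
#' b <- build_basis()
#' rowSums(b$Phi)            # partition of unity: all 1
#' @export
build_basis <- function(times = c(0, 30, 60, 90, 120), n_basis = 7L,
                        order = 4L, quadrature_step = 1) {
  if (length(times) < 3L || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with at least 3 points")
  }
  if (n_basis != length(times) - 2L + order) {
    stop(sprintf(
      "inconsistent basis: %d knots with order %d give %d basis functions, not %d",
      length(times), order, length(times) - 2L + order, n_basis))
  }
  if (quadrature_step <= 0 ||
      abs((diff(range(times)) / quadrature_step) %% 1) > 1e-8) {
    stop("`quadrature_step` must divide the time range exactly")
  }
  rng <- range(times)
  knots <- c(rep(rng[1], order), times[-c(1L, length(times))], rep(rng[2], order))
  grid <- seq(rng[1], rng[2], by = quadrature_step)
  w <- trapezoid_weights(grid)

  Phi <- splines::splineDesign(knots, times, ord = order)
  Phi_grid <- splines::splineDesign(knots, grid, ord = order)
  D2 <- splines::splineDesign(knots, grid, ord = order, derivs = 2L)
  R <- crossprod(D2, w * D2)
  R <- (R + t(R)) / 2
  J <- crossprod(Phi_grid, w * Phi_grid)
  J <- (J + t(J)) / 2

  structure(
    list(times = times, order = order, knots = knots, n_basis = n_basis,
         Phi = Phi, R = R, J = J, grid = grid, weights = w,
         Phi_grid = Phi_grid),
    class = "ogtt_basis")
}

#' @export
print.ogtt_basis <- function(x, ...) {
  cat(sprintf("OGTT B-spline basis: order %d, %d functions, knots at %s min\n",
              x$order, x$n_basis, paste(x$times, collapse = ", ")))
  invisible(x)
}

# composite trapezoid weights on a uniform grid
trapezoid_weights <- function(grid) {
  h <- diff(grid)
  w <- numeric(length(grid))
  w[-length(w)] <- w[-length(w)] + h / 2
  w[-1L] <- w[-1L] + h / 2
  w
}

#' Penalized least-squares fit of one sampled series
#'
#' Solves \eqn{\hat c = \arg\min_c \|y - \Phi c\|^2 + \lambda c^T R c},
#' i.e. the linear system \eqn{(\Phi^T\Phi + \lambda R) c = \Phi^T y}. For
#' \eqn{\lambda > 0} the system is positive definite (the penalty null space
#' of linear functions intersects the interpolation null space only at 0),
#' so constant and linear series are reproduced exactly at any
#' \eqn{\lambda}. At \eqn{\lambda = 0} the system (5 equations, 7 unknowns)
#' is rank deficient and the minimum-norm least-squares solution is returned
#' with a warning.
#'
#' @param y numeric vector of measurements at \code{basis$times}.
#' @param basis an \code{ogtt_basis}.
#' @param lambda non-negative smoothing parameter.
#' @param analyte optional label ("glucose" or "insulin") carried on the fit.
#' @return An object of class \code{ogtt_curve} with elements
#'   \code{coefficients}, \code{lambda}, \code{analyte}, \code{fitted},
#'   \code{residuals}, \code{rss} and the \code{basis}.
#' @export
fit_curve <- function(y, basis, lambda, analyte = NA_character_) {
  stopifnot(inherits(basis, "ogtt_basis"))
  y <- as.numeric(y)
  if (length(y) != length(basis$times) || any(!is.finite(y))) {
    stop("`y` must supply one finite value per measurement time")
  }
  if (!is.finite(lambda) || lambda < 0) stop("`lambda` must be >= 0")
  if (lambda == 0) {
    warning("lambda = 0: under-determined system, returning minimum-norm solution")
    cf <- drop(MASS::ginv(basis$Phi) %*% y)
  } else {
    A <- crossprod(basis$Phi) + lambda * basis$R
    b <- crossprod(basis$Phi, y)
    cf <- solve(A, b)
    # one step of iterative refinement: at large lambda the system is badly
    # conditioned and penalty-free directions (constants, lines) drift
    cf <- drop(cf + solve(A, b - A %*% cf))
  }
  fitted <- drop(basis$Phi %*% cf)
  structure(
    list(coefficients = cf, lambda = lambda, analyte = analyte,
         y = y, fitted = fitted, residuals = y - fitted,
         rss = sum((y - fitted)^2), basis = basis),
    class = "ogtt_curve")
}

#' Fit a cohort of series sharing one basis and one lambda
#'
#' Vectorised form of [fit_curve()] for a matrix of series (participants in
#' rows). One Cholesky factorisation serves the whole cohort.
#'
#' @param Y numeric matrix, one row per participant, one column per
#'   measurement time.
#' @param basis an \code{ogtt_basis}.
#' @param lambda positive smoothing parameter shared by the cohort.
#' @param analyte label carried on the set.
#' @param ids optional participant identifiers (defaults to row names or
#'   1..n).
#' @return An object of class \code{ogtt_curveset}: coefficient matrix
#'   (participants x basis), \code{lambda}, per-participant \code{rss}, the
#'   shared \code{basis} and \code{ids}.
#' @export
fit_curves <- function(Y, basis, lambda, analyte = NA_character_, ids = NULL) {
  stopifnot(inherits(basis, "ogtt_basis"))
  Y <- as.matrix(Y)
  if (ncol(Y) != length(basis$times)) {
    stop("`Y` must have one column per measurement time")
  }
  if (any(!is.finite(Y))) stop("`Y` contains non-finite values")
  if (!is.finite(lambda) || lambda <= 0) stop("`lambda` must be > 0")
  if (is.null(ids)) ids <- if (!is.null(rownames(Y))) rownames(Y) else as.character(seq_len(nrow(Y)))
  A <- crossprod(basis$Phi) + lambda * basis$R
  B <- crossprod(basis$Phi, t(Y))
  Cf <- solve(A, B)
  Cf <- t(Cf + solve(A, B - A %*% Cf))   # n x K, with one refinement step
  fitted <- Cf %*% t(basis$Phi)
  structure(
    list(coefficients = Cf, lambda = lambda, analyte = analyte,
         rss = rowSums((Y - fitted)^2), basis = basis, ids = ids, Y = Y),
    class = "ogtt_curveset")
}

#' @export
print.ogtt_curveset <- function(x, ...) {
  cat(sprintf("OGTT curve set: %d %s curves, lambda = %.4g, mean RSS = %.4g\n",
              nrow(x$coefficients), x$analyte, x$lambda, mean(x$rss)))
  invisible(x)
}

#' Evaluate a fitted curve on a time grid
#'
#' @param curve an \code{ogtt_curve}, or a coefficient vector with
#'   \code{basis} supplied.
#' @param grid evaluation times, all within the basis time range
#'   (extrapolation is an error).
#' @param basis required when \code{curve} is a bare coefficient vector.
#' @return numeric vector of curve values \eqn{\sum_k c_k \phi_k(t)}.
#' @export
evaluate_curve <- function(curve, grid, basis = NULL) {
  if (inherits(curve, "ogtt_curve")) {
    basis <- curve$basis
    cf <- curve$coefficients
  } else {
    stopifnot(inherits(basis, "ogtt_basis"))
    cf <- as.numeric(curve)
  }
  rng <- range(basis$times)
  if (any(grid < rng[1] - 1e-9 | grid > rng[2] + 1e-9)) {
    stop("evaluation grid extends outside the basis time range (no extrapolation)")
  }
  drop(splines::splineDesign(basis$knots, pmin(pmax(grid, rng[1]), rng[2]),
                             ord = basis$order) %*% cf)
}

#' Select the smoothing parameter by pooled leave-one-point-out CV
#'
#' One lambda is chosen per analyte for the whole cohort: for every
#' participant and every held-out time point, the curve is refit from the
#' remaining four points and the held-out measurement is predicted; the
#' lambda minimising the pooled mean squared prediction error wins. Because
#' all participants share the measurement schedule, the leave-one-out
#' predictor at each (lambda, time point) is a fixed linear functional of
#' the remaining points and is precomputed once.
#'
#' When the CV profile is flat to within relative tolerance \code{flat_tol}
#' (e.g. a cohort of straight lines, reproduced exactly at any lambda), the
#' largest grid value is returned and the result is flagged via
#' \code{attr(, "flat")}; exact ties otherwise resolve to the smallest
#' lambda.
#'
#' @param Y numeric matrix of series, participants in rows.
#' @param basis an \code{ogtt_basis}.
#' @param lambda_grid positive candidate values; searched as given after
#'   ascending sort.
#' @param flat_tol relative spread below which the CV profile is considered
#'   flat.
#' @return the selected lambda, with attributes \code{cv} (a data.frame of
#'   lambda and pooled CV error) and \code{flat}.
#' @export
select_lambda <- function(Y, basis, lambda_grid, flat_tol = 1e-8) {
  stopifnot(inherits(basis, "ogtt_basis"))
  Y <- as.matrix(Y)
  if (length(lambda_grid) == 0L) stop("`lambda_grid` must be non-empty")
  if (any(lambda_grid <= 0)) stop("`lambda_grid` values must be > 0")
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  m <- length(basis$times)
  cv <- vapply(lambda_grid, function(lam) {
    pred <- matrix(NA_real_, nrow(Y), m)
    for (j in seq_len(m)) {
      Pj <- basis$Phi[-j, , drop = FALSE]
      A <- crossprod(Pj) + lam * basis$R
      # row vector mapping the 4 retained points to the held-out prediction
      hj <- drop(basis$Phi[j, ] %*% solve(A, t(Pj)))
      pred[, j] <- Y[, -j, drop = FALSE] %*% hj
    }
    mean((Y - pred)^2)
  }, numeric(1))
  spread <- max(cv) - min(cv)
  # a spread negligible against the squared data scale is numerical noise
  flat <- spread <= flat_tol * max(mean(Y^2), .Machine$double.eps)
  lam <- if (flat) lambda_grid[length(lambda_grid)] else lambda_grid[which.min(cv)]
  structure(lam, cv = data.frame(lambda = lambda_grid, cv_error = cv), flat = flat)
}
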