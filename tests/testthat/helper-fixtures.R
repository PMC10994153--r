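# shared fixtures: one default basis, small curve-set constructors

ogtt_times <- c(0, 30, 60, 90, 120)

default_basis <- build_basis()

# curve set straight from a coefficient matrix (rows = participants),
# bypassing the smoothing step for planted-structure FPCA tests
curveset_from_coef <- function(C, basis = default_basis, analyte = "glucose") {
  structure(
    list(coefficients = C, lambda = 1, analyte = analyte,
         rss = rep(0, nrow(C)), basis = basis,
         ids = sprintf("S%03d", seq_len(nrow(C))),
         Y = C %*% t(basis$Phi)),
    class = "ogtt_curveset")
}

# normalize a basis-coefficient vector to unit L2 norm under the Gram matrix
unit_fn <- function(b, basis = default_basis) {
  b / sqrt(drop(t(b) %*% basis$J %*% b))
}

# grid-discretized FPCA oracle: eigen-decomposition of the trapezoid-weighted
# sample covariance of curves evaluated on the quadrature grid
fpca_grid_oracle <- function(C, basis = default_basis, k = 3) {
  X <- C %*% t(basis$Phi_grid)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (nrow(X) - 1)
  sw <- sqrt(basis$weights)
  A <- outer(sw, sw) * S
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  list(values = pmax(e$values, 0),
       xi = sweep(e$vectors[, seq_len(k), drop = FALSE], 1, sw, "/"))
}

# weighted cosine between two functions sampled on the quadrature grid
fn_cosine <- function(f, g, basis = default_basis) {
  w <- basis$weights
  sum(w * f * g) / sqrt(sum(w * f^2) * sum(w * g^2))
}

write_temp_cohort <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  f
}

# minimal valid wide-row for io tests
valid_row <- function(id = "A1") {
  data.frame(id = id, age = 12, sex = "female", race = "white",
             ethnicity = "non-hispanic", bmi_percentile = 96, hba1c = 5.3,
             glucose_0 = 85, glucose_30 = 130, glucose_60 = 120,
             glucose_90 = 110, glucose_120 = 100,
             insulin_0 = 10, insulin_30 = 60, insulin_60 = 70,
             insulin_90 = 50, insulin_120 = 40, stringsAsFactors = FALSE)
}
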