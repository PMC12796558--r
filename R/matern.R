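#' Matérn (nu = 1) correlation function
#'
#' Correlation between points a distance `d` apart, with smoothness fixed at
#' nu = 1 (the conventional SPDE choice) and `range_km` the effective range:
#' the distance at which correlation drops to ~0.1, i.e.
#' `kappa = sqrt(8 * nu) / range_km`.
#'
#' @param d nonnegative distances (km).
#' @param range_km positive effective range (km).
#' @export
matern_cor <- function(d, range_km) {
  if (range_km <= 0) stop("range_km must be positive")
  kappa <- sqrt(8) / range_km
  x <- kappa * d
  out <- ifelse(x == 0, 1, x * besselK(x, 1))
  out[!is.finite(out)] <- 0  # besselK underflow at large x
  out
}

# Cholesky factor (lower) of the Matérn correlation among points; small
# diagonal jitter keeps the factorization stable for near-duplicate points.
.matern_chol <- function(coords, range_km, jitter = 1e-8) {
  D <- as.matrix(stats::dist(coords))
  C <- matern_cor(D, range_km)
  diag(C) <- 1 + jitter
  t(chol(C))
}

#' Simulate a zero-mean Matérn Gaussian random field on a grid
#'
#' Dense-Cholesky sampling of a stationary GRF with Matérn (nu = 1)
#' covariance at the grid cell centers; stands in for latent spatial
#' variability (e.g. variability associated with depth) in the synthetic
#' world. Deterministic for a fixed seed.
#'
#' @param grid a [grid_spec()]; must have at least 4 cells.
#' @param range_km effective correlation range (km), > 0.
#' @param sigma marginal SD, >= 0 (0 gives the all-zero field).
#' @param seed integer seed.
#' @param n_rep number of independent replicate fields (all share one
#'   Cholesky factorization).
#' @return a [grid_field()] when `n_rep = 1`, otherwise an
#'   `n_cells x n_rep` matrix of replicates.
#' @export
simulate_matern_grf <- function(grid, range_km, sigma, seed, n_rep = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (range_km <= 0) stop("range_km must be positive")
  if (sigma < 0) stop("sigma must be nonnegative")
  if (n_cells(grid) < 4) stop("grid must have at least 4 cells")
  cc <- grid_centers(grid)
  n <- n_cells(grid)
  if (sigma == 0) {
    vals <- matrix(0, n, n_rep)
  } else {
    L <- .matern_chol(cc[, c("x", "y")], range_km)
    vals <- withr_seed(seed, sigma * (L %*% matrix(stats::rnorm(n * n_rep), n)))
  }
  if (n_rep == 1) grid_field(grid, vals[, 1]) else vals
}

# run expr with a local RNG state (restores caller's RNG afterwards)
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate AR1-correlated annual Matérn fields
#'
#' One zero-mean spatial field per year with stationary marginal SD
#' `sigma_st` in every year and first-order autoregressive year-to-year
#' correlation `rho` at each cell:
#' `f_t = rho * f_(t-1) + sqrt(1 - rho^2) * sigma_st * innovation`.
#'
#' @param grid a [grid_spec()].
#' @param years ordered integer vector of years.
#' @param rho AR1 correlation, |rho| < 1.
#' @param sigma_st stationary marginal SD, >= 0.
#' @param range_km Matérn effective range of each field (km).
#' @param seed integer seed.
#' @return a [grid_stack()] with one layer per year.
#' @export
simulate_ar1_fields <- function(grid, years, rho, sigma_st, range_km, seed) {
  stopifnot(inherits(grid, "grid_spec"))
  if (abs(rho) >= 1) stop("|rho| must be < 1 (stationarity)")
  if (sigma_st < 0) stop("sigma_st must be nonnegative")
  n <- n_cells(grid)
  T_ <- length(years)
  if (sigma_st == 0) return(grid_stack(grid, years, matrix(0, n, T_)))
  cc <- grid_centers(grid)
  L <- .matern_chol(cc[, c("x", "y")], range_km)
  vals <- withr_seed(seed, {
    z <- L %*% matrix(stats::rnorm(n * T_), n)
    out <- matrix(0, n, T_)
    out[, 1] <- sigma_st * z[, 1]
    if (T_ > 1) for (t in 2:T_)
      out[, t] <- rho * out[, t - 1] + sqrt(1 - rho^2) * sigma_st * z[, t]
    out
  })
  grid_stack(grid, years, vals)
}
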