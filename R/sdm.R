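#' Smooth term definition for an SDM formula
#'
#' @param var covariate column name.
#' @param k basis dimension (>= 3; models here use k = 3 throughout).
#' @export
s_term <- function(var, k = 3) {
  if (k < 3) stop("k must be >= 3")
  list(var = var, k = as.integer(k))
}

#' Specification of a spatiotemporal Tweedie SDM
#'
#' Describes one candidate model: penalized-spline covariate effects, an
#' optional fixed year-factor mean, an optional Gaussian year random
#' intercept, a time-invariant spatial random field and/or AR1-correlated
#' spatiotemporal random fields on a knot mesh, with a Tweedie (log link)
#' observation likelihood. The mesh is controlled by exactly one of
#' `n_knots` (k-means) or `cutoff_km` (greedy thinning) when any field is
#' requested.
#'
#' @param response response column name (nonnegative density, e.g. NASC).
#' @param smooths list of [s_term()] definitions.
#' @param year_factor include fixed year means.
#' @param year_intercept include a Gaussian random intercept of year.
#' @param spatial_field include the time-invariant spatial field.
#' @param st_ar1 include AR1 spatiotemporal fields (requires >= 2 years).
#' @param n_knots,cutoff_km mesh control (exactly one when a field is on).
#' @param name label used in AIC tables.
#' @export
sdm_spec <- function(response = "nasc", smooths = list(), year_factor = FALSE,
                     year_intercept = FALSE, spatial_field = TRUE,
                     st_ar1 = FALSE, n_knots = NULL, cutoff_km = NULL,
                     name = NULL) {
  any_field <- spatial_field || st_ar1
  if (any_field && (is.null(n_knots) + is.null(cutoff_km)) != 1)
    stop("exactly one of n_knots / cutoff_km must be set when a field is on")
  for (s in smooths) if (!is.list(s) || is.null(s$var)) stop("smooths must be s_term() objects")
  structure(list(response = response, smooths = smooths,
                 year_factor = year_factor, year_intercept = year_intercept,
                 spatial_field = spatial_field, st_ar1 = st_ar1,
                 n_knots = n_knots, cutoff_km = cutoff_km,
                 name = if (is.null(name)) "sdm" else name),
            class = "sdm_spec")
}

#' Pairwise-correlation (concurvity) screen for covariates
#'
#' Flags covariate pairs whose squared Pearson correlation meets or
#' exceeds `r2_threshold` (0.7 by default) and enumerates the maximal
#' admissible subsets — subsets in which every pair is below the
#' threshold. Constant covariates have undefined correlation and are
#' excluded with a warning.
#'
#' @param covariate_table data.frame of numeric candidate covariates.
#' @param r2_threshold pairs with r^2 >= this never co-occur.
#' @return list with `r2` (matrix), `excluded` (constant columns),
#'   `conflicts` (data.frame of offending pairs) and `admissible`
#'   (list of maximal admissible covariate subsets).
#' @export
concurvity_screen <- function(covariate_table, r2_threshold = 0.7) {
  covariate_table <- as.data.frame(covariate_table)
  if (ncol(covariate_table) < 2) stop("need at least 2 covariates")
  sds <- vapply(covariate_table, stats::sd, 0, na.rm = TRUE)
  excluded <- names(which(sds == 0 | is.na(sds)))
  if (length(excluded))
    warning("constant covariates excluded (undefined correlation): ",
            paste(excluded, collapse = ", "))
  keep <- setdiff(names(covariate_table), excluded)
  r2 <- stats::cor(covariate_table[keep],
                   use = "pairwise.complete.obs")^2
  conflict <- r2 >= r2_threshold
  diag(conflict) <- FALSE
  pairs <- which(conflict & upper.tri(conflict), arr.ind = TRUE)
  conflicts <- data.frame(a = keep[pairs[, 1]], b = keep[pairs[, 2]],
                          r2 = r2[pairs])
  # maximal independent sets of the conflict graph (small p: plain recursion)
  p <- length(keep)
  adm <- list()
  extend <- function(set, cand) {
    if (!length(cand)) {
      # maximal if no vertex outside `set` is compatible with all of it
      outside <- setdiff(seq_len(p), set)
      if (!any(vapply(outside, function(v) !any(conflict[v, set]), TRUE)) ||
          !length(outside))
        adm[[length(adm) + 1]] <<- keep[sort(set)]
      return(invisible())
    }
    v <- cand[1]
    extend(c(set, v), cand[cand != v & !conflict[cand, v]])
    extend(set, cand[-1])
  }
  extend(integer(0), seq_len(p))
  adm <- unique(adm)
  list(r2 = r2, excluded = excluded, conflicts = conflicts,
       admissible = adm, threshold = r2_threshold)
}

# -- parameter transforms ----------------------------------------------------

.tr_p <- function(tr) 1.01 + 0.98 * stats::plogis(tr)
.tr_p_inv <- function(p) stats::qlogis((p - 1.01) / 0.98)

# theta bookkeeping: named numeric vector on the transformed scale
.theta_template <- function(spec, diam) {
  nm <- c()
  if (length(spec$smooths)) nm <- c(nm, paste0("log_tau_", seq_along(spec$smooths)))
  if (spec$spatial_field || spec$st_ar1) nm <- c(nm, "log_range")
  if (spec$spatial_field) nm <- c(nm, "log_sigma_sp")
  if (spec$st_ar1) nm <- c(nm, "log_sigma_st", "tr_rho")
  if (spec$year_intercept) nm <- c(nm, "log_sigma_y")
  nm <- c(nm, "tr_p", "log_phi")
  start <- lower <- upper <- stats::setNames(numeric(length(nm)), nm)
  for (n in nm) {
    if (startsWith(n, "log_tau_")) { start[n] <- -1; lower[n] <- -10; upper[n] <- 6 }
    else if (n == "log_range") { start[n] <- log(0.25 * diam)
      lower[n] <- log(0.02 * diam); upper[n] <- log(2 * diam) }
    else if (startsWith(n, "log_sigma")) { start[n] <- log(0.5)
      lower[n] <- -7; upper[n] <- 3 }
    else if (n == "tr_rho") { start[n] <- 0
      lower[n] <- atanh(-0.98); upper[n] <- atanh(0.98) }
    else if (n == "tr_p") { start[n] <- 0; lower[n] <- -6; upper[n] <- 6 }
    else if (n == "log_phi") { start[n] <- 0; lower[n] <- -7; upper[n] <- 4 }
  }
  list(start = start, lower = lower, upper = upper)
}

# -- model matrices ----------------------------------------------------------

.build_design <- function(obs, spec, mesh) {
  n <- nrow(obs)
  y <- obs[[spec$response]]
  if (is.null(y)) stop("response column '", spec$response, "' not found")
  if (any(y < 0) || any(!is.finite(y))) stop("response must be finite and nonnegative")
  years <- sort(unique(obs$year))
  Tn <- length(years)
  tix <- match(obs$year, years)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$year_factor && Tn > 1) {
    Xy <- stats::model.matrix(~ factor(year), data.frame(year = obs$year))[, -1, drop = FALSE]
    X <- cbind(X, Xy)
  }

  smooth_objs <- list()
  Zb <- list(); btype <- c(); bsize <- c()
  for (si in seq_along(spec$smooths)) {
    tm <- spec$smooths[[si]]
    if (is.null(obs[[tm$var]])) stop("missing covariate for smooth: ", tm$var)
    def <- eval(str2lang(sprintf("mgcv::s(%s, k = %d, bs = 'cr')", tm$var, tm$k)))
    sm <- mgcv::smoothCon(def, data = obs, absorb.cons = TRUE)[[1]]
    s2r <- mgcv::smooth2random(sm, "", type = 2)
    smooth_objs[[si]] <- list(sm = sm, s2r = s2r, var = tm$var)
    if (!is.null(s2r$Xf) && ncol(s2r$Xf) > 0) {
      colnames(s2r$Xf) <- paste0("s(", tm$var, ")_f", seq_len(ncol(s2r$Xf)))
      X <- cbind(X, s2r$Xf)
    }
    Zb[[length(Zb) + 1]] <- Matrix::Matrix(s2r$rand$Xr, sparse = TRUE)
    btype <- c(btype, "smooth"); bsize <- c(bsize, ncol(s2r$rand$Xr))
  }

  A <- NULL; K <- 0
  if (spec$spatial_field || spec$st_ar1) {
    A <- mesh_project(mesh, cbind(obs$x_km, obs$y_km))
    K <- nrow(mesh$knots)
  }
  if (spec$spatial_field) {
    Zb[[length(Zb) + 1]] <- A
    btype <- c(btype, "spatial"); bsize <- c(bsize, K)
  }
  if (spec$st_ar1) {
    tr <- Matrix::summary(A)
    Zst <- Matrix::sparseMatrix(i = tr$i, j = (tix[tr$i] - 1L) * K + tr$j,
                                x = tr$x, dims = c(n, K * Tn))
    Zb[[length(Zb) + 1]] <- Zst
    btype <- c(btype, "st"); bsize <- c(bsize, K * Tn)
  }
  if (spec$year_intercept) {
    Zb[[length(Zb) + 1]] <- Matrix::sparseMatrix(i = seq_len(n), j = tix,
                                                 x = 1, dims = c(n, Tn))
    btype <- c(btype, "year"); bsize <- c(bsize, Tn)
  }
  Z <- if (length(Zb)) do.call(cbind, Zb) else NULL
  list(y = y, X = X, Z = Z, btype = btype, bsize = bsize, years = years,
       tix = tix, smooth_objs = smooth_objs, A = A, K = K, Tn = Tn)
}

# precision matrix of the joint random-effect vector + its log-determinant
.build_Q <- function(theta, spec, des, knot_dist) {
  if (!length(des$btype)) return(list(Q = NULL, logdet = 0))
  blocks <- list(); logdet <- 0
  Cinv <- NULL; logdetC <- NULL
  if (spec$spatial_field || spec$st_ar1) {
    C <- matern_cor(knot_dist, exp(theta[["log_range"]]))
    diag(C) <- 1 + 1e-6
    ch <- chol(C)
    Cinv <- chol2inv(ch)
    logdetC <- 2 * sum(log(diag(ch)))
  }
  si <- 0
  for (bi in seq_along(des$btype)) {
    tp <- des$btype[bi]; m <- des$bsize[bi]
    if (tp == "smooth") {
      si <- si + 1
      tau2 <- exp(2 * theta[[paste0("log_tau_", si)]])
      blocks[[bi]] <- Matrix::Diagonal(m, 1 / tau2)
      logdet <- logdet - m * log(tau2)
    } else if (tp == "spatial") {
      s2 <- exp(2 * theta[["log_sigma_sp"]])
      blocks[[bi]] <- Matrix::Matrix(Cinv / s2, sparse = TRUE)
      logdet <- logdet - logdetC - m * log(s2)
    } else if (tp == "st") {
      s2 <- exp(2 * theta[["log_sigma_st"]])
      rho <- tanh(theta[["tr_rho"]])
      Tn <- des$Tn; K <- des$K
      d <- c(1, rep(1 + rho^2, max(Tn - 2, 0)), 1)[seq_len(Tn)]
      if (Tn == 1) d <- 1
      Qar <- Matrix::bandSparse(Tn, k = c(0, 1),
                                diagonals = list(d, rep(-rho, Tn - 1)),
                                symmetric = TRUE) / (1 - rho^2)
      blocks[[bi]] <- Matrix::kronecker(Qar, Matrix::Matrix(Cinv / s2, sparse = TRUE))
      logdet <- logdet + K * (-(Tn - 1) * log(1 - rho^2)) +
        Tn * (-logdetC - K * log(s2))
    } else if (tp == "year") {
      s2 <- exp(2 * theta[["log_sigma_y"]])
      blocks[[bi]] <- Matrix::Diagonal(m, 1 / s2)
      logdet <- logdet - m * log(s2)
    }
  }
  list(Q = if (length(blocks) == 1) blocks[[1]] else Matrix::bdiag(blocks),
       logdet = logdet)
}

# Fisher-scoring Newton for the joint mode over (beta, b). `Qfull` is the
# random-effect precision padded with a zero block for the fixed effects.
.inner_newton <- function(v, y, M, pX, Qfull, p, phi, maxit = 60, tol = 1e-8) {
  nb <- ncol(M) - pX
  obj <- function(v) {
    eta <- pmin(as.numeric(M %*% v), 50)
    ll <- sum(tweedie_logpdf(y, exp(eta), p, phi))
    pen <- if (nb > 0) 0.5 * as.numeric(Matrix::crossprod(v, Qfull %*% v)) else 0
    ll - pen
  }
  f <- obj(v)
  for (it in seq_len(maxit)) {
    eta <- pmin(as.numeric(M %*% v), 50)
    mu <- exp(eta)
    s <- (y * mu^(1 - p) - mu^(2 - p)) / phi
    W <- mu^(2 - p) / phi
    g <- as.numeric(Matrix::crossprod(M, s))
    if (nb > 0) g <- g - as.numeric(Qfull %*% v)
    if (max(abs(g)) < tol * (1 + abs(f))) break
    Hw <- Matrix::crossprod(M * sqrt(W))
    if (nb > 0) Hw <- Hw + Qfull
    Hw <- Hw + Matrix::Diagonal(ncol(M), 1e-8)
    step <- tryCatch(as.numeric(Matrix::solve(Hw, g)), error = function(e) NULL)
    if (is.null(step)) {
      Hw <- Hw + Matrix::Diagonal(ncol(M), 1e-4)
      step <- as.numeric(Matrix::solve(Hw, g))
    }
    alpha <- 1
    repeat {
      vn <- v + alpha * step
      fn <- obj(vn)
      if (is.finite(fn) && fn >= f - 1e-12) { v <- vn; f <- fn; break }
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    if (alpha < 1e-10) break
  }
  eta <- pmin(as.numeric(M %*% v), 50)
  mu <- exp(eta)
  list(v = v, f = f, mu = mu,
       loglik = sum(tweedie_logpdf(y, mu, p, phi)),
       W = mu^(2 - p) / phi,
       score = (y * mu^(1 - p) - mu^(2 - p)) / phi)
}

#' Fit a spatiotemporal Tweedie random-field SDM
#'
#' Maximizes the Laplace-approximate marginal likelihood over the
#' variance/correlation/observation parameters, with the random effects
#' (knot-level field values, penalized-spline coefficients, year
#' intercepts) integrated out and the fixed effects profiled in the inner
#' Newton problem. Fields use a predictive-process construction: Gaussian
#' knot effects with Matérn (nu = 1) covariance between knots, projected
#' to observations by barycentric interpolation. The spatiotemporal field
#' is first-order autoregressive across years with a shared Matérn range.
#'
#' @param obs observation data.frame with `x_km`, `y_km`, `year`, the
#'   response column and any smooth covariates.
#' @param spec an [sdm_spec()].
#' @param mesh optional pre-built `knot_mesh`; built from `spec` otherwise.
#' @param control list: `hessian` (compute outer Hessian and Wald CIs,
#'   default TRUE), `trace` (nlminb trace level), `maxit` (outer
#'   iterations, default 300).
#' @return an object of class `sdm_fit`; see [check_convergence()],
#'   [predict.sdm_fit()], [r2_decompose()].
#' @export
fit_sdm <- function(obs, spec, mesh = NULL, control = list()) {
  stopifnot(inherits(spec, "sdm_spec"))
  ctrl <- utils::modifyList(list(hessian = TRUE, trace = 0, maxit = 300,
                                 rel_tol = 1e-7), control)
  if (spec$st_ar1 && length(unique(obs$year)) < 2)
    stop("AR1 spatiotemporal fields require >= 2 years of observations")
  if ((spec$spatial_field || spec$st_ar1) && is.null(mesh)) {
    coords <- cbind(obs$x_km, obs$y_km)
    mesh <- if (!is.null(spec$n_knots)) select_knots(coords, spec$n_knots)
            else select_knots_by_cutoff(coords, spec$cutoff_km)
  }
  des <- .build_design(obs, spec, mesh)
  n <- length(des$y); pX <- ncol(des$X)
  nb <- if (is.null(des$Z)) 0 else ncol(des$Z)
  M <- if (nb > 0) cbind(Matrix::Matrix(des$X, sparse = TRUE), des$Z)
       else Matrix::Matrix(des$X, sparse = TRUE)
  knot_dist <- if (!is.null(mesh)) as.matrix(stats::dist(mesh$knots)) else NULL
  diam <- max(stats::dist(rbind(
    c(min(obs$x_km), min(obs$y_km)), c(max(obs$x_km), max(obs$y_km)))), 1)
  tt <- .theta_template(spec, diam)

  env <- new.env()
  env$v <- c(log(mean(des$y) + 1e-3), numeric(pX - 1 + nb))
  env$count <- 0L

  nll <- function(theta) {
    theta <- stats::setNames(theta, names(tt$start))
    out <- tryCatch({
      p <- .tr_p(theta[["tr_p"]]); phi <- exp(theta[["log_phi"]])
      Qb <- .build_Q(theta, spec, des, knot_dist)
      Qfull <- if (nb > 0) Matrix::bdiag(Matrix::Diagonal(pX, 0), Qb$Q) else NULL
      fit <- .inner_newton(env$v, des$y, M, pX, Qfull, p, phi)
      env$v <- fit$v
      env$count <- env$count + 1L
      if (nb > 0) {
        b <- fit$v[-seq_len(pX)]
        # Laplace needs the OBSERVED information at the mode (Fisher
        # weights are only used to drive the Newton steps)
        Wobs <- ((2 - p) * fit$mu^(2 - p) +
                   (p - 1) * des$y * fit$mu^(1 - p)) / phi
        Hbb <- Matrix::crossprod(des$Z * sqrt(Wobs)) + Qb$Q +
          Matrix::Diagonal(nb, 1e-8)
        ldH <- as.numeric(Matrix::determinant(Matrix::forceSymmetric(Hbb),
                                              logarithm = TRUE)$modulus)
        -(fit$loglik - 0.5 * as.numeric(Matrix::crossprod(b, Qb$Q %*% b)) +
            0.5 * Qb$logdet - 0.5 * ldH)
      } else -fit$loglik
    }, error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }

  nll_init <- nll(tt$start)
  opt <- stats::nlminb(tt$start, nll, lower = tt$lower, upper = tt$upper,
                       control = list(trace = ctrl$trace, iter.max = ctrl$maxit,
                                      eval.max = 2000,
                                      rel.tol = ctrl$rel_tol))
  theta <- stats::setNames(opt$par, names(tt$start))
  # refresh state at the optimum
  final_nll <- nll(theta)
  p_hat <- .tr_p(theta[["tr_p"]]); phi_hat <- exp(theta[["log_phi"]])
  Qb <- .build_Q(theta, spec, des, knot_dist)
  Qfull_f <- if (nb > 0) Matrix::bdiag(Matrix::Diagonal(pX, 0), Qb$Q) else NULL
  fitin <- .inner_newton(env$v, des$y, M, pX, Qfull_f, p_hat, phi_hat)
  grad_fixed <- as.numeric(crossprod(des$X, fitin$score))

  hess <- NULL; hess_pd <- NA; ci <- NULL
  if (ctrl$hessian) {
    hess <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
    if (!is.null(hess)) {
      ev <- eigen(hess, symmetric = TRUE, only.values = TRUE)$values
      hess_pd <- all(ev > 0)
      se <- tryCatch(sqrt(diag(solve(hess))), error = function(e) rep(NA, length(theta)))
      ci <- data.frame(theta = names(theta), est = theta, se = se,
                       lo = theta - 1.96 * se, hi = theta + 1.96 * se)
    }
  }

  nat <- function(nm, f) if (nm %in% names(theta)) f(theta[[nm]]) else NA_real_
  nat_ci <- function(nm, f) {
    if (is.null(ci) || !nm %in% ci$theta) return(c(NA_real_, NA_real_))
    r <- ci[ci$theta == nm, ]
    sort(c(f(r$lo), f(r$hi)))
  }
  n_par <- pX + length(theta)
  loglik <- -final_nll
  par_tab <- rbind(
    data.frame(param = "range_km", est = nat("log_range", exp),
               lo = nat_ci("log_range", exp)[1], hi = nat_ci("log_range", exp)[2]),
    data.frame(param = "sigma_spatial", est = nat("log_sigma_sp", exp),
               lo = nat_ci("log_sigma_sp", exp)[1], hi = nat_ci("log_sigma_sp", exp)[2]),
    data.frame(param = "sigma_st", est = nat("log_sigma_st", exp),
               lo = nat_ci("log_sigma_st", exp)[1], hi = nat_ci("log_sigma_st", exp)[2]),
    data.frame(param = "rho", est = nat("tr_rho", tanh),
               lo = nat_ci("tr_rho", tanh)[1], hi = nat_ci("tr_rho", tanh)[2]),
    data.frame(param = "sigma_year", est = nat("log_sigma_y", exp),
               lo = nat_ci("log_sigma_y", exp)[1], hi = nat_ci("log_sigma_y", exp)[2]),
    data.frame(param = "tweedie_p", est = .tr_p(theta[["tr_p"]]),
               lo = nat_ci("tr_p", .tr_p)[1], hi = nat_ci("tr_p", .tr_p)[2]),
    data.frame(param = "tweedie_phi", est = phi_hat,
               lo = nat_ci("log_phi", exp)[1], hi = nat_ci("log_phi", exp)[2]))
  par_tab <- par_tab[!is.na(par_tab$est), ]

  structure(list(
    spec = spec, mesh = mesh, des = des, obs = obs,
    theta = theta, opt = opt,
    beta = stats::setNames(fitin$v[seq_len(pX)], colnames(des$X)),
    b = if (nb > 0) fitin$v[-seq_len(pX)] else numeric(0),
    fitted_link = pmin(as.numeric(M %*% fitin$v), 50),
    range_km = nat("log_range", exp),
    sigma_spatial = nat("log_sigma_sp", exp),
    sigma_st = nat("log_sigma_st", exp),
    rho = nat("tr_rho", tanh),
    sigma_year = nat("log_sigma_y", exp),
    tau = exp(theta[grepl("^log_tau_", names(theta))]),
    tweedie_p = p_hat, tweedie_phi = phi_hat,
    loglik = loglik, loglik_init = -nll_init, n_params = n_par,
    aic = -2 * loglik + 2 * n_par,
    gradient_max = max(abs(grad_fixed)),
    hessian = hess, hessian_pd = hess_pd,
    par_table = par_tab,
    n_obs = n, n_eval = env$count,
    convergence = opt$convergence, message = opt$message),
    class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> '%s': n = %d, logLik = %.2f, AIC = %.2f\n",
              x$spec$name, x$n_obs, x$loglik, x$aic))
  cat(sprintf("  Tweedie p = %.3f, phi = %.3f\n", x$tweedie_p, x$tweedie_phi))
  if (!is.na(x$range_km)) cat(sprintf("  field range = %.1f km\n", x$range_km))
  if (!is.na(x$sigma_spatial)) cat(sprintf("  sigma_spatial = %.3f\n", x$sigma_spatial))
  if (!is.na(x$sigma_st)) cat(sprintf("  sigma_st = %.3f, rho = %.3f\n", x$sigma_st, x$rho))
  cc <- check_convergence(x)
  cat("  convergence:", if (cc$pass) "ok" else paste("FAILED:", paste(cc$reasons, collapse = ", ")), "\n")
  invisible(x)
}

#' Convergence diagnostics for an SDM fit
#'
#' A fit passes iff the maximum log-likelihood gradient with respect to
#' the fixed effects is < 0.01, the outer Hessian is positive definite,
#' and no random-field marginal SD collapsed below 0.01 (a degenerate
#' field).
#'
#' @param fit an `sdm_fit`.
#' @return list with `pass` (logical) and `reasons` (character).
#' @export
check_convergence <- function(fit) {
  reasons <- character(0)
  if (!is.finite(fit$gradient_max) || fit$gradient_max >= 0.01)
    reasons <- c(reasons, "gradient")
  if (isFALSE(fit$hessian_pd)) reasons <- c(reasons, "hessian")
  sds <- c(fit$sigma_spatial, fit$sigma_st)
  sds <- sds[!is.na(sds)]
  if (length(sds) && any(sds < 0.01)) reasons <- c(reasons, "degenerate field")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Rank candidate model specifications by AIC
#'
#' Fits (or accepts pre-fitted) candidates on one observation set,
#' excludes non-converged fits with a warning, and ranks by AIC with
#' ties broken by fewer parameters then by name.
#'
#' @param candidates list of [sdm_spec()]s or of `sdm_fit`s.
#' @param obs observation table (ignored when fits are supplied).
#' @param ... passed to [fit_sdm()].
#' @return data.frame sorted by AIC with a `delta_aic` column.
#' @export
aic_select <- function(candidates, obs = NULL, ...) {
  fits <- lapply(candidates, function(cand) {
    if (inherits(cand, "sdm_fit")) cand else fit_sdm(obs, cand, ...)
  })
  conv <- vapply(fits, function(f) check_convergence(f)$pass, TRUE)
  if (any(!conv))
    warning("excluding non-converged candidates: ",
            paste(vapply(fits[!conv], function(f) f$spec$name, ""), collapse = ", "))
  fits <- fits[conv]
  if (!length(fits)) stop("no converged candidates")
  tab <- data.frame(name = vapply(fits, function(f) f$spec$name, ""),
                    aic = vapply(fits, function(f) f$aic, 0),
                    loglik = vapply(fits, function(f) f$loglik, 0),
                    n_params = vapply(fits, function(f) f$n_params, 0))
  tab <- tab[order(tab$aic, tab$n_params, tab$name), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Predict from a fitted SDM
#'
#' Link-scale prediction = fixed effects + smooth effects + interpolated
#' random fields + year intercept; response scale = `exp(link)`.
#'
#' @param object an `sdm_fit`.
#' @param newdata data.frame with `x_km`, `y_km`, `year` and any smooth
#'   covariates; defaults to the training observations.
#' @param type `"link"` or `"response"`.
#' @param include_fields include the spatial/spatiotemporal random fields
#'   (set `FALSE` for the covariates-only, marginal prediction).
#' @param include_year_re include the year random intercept.
#' @param ... unused.
#' @export
predict.sdm_fit <- function(object, newdata = NULL, type = c("link", "response"),
                            include_fields = TRUE, include_year_re = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$obs
  des <- object$des; spec <- object$spec
  n <- nrow(newdata)
  eta <- rep(object$beta[["(Intercept)"]], n)
  if (spec$year_factor && des$Tn > 1) {
    if (!all(newdata$year %in% des$years))
      stop("prediction years outside fitted year levels")
    lev <- paste0("factor(year)", des$years[-1])
    for (j in seq_along(lev)) {
      w <- newdata$year == des$years[j + 1]
      eta[w] <- eta[w] + object$beta[[lev[j]]]
    }
  }
  # random-effect pointer into b
  offs <- c(0, cumsum(des$bsize))
  si <- 0
  for (bi in seq_along(des$btype)) {
    tp <- des$btype[bi]
    bcoef <- object$b[(offs[bi] + 1):offs[bi + 1]]
    if (tp == "smooth") {
      si <- si + 1
      so <- des$smooth_objs[[si]]
      if (is.null(newdata[[so$var]])) stop("missing covariate layer: ", so$var)
      Xp <- mgcv::PredictMat(so$sm, newdata)
      Zall <- Xp %*% so$s2r$trans.U %*% diag(so$s2r$trans.D, length(so$s2r$trans.D))
      mr <- ncol(so$s2r$rand$Xr)
      eta <- eta + as.numeric(Zall[, seq_len(mr), drop = FALSE] %*% bcoef)
      if (ncol(Zall) > mr) {
        fnames <- paste0("s(", so$var, ")_f", seq_len(ncol(Zall) - mr))
        eta <- eta + as.numeric(Zall[, -seq_len(mr), drop = FALSE] %*%
                                  object$beta[fnames])
      }
    } else if (tp == "spatial" && include_fields) {
      An <- mesh_project(object$mesh, cbind(newdata$x_km, newdata$y_km))
      eta <- eta + as.numeric(An %*% bcoef)
    } else if (tp == "st" && include_fields) {
      if (!all(newdata$year %in% des$years))
        stop("prediction years outside fitted years")
      An <- mesh_project(object$mesh, cbind(newdata$x_km, newdata$y_km))
      tixn <- match(newdata$year, des$years)
      vmat <- matrix(bcoef, des$K, des$Tn)
      eta <- eta + Matrix::rowSums(An * t(vmat[, tixn, drop = FALSE]))
    } else if (tp == "year" && include_year_re) {
      tixn <- match(newdata$year, des$years)
      eta <- eta + ifelse(is.na(tixn), 0, bcoef[tixn])
    }
  }
  if (type == "link") eta else exp(eta)
}

#' Predict an SDM over a grid
#'
#' @param fit an `sdm_fit`.
#' @param grid a [grid_spec()] to predict on.
#' @param years years to predict (must be fitted years when year terms or
#'   AR1 fields are present).
#' @param covariates named list of [grid_field()]/[grid_stack()] layers
#'   supplying every smooth covariate in the spec; an error names any
#'   missing layer.
#' @return list of two [grid_stack()]s: `link` and `response`.
#' @export
predict_grid <- function(fit, grid, years, covariates = NULL) {
  cc <- grid_centers(grid)
  need <- vapply(fit$spec$smooths, function(s) s$var, "")
  for (v in need)
    if (is.null(covariates[[v]])) stop("missing covariate layer: ", v)
  link <- matrix(NA_real_, n_cells(grid), length(years))
  for (j in seq_along(years)) {
    nd <- data.frame(x_km = cc$x, y_km = cc$y, year = years[j])
    for (v in need) {
      lay <- covariates[[v]]
      nd[[v]] <- if (inherits(lay, "grid_stack"))
        lay$values[, match(years[j], lay$years)] else lay$values
    }
    ok <- stats::complete.cases(nd)
    link[ok, j] <- predict(fit, nd[ok, , drop = FALSE], type = "link")
  }
  list(link = grid_stack(grid, years, link),
       response = grid_stack(grid, years, exp(link)))
}

#' Decompose variance explained into conditional and marginal r-squared
#'
#' Squared Pearson correlation of observed vs predicted density, both on
#' the `log(x + 0.01)` scale. The conditional r^2 uses the full
#' prediction; the marginal r^2 zeroes the spatial and spatiotemporal
#' fields (and the year random intercept), leaving covariate and fixed
#' year effects; the spatiotemporal r^2 is their difference — the share
#' attributable to the latent fields.
#'
#' @param fit an `sdm_fit`.
#' @param obs observation table (defaults to the training data).
#' @return list with `conditional_r2`, `marginal_r2`, `spatiotemporal_r2`.
#' @export
r2_decompose <- function(fit, obs = NULL) {
  if (is.null(obs)) obs <- fit$obs
  y <- log(obs[[fit$spec$response]] + 0.01)
  if (stats::var(y) == 0) stop("zero-variance observations")
  full <- log(predict(fit, obs, type = "response") + 0.01)
  marg <- log(predict(fit, obs, type = "response", include_fields = FALSE,
                      include_year_re = FALSE) + 0.01)
  cond_r2 <- stats::cor(y, full)^2
  marg_r2 <- if (stats::var(marg) == 0) 0 else stats::cor(y, marg)^2
  list(conditional_r2 = cond_r2, marginal_r2 = marg_r2,
       spatiotemporal_r2 = max(0, cond_r2 - marg_r2))
}

#' Simulate observations from the SDM model class
#'
#' Generates data exactly from the predictive-process model that
#' [fit_sdm()] estimates: Gaussian knot effects with Matérn (nu = 1)
#' covariance (time-invariant and/or AR1 across years), barycentric
#' projection to the observation coordinates, log link, Tweedie sampling.
#' Used by the parameter-recovery checks, which separate estimator
#' correctness from mesh-approximation error.
#'
#' @param coords n x 2 matrix of observation coordinates (km).
#' @param years_of_obs integer year per observation.
#' @param mesh a `knot_mesh`.
#' @param beta0 intercept on the log scale.
#' @param range_km,sigma_spatial,sigma_st,rho field parameters (set an SD
#'   to 0 to drop that field).
#' @param p,phi Tweedie observation parameters.
#' @param seed integer seed.
#' @return data.frame with `x_km`, `y_km`, `year`, `nasc`, `eta_true`.
#' @export
simulate_sdm_obs <- function(coords, years_of_obs, mesh, beta0 = 2,
                             range_km = 30, sigma_spatial = 0, sigma_st = 0.8,
                             rho = 0.5, p = 1.5, phi = 1.2, seed = 1) {
  coords <- as.matrix(coords)
  years <- sort(unique(years_of_obs))
  Tn <- length(years); K <- nrow(mesh$knots)
  A <- mesh_project(mesh, coords)
  tix <- match(years_of_obs, years)
  withr_seed(seed, {
    L <- .matern_chol(mesh$knots, range_km, jitter = 1e-6)
    eta <- rep(beta0, nrow(coords))
    if (sigma_spatial > 0)
      eta <- eta + as.numeric(A %*% (sigma_spatial * (L %*% stats::rnorm(K))))
    if (sigma_st > 0) {
      vmat <- matrix(0, K, Tn)
      z <- L %*% matrix(stats::rnorm(K * Tn), K)
      vmat[, 1] <- sigma_st * z[, 1]
      if (Tn > 1) for (t in 2:Tn)
        vmat[, t] <- rho * vmat[, t - 1] + sqrt(1 - rho^2) * sigma_st * z[, t]
      eta <- eta + Matrix::rowSums(A * t(vmat[, tix, drop = FALSE]))
    }
    data.frame(x_km = coords[, 1], y_km = coords[, 2], year = years_of_obs,
               nasc = rtweedie(length(eta), exp(eta), p, phi),
               eta_true = eta)
  })
}
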