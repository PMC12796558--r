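# fake minimal fits for testing selection/diagnostic logic in isolation
fake_fit <- function(name, loglik, n_params, grad = 1e-4, pd = TRUE,
                     sds = numeric(0)) {
  structure(list(spec = list(name = name), loglik = loglik,
                 n_params = n_params, aic = -2 * loglik + 2 * n_params,
                 gradient_max = grad, hessian_pd = pd,
                 sigma_spatial = if (length(sds)) sds[1] else NA_real_,
                 sigma_st = if (length(sds) > 1) sds[2] else NA_real_),
            class = "sdm_fit")
}

test_that("spec validation and convergence-check thresholds", {
  expect_error(sdm_spec(spatial_field = TRUE), "exactly one")
  expect_error(sdm_spec(spatial_field = TRUE, n_knots = 10, cutoff_km = 5),
               "exactly one")
  expect_error(s_term("x", k = 2), "k must be")

  ok <- fake_fit("a", -10, 3, grad = 0.005, sds = c(0.3, 0.8))
  expect_true(check_convergence(ok)$pass)
  bad_g <- fake_fit("b", -10, 3, grad = 0.02)
  expect_identical(check_convergence(bad_g)$reasons, "gradient")
  bad_h <- fake_fit("c", -10, 3, pd = FALSE)
  expect_identical(check_convergence(bad_h)$reasons, "hessian")
  degen <- fake_fit("d", -10, 3, sds = c(0.001))
  expect_identical(check_convergence(degen)$reasons, "degenerate field")
})

test_that("AIC identity and ranking with tie-breaks", {
  f1 <- fake_fit("same1", -100, 5)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * f1$n_params)
  tab <- aic_select(list(f1, fake_fit("same2", -100, 5)))
  expect_equal(tab$delta_aic, c(0, 0))
  # one extra parameter at identical log-likelihood: delta exactly +2,
  # and the smaller model wins the tie-break
  tab2 <- aic_select(list(fake_fit("big", -100, 6), fake_fit("small", -100, 5)))
  expect_identical(tab2$name, c("small", "big"))
  expect_equal(tab2$delta_aic, c(0, 2))
  # non-converged candidates are excluded with a warning
  expect_warning(tab3 <- aic_select(list(f1, fake_fit("bad", -90, 5, grad = 1))),
                 "bad")
  expect_identical(nrow(tab3), 1L)
})

test_that("concurvity screen separates collinear covariates", {
  set.seed(1)
  n <- 300
  a <- rnorm(n); b <- 0.97 * a + sqrt(1 - 0.97^2) * rnorm(n)  # r2 ~ 0.94
  c_ <- rnorm(n); d <- rnorm(n)
  sc <- concurvity_screen(data.frame(a = a, b = b, c = c_, d = d))
  expect_gt(sc$r2["a", "b"], 0.7)
  # a and b never co-occur in an admissible subset
  expect_false(any(vapply(sc$admissible,
                          function(s) all(c("a", "b") %in% s), TRUE)))
  # duplicated covariate conflicts with itself (r2 = 1)
  sc2 <- concurvity_screen(data.frame(a = a, a2 = a * 2, c = c_))
  expect_true(any(sc2$conflicts$a == "a" | sc2$conflicts$b == "a2"))
  # three independent covariates: the full set is admissible
  sc3 <- concurvity_screen(data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n)))
  expect_true(any(vapply(sc3$admissible, function(s) length(s) == 3, TRUE)))
  # constant covariate excluded with a warning
  expect_warning(sc4 <- concurvity_screen(data.frame(a = a, k = rep(1, n))),
                 "constant")
  expect_identical(sc4$excluded, "k")
})

test_that("reduced model reproduces the independent Tweedie ML oracle", {
  set.seed(21)
  y <- rtweedie(1500, 2.2, 1.6, 0.9)
  obs <- data.frame(x_km = runif(1500, 0, 50), y_km = runif(1500, 0, 50),
                    year = 2018L, nasc = y)
  fit <- fit_sdm(obs, sdm_spec(spatial_field = FALSE, name = "null"),
                 control = list(hessian = FALSE))
  o <- oracle_tweedie_ml(y)
  expect_lt(abs(exp(fit$beta[["(Intercept)"]]) - o$mu), 1e-3)
  expect_lt(abs(fit$tweedie_p - o$p), 1e-3)
  expect_lt(abs(fit$tweedie_phi - o$phi), 1e-3)
  expect_lt(fit$gradient_max, 0.01)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  # optimizer never ends below its initialization
  expect_gte(fit$loglik, fit$loglik_init - 1e-6)
})

test_that("spatial-field fit recovers the surface and predicts consistently", {
  set.seed(33)
  n <- 900
  coords <- cbind(runif(n, 0, 90), runif(n, 0, 90))
  mesh <- select_knots(coords, 30, seed = 2)
  obs <- simulate_sdm_obs(coords, rep(2018L, n), mesh, beta0 = 1.5,
                          range_km = 35, sigma_spatial = 1, sigma_st = 0,
                          p = 1.5, phi = 0.8, seed = 9)
  fit <- fit_sdm(obs, sdm_spec(spatial_field = TRUE, st_ar1 = FALSE,
                               n_knots = 30, name = "sp"),
                 mesh = mesh, control = list(hessian = FALSE))
  # latent-surface recovery
  expect_gt(cor(predict(fit, type = "link"), obs$eta_true), 0.8)
  # prediction at the observations equals the fitted values
  expect_lt(max(abs(predict(fit, obs, type = "link") - fit$fitted_link)), 1e-8)
  # response scale is exp(link), everywhere positive
  resp <- predict(fit, obs, type = "response")
  expect_equal(resp, exp(predict(fit, obs, type = "link")), tolerance = 1e-12)
  expect_true(all(resp > 0))
  # r2 nesting: conditional >= marginal
  r2 <- r2_decompose(fit)
  expect_gte(r2$conditional_r2, r2$marginal_r2)
  expect_equal(r2$spatiotemporal_r2,
               max(0, r2$conditional_r2 - r2$marginal_r2))
})

test_that("fitted values are translation-equivariant", {
  set.seed(35)
  n <- 500
  coords <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  mesh <- select_knots(coords, 20, seed = 3)
  obs <- simulate_sdm_obs(coords, rep(1L, n), mesh, beta0 = 1, range_km = 25,
                          sigma_spatial = 0.8, sigma_st = 0, p = 1.5,
                          phi = 1, seed = 4)
  spec <- sdm_spec(spatial_field = TRUE, n_knots = 20)
  f1 <- fit_sdm(obs, spec, control = list(hessian = FALSE))
  obs2 <- obs; obs2$x_km <- obs$x_km + 500; obs2$y_km <- obs$y_km - 200
  f2 <- fit_sdm(obs2, spec, control = list(hessian = FALSE))
  expect_lt(max(abs(f1$fitted_link - f2$fitted_link)), 1e-4)
})

test_that("degenerate spatial field is flagged per the SD < 0.01 rule", {
  set.seed(37)
  n <- 800
  coords <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  mesh <- select_knots(coords, 25, seed = 5)
  # truth has NO spatial field
  obs <- simulate_sdm_obs(coords, rep(1L, n), mesh, beta0 = 1.2, range_km = 25,
                          sigma_spatial = 0, sigma_st = 0, p = 1.5, phi = 1,
                          seed = 6)
  fit <- fit_sdm(obs, sdm_spec(spatial_field = TRUE, n_knots = 25),
                 mesh = mesh, control = list(hessian = FALSE))
  expect_lt(fit$sigma_spatial, 0.01)
  expect_true("degenerate field" %in% check_convergence(fit)$reasons)
})

test_that("smooth terms recover a nonlinear covariate effect", {
  set.seed(39)
  n <- 900
  x <- runif(n, -2, 2)
  eta <- 1 + sin(1.5 * x)
  obs <- data.frame(x_km = runif(n, 0, 50), y_km = runif(n, 0, 50),
                    year = 1L, nasc = rtweedie(n, exp(eta), 1.5, 0.5),
                    sst = x)
  fit <- fit_sdm(obs, sdm_spec(smooths = list(s_term("sst", 5)),
                               spatial_field = FALSE),
                 control = list(hessian = FALSE))
  expect_gt(cor(predict(fit, type = "link"), eta), 0.9)
  # covariates-only truth: marginal ~ conditional
  r2 <- r2_decompose(fit)
  expect_lt(r2$conditional_r2 - r2$marginal_r2, 0.05)
  # missing covariate in newdata errors by name
  expect_error(predict(fit, obs[, setdiff(names(obs), "sst")]), "sst")
})

test_that("AR1 fields need >= 2 years", {
  obs <- data.frame(x_km = runif(30), y_km = runif(30), year = 1L,
                    nasc = rexp(30))
  expect_error(fit_sdm(obs, sdm_spec(st_ar1 = TRUE, spatial_field = FALSE,
                                     n_knots = 5)), ">= 2 years")
})
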