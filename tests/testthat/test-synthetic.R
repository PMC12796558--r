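test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(grid_extent = c(0, 100, 0, 90), cell_km = 3), "divide")
  expect_error(sim_config(tweedie_p = 2), "tweedie_p")
  expect_error(sim_config(rho_ar1 = 1), "rho_ar1")
})

test_that("matern GRF: determinism, zero-variance and error cases", {
  g <- grid_spec(0, 0, 3, 12, 12)
  f1 <- simulate_matern_grf(g, 30, 1, seed = 5)
  f2 <- simulate_matern_grf(g, 30, 1, seed = 5)
  expect_identical(f1$values, f2$values)   # bitwise for same seed
  f3 <- simulate_matern_grf(g, 30, 1, seed = 6)
  expect_false(identical(f1$values, f3$values))
  expect_identical(simulate_matern_grf(g, 30, 0, seed = 1)$values,
                   rep(0, 144))
  expect_error(simulate_matern_grf(g, -1, 1, 1), "range")
  expect_error(simulate_matern_grf(grid_spec(0, 0, 1, 1, 2), 10, 1, 1),
               "at least 4 cells")
})

test_that("matern GRF variogram has the designed sill and range", {
  # Monte-Carlo check of the stated covariance: sill ~ sigma^2 = 1,
  # effective range (gamma = 0.9 * sill) within 20% of the target
  g <- grid_spec(0, 0, 2, 40, 40)   # 80 km domain (scaled from the
                                    # 60x60 example to keep runtime down)
  range_true <- 24
  reps <- simulate_matern_grf(g, range_true, 1, seed = 99, n_rep = 150)
  cc <- grid_centers(g)
  vg <- oracle_variogram(reps, cc[, c("x", "y")], breaks = seq(0, 60, by = 4))
  sill <- mean(vg$gamma[vg$dist > 2 * range_true], na.rm = TRUE)
  expect_lt(abs(sill - 1), 0.1)
  # effective range: linear interpolation of the 0.9-sill crossing
  i <- which(vg$gamma >= 0.9 * sill)[1]
  eff <- vg$dist[i - 1] + (vg$dist[i] - vg$dist[i - 1]) *
    (0.9 * sill - vg$gamma[i - 1]) / (vg$gamma[i] - vg$gamma[i - 1])
  expect_lt(abs(eff - range_true) / range_true, 0.2)
})

test_that("AR1 stacks are stationary with the designed lag-1 correlation", {
  g <- grid_spec(0, 0, 2, 32, 32)
  st <- simulate_ar1_fields(g, 2001:2012, rho = 0.8, sigma_st = 1.5,
                            range_km = 10, seed = 3)
  v <- st$values
  # stationary marginal SD every year (Monte-Carlo tolerance over 1024 cells)
  sds <- apply(v, 2, sd)
  expect_true(all(abs(sds - 1.5) / 1.5 < 0.25))
  # pooled lag-1 cellwise correlation near 0.8
  r <- cor(as.numeric(v[, -ncol(v)]), as.numeric(v[, -1]))
  expect_lt(abs(r - 0.8), 0.05)
  # rho = 0: no year-to-year correlation
  st0 <- simulate_ar1_fields(g, 2001:2012, rho = 0, sigma_st = 1,
                             range_km = 10, seed = 4)
  r0 <- cor(as.numeric(st0$values[, -12]), as.numeric(st0$values[, -1]))
  expect_lt(abs(r0), 0.05)
  # degenerate cases
  expect_equal(unname(simulate_ar1_fields(g, 2001:2003, 0.5, 0, 10, 1)$values),
               matrix(0, 1024, 3))
  expect_error(simulate_ar1_fields(g, 2001:2003, 1, 1, 10, 1), "stationarity")
})

test_that("simulate_survey conserves records and respects the zero mass", {
  g <- grid_spec(0, 0, 3, 20, 20)
  truth <- grid_field(g, rep(1, 400))    # constant mu = 1
  tl <- transect_layout(g, spacing_km = 6)
  obs <- simulate_survey(truth, tl, p = 1.5, phi = 1, seed = 10)
  expect_identical(nrow(obs), nrow(tl))  # all bins inside -> count conserved
  # zero fraction ~ exp(-2) at mu=1, p=1.5, phi=1
  big <- simulate_survey(truth, tl[rep(seq_len(nrow(tl)), 40), ], 1.5, 1,
                         seed = 11)
  p0 <- exp(-2)
  se <- sqrt(p0 * (1 - p0) / nrow(big))
  expect_lt(abs(mean(big$nasc == 0) - p0), max(3 * se, 0.01))
  # out-of-grid bins dropped with a message
  tl_out <- rbind(tl, data.frame(transect = 99, bin = 1, x = -5, y = -5))
  expect_message(obs2 <- simulate_survey(truth, tl_out, 1.5, 1, seed = 1),
                 "dropped")
  expect_identical(nrow(obs2), nrow(tl))
  # non-positive truth rejected
  bad <- grid_field(g, rep(0, 400))
  expect_error(simulate_survey(bad, tl, 1.5, 1, 1), "strictly positive")
})

test_that("survey determinism: same seed, same records", {
  g <- grid_spec(0, 0, 3, 10, 10)
  truth <- grid_field(g, rexp(100) + 0.5)
  tl <- transect_layout(g, 6)
  expect_identical(simulate_survey(truth, tl, 1.5, 1, seed = 7),
                   simulate_survey(truth, tl, 1.5, 1, seed = 7))
})

test_that("dual-frequency generator plants recoverable krill cells", {
  mask <- matrix(FALSE, 20, 50)
  mask[5:10, 10:30] <- TRUE
  eg <- simulate_dual_frequency_echogram(mask, db_diff_target = 13.15,
                                         noise_sd = 0, seed = 1)
  got <- db_difference_classify(eg$sv120, eg$sv38)
  expect_identical(got, mask)            # noise-free round trip
  # empty mask -> empty classification
  eg0 <- simulate_dual_frequency_echogram(matrix(FALSE, 4, 6), seed = 1)
  expect_false(any(db_difference_classify(eg0$sv120, eg0$sv38)))
  # noisy recall matches the Gaussian window probability
  maskb <- matrix(TRUE, 100, 100)
  egn <- simulate_dual_frequency_echogram(maskb, 13.15, noise_sd = 1, seed = 2)
  rec <- mean(db_difference_classify(egn$sv120, egn$sv38)[maskb])
  expected <- pnorm(16.3 - 13.15) - pnorm(10.0 - 13.15)
  expect_lt(abs(rec - expected), 0.005)
})

test_that("planted hotspot surfaces achieve the designed overlap", {
  g <- grid_spec(0, 0, 1, 100, 100)
  ph <- plant_hotspot_surfaces(2, 0.40, g, seed = 3)
  A <- ph$masks[[1]]; B <- ph$masks[[2]]
  J <- sum(A & B) / sum(A | B)
  expect_lt(abs(J - 0.40), 0.01)
  expect_equal(sum(A), 1000)             # 10% of cells each
  # extremes
  ph0 <- plant_hotspot_surfaces(2, 0, g, seed = 4)
  expect_false(any(ph0$masks[[1]] & ph0$masks[[2]]))
  ph1 <- plant_hotspot_surfaces(2, 1, g, seed = 5)
  expect_identical(ph1$masks[[1]], ph1$masks[[2]])
  # elevated mean inside the hotspot
  expect_gt(mean(ph$surfaces[[1]]$values[A]),
            5 * mean(ph$surfaces[[1]]$values[!A]))
  # infeasible design errors, naming the pair
  expect_error(plant_hotspot_surfaces(12, 0, g, seed = 1, hot_frac = 0.1),
               "infeasible")
})

test_that("regions argument separates species spatially", {
  g <- grid_spec(0, 0, 1, 60, 60)
  ph <- plant_hotspot_surfaces(2, 0, g, seed = 6,
                               regions = list(c(0, 1, 0.5, 1),
                                              c(0, 1, 0, 0.5)))
  cc <- grid_centers(g)
  expect_true(all(cc$y[ph$masks[[1]]] >= 30))
  expect_true(all(cc$y[ph$masks[[2]]] < 30))
})
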