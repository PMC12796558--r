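grid_coords <- function(nx, ny, cell = 1) {
  g <- grid_spec(0, 0, cell, nx, ny)
  as.matrix(grid_centers(g)[, c("x", "y")])
}

rook_w <- function(nx, ny) {
  co <- grid_coords(nx, ny)
  D <- as.matrix(dist(co))
  (D > 0 & D <= 1.001) * 1
}

test_that("Moran's I: checkerboard closed form and permutation null", {
  # 2x2 rook checkerboard {+1,-1;-1,+1} -> I = -1 exactly
  x <- c(1, -1, -1, 1)
  m <- morans_i(x, rook_w(2, 2))
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expected, -1 / 3)

  # permutation null: mean I over permutations ~ -1/(N-1)
  set.seed(31)
  n <- 15 * 15
  W <- rook_w(15, 15)
  x <- rnorm(n)
  Is <- replicate(1000, morans_i(sample(x), W)$I)
  se <- sd(Is) / sqrt(length(Is))
  expect_lt(abs(mean(Is) - (-1 / (n - 1))), 3 * se)

  expect_error(morans_i(rep(2, 9), rook_w(3, 3)), "constant")
  expect_error(morans_i(c(1, 2), matrix(1, 2, 2)), "at least 3")
})

test_that("correlogram decays for a known-range field and picks a sane neighborhood", {
  g <- grid_spec(0, 0, 2, 30, 30)
  co <- as.matrix(grid_centers(g)[, c("x", "y")])
  hits <- 0
  for (r in 1:5) {
    f <- simulate_matern_grf(g, 30, 1, seed = 200 + r)
    cg <- correlogram(f$values, co, distance_bins = seq(5, 60, by = 5))
    nb <- suppressWarnings(choose_neighborhood(cg))
    if (nb >= 15 && nb <= 60) hits <- hits + 1
    # smooth long-range field: I nonincreasing over the first three bands
    expect_true(all(diff(cg$I[1:3]) <= 0.02))
  }
  expect_gte(hits, 4)

  # white noise: first band already non-significant
  set.seed(9)
  expect_warning(
    nb0 <- choose_neighborhood(correlogram(rnorm(900), co, seq(5, 40, 5))),
    "first band")
  expect_equal(nb0, 5)
})

test_that("gi_star matches the brute-force O(N^2) oracle", {
  set.seed(17)
  for (rep in 1:3) {
    co <- grid_coords(20, 20)
    x <- rnorm(400) + rep(seq(0, 2, length.out = 20), each = 20)
    z <- gi_star(x, co, neighborhood_km = 3.2)
    zo <- oracle_gi_star(x, co, 3.2)
    expect_lt(max(abs(z$z - zo)), 1e-10)
    # Gi (self excluded) variant agrees with its oracle too
    zg <- gi_star(x, co, 3.2, include_self = FALSE)
    zgo <- oracle_gi_star(x, co, 3.2, include_self = FALSE)
    expect_lt(max(abs(zg$z - zgo)), 1e-10)
  }
})

test_that("gi_star scale invariance and hotspot localization", {
  set.seed(23)
  co <- grid_coords(25, 25)
  x <- rexp(625)
  x[c(312, 313, 337, 338)] <- x[c(312, 313, 337, 338)] + 30  # planted block
  z1 <- gi_star(x, co, 2.5)
  z2 <- gi_star(x * 7.3, co, 2.5)
  expect_lt(max(abs(z1$z - z2$z)), 1e-10)
  # argmax Z lies within one neighborhood radius of the planted block center
  ctr <- colMeans(co[c(312, 313, 337, 338), ])
  am <- co[which.max(z1$z), ]
  expect_lte(sqrt(sum((am - ctr)^2)), 2.5)
  expect_error(gi_star(rep(1, 100), grid_coords(10, 10), 2), "distinct")
})

test_that("pooled standardization compares years on a common scale", {
  g <- grid_spec(0, 0, 1, 12, 12)
  set.seed(5)
  base <- rexp(144)
  # identical years -> identical Z
  st <- grid_stack(g, 1:3, cbind(base, base, base))
  zz <- pooled_gi_star_by_year(st, 2.5)
  expect_equal(zz[[1]]$z, zz[[3]]$z)
  # one anomalously hot year dominates the pooled maxima
  hot <- base; hot[40:43] <- hot[40:43] + 50
  st2 <- grid_stack(g, 1:2, cbind(base, hot))
  zz2 <- pooled_gi_star_by_year(st2, 2.5)
  expect_gt(max(zz2[[2]]$z), max(zz2[[1]]$z))
  # pooled differs from per-year standardization on unequal-variance years
  per_year <- gi_star(hot, as.matrix(grid_centers(g)[, c("x", "y")]), 2.5)
  expect_gt(max(abs(zz2[[2]]$z - per_year$z)), 0.01)
  # single year falls back with a warning
  expect_warning(pooled_gi_star_by_year(grid_stack(g, 1, cbind(base)), 2.5),
                 "single year")
})

test_that("hotspot mask arithmetic: counts, ties, area", {
  set.seed(3)
  z <- sample(rnorm(1000))  # distinct values
  m <- hotspot_mask(z, 0.90, cell_km = 3)
  expect_identical(sum(m), 100L)
  expect_equal(attr(m, "area_km2"), 100 * 9)
  # ceil(0.1 N) on assorted tie-free sizes
  for (n in c(10, 11, 21, 95, 473)) {
    zi <- sample(seq_len(n))
    expect_identical(sum(hotspot_mask(zi, 0.90)), as.integer(ceiling(0.1 * n)))
  }
  # monotone in the percentile
  expect_true(all(hotspot_mask(z, 0.95) <= hotspot_mask(z, 0.90)))
  # all-equal Z: everything ties at the threshold
  expect_warning(mt <- hotspot_mask(rep(1, 50), 0.90), "ties")
  expect_true(all(mt))
})

test_that("overlap percentage set arithmetic", {
  a <- c(rep(TRUE, 100), rep(FALSE, 100))
  expect_equal(overlap_percentage(a, a)$pct_overlap, 100)
  b <- rev(a)
  expect_equal(overlap_percentage(a, b)$pct_overlap, 0)
  # |A|=|B|=100, |AnB|=40 -> 100*40/160 = 25
  a2 <- c(rep(TRUE, 100), rep(FALSE, 120))
  b2 <- c(rep(FALSE, 60), rep(TRUE, 100), rep(FALSE, 60))
  ov <- overlap_percentage(a2, b2, cell_km = 1)
  expect_equal(ov$pct_overlap, 25)
  expect_equal(ov$area_both, 40)
  expect_equal(ov$area_a_only + ov$area_b_only + ov$area_both, 160)
  # symmetry; empty masks defined as 0 with warning
  expect_equal(overlap_percentage(b2, a2)$pct_overlap, 25)
  expect_warning(z <- overlap_percentage(logical(5), logical(5)), "empty")
  expect_equal(z$pct_overlap, 0)
  expect_error(overlap_percentage(a, b2), "co-registered")
})

test_that("co-occurrence percent counts species per cell", {
  masks <- lapply(1:8, function(i) c(TRUE, i <= 6, FALSE))
  co <- cooccurrence_percent(masks)
  expect_equal(co, c(100, 75, 0))
  # permutation invariance in species order
  expect_equal(cooccurrence_percent(rev(masks)), co)
  # unsurveyed cells missing
  surv <- lapply(1:8, function(i) c(TRUE, TRUE, i != 3))
  expect_true(is.na(cooccurrence_percent(masks, surv)[3]))
  expect_error(cooccurrence_percent(list()), "empty")
})

test_that("binned hotspot areas partition the total", {
  set.seed(12)
  g <- grid_spec(0, 5400, 5, 20, 60)   # northings 5400-5700 km
  cc <- grid_centers(g)
  for (i in 1:20) {
    m <- runif(1200) < 0.15
    tab <- binned_hotspot_area(m, cc$y, cell_km = 5)
    expect_equal(sum(tab$area_km2), sum(m) * 25)
  }
  # mask inside one bin concentrates there
  m1 <- cc$y >= 5510 & cc$y < 5580 & cc$x < 30
  tab1 <- binned_hotspot_area(m1, cc$y, cell_km = 5)
  expect_equal(sum(tab1$area_km2 > 0), 1)
  # two-mask variant: per-bin decomposition adds up
  m2 <- runif(1200) < 0.1
  tab2 <- binned_hotspot_area(m1, cc$y, 5, mask2 = m2)
  expect_equal(tab2$area_a_only + tab2$area_co,
               binned_hotspot_area(m1, cc$y, 5)$area_km2)
})
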