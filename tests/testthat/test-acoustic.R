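make_eg <- function(sv, dz = 1, depth0 = 0.5, dping = 0.0125, freq = 120) {
  echogram_grid(sv, depth0 + (seq_len(nrow(sv)) - 1) * dz,
                (seq_len(ncol(sv)) - 0.5) * dping, freq)
}

test_that("MVBS averages in the linear domain", {
  # constant field is a fixed point
  eg <- make_eg(matrix(-70, 20, 80))
  mv <- compute_mvbs(eg, window_pings = 40, window_depth_m = 10)
  expect_equal(dim(mv$sv_db), c(2, 2))
  expect_equal(as.numeric(mv$sv_db), rep(-70, 4), tolerance = 1e-12)

  # two-cell window {-60, -70}: linear mean, not dB mean
  eg2 <- make_eg(matrix(c(-60, -70), 2, 1), dz = 5)
  mv2 <- compute_mvbs(eg2, window_pings = 1, window_depth_m = 10)
  expect_equal(as.numeric(mv2$sv_db), 10 * log10((1e-6 + 1e-7) / 2),
               tolerance = 1e-12)
  expect_gt(as.numeric(mv2$sv_db), -65)  # linear mean > dB-domain mean

  # partial trailing windows are kept, averaged over available samples
  eg3 <- make_eg(matrix(-60, 15, 50))
  mv3 <- compute_mvbs(eg3, window_pings = 40, window_depth_m = 10)
  expect_equal(dim(mv3$sv_db), c(2, 2))
  expect_equal(as.numeric(mv3$sv_db), rep(-60, 4), tolerance = 1e-12)

  # all-missing window stays missing
  svna <- matrix(-70, 10, 40); svna[1:10, 1:40] <- NA
  expect_true(is.na(compute_mvbs(make_eg(svna), 40, 10)$sv_db[1, 1]))
})

test_that("dB-difference window is closed and handles missing data", {
  base <- matrix(-80, 3, 3)
  for (d in c(10.0, 12.0, 16.3)) {
    m <- db_difference_classify(make_eg(base + d), make_eg(base, freq = 38))
    expect_true(all(m))
  }
  for (d in c(9.999, 16.301, 20)) {
    m <- db_difference_classify(make_eg(base + d), make_eg(base, freq = 38))
    expect_false(any(m))
  }
  withna <- base + 12; withna[1, 1] <- NA
  m <- db_difference_classify(make_eg(withna), make_eg(base, freq = 38))
  expect_false(m[1, 1]); expect_true(all(m[-1]))
  expect_error(db_difference_classify(make_eg(base), make_eg(base[1:2, ], freq = 38)),
               "co-registered")
})

test_that("NASC closed form, masking, and vertical-regrid invariance", {
  # constant Sv = -70 over a fully masked 100-m window:
  # NASC = 4 pi 1852^2 * 1e-7 * 100
  sv <- matrix(-70, 100, 40)   # 1-m cells, 0-100 m
  eg <- make_eg(sv)
  rec <- echo_integrate_nasc(eg, depth_min_m = 0, depth_max_m = 1000,
                             bin_nmi = 0.5)
  expected <- 4 * pi * 1852^2 * 1e-7 * 100
  expect_equal(rec$nasc, expected, tolerance = 1e-9)

  # all cells unmasked -> every bin 0 (valid absence)
  rec0 <- echo_integrate_nasc(eg, mask = matrix(FALSE, 100, 40),
                              depth_min_m = 0, depth_max_m = 1000)
  expect_identical(rec0$nasc, 0)

  # halving the vertical resolution leaves NASC unchanged
  sv2 <- matrix(-70, 50, 40)
  eg2 <- make_eg(sv2, dz = 2, depth0 = 1)
  rec2 <- echo_integrate_nasc(eg2, depth_min_m = 0, depth_max_m = 1000)
  expect_equal(rec2$nasc, rec$nasc, tolerance = 1e-9)

  # +3.0103 dB everywhere doubles NASC (linearity in 10^(Sv/10))
  rec3 <- echo_integrate_nasc(make_eg(sv + 10 * log10(2)),
                              depth_min_m = 0, depth_max_m = 1000)
  expect_equal(rec3$nasc / rec$nasc, 2, tolerance = 1e-6)

  # empty echogram -> empty record list
  emp <- echo_integrate_nasc(make_eg(matrix(numeric(0), 5, 0)),
                             depth_min_m = 0, depth_max_m = 100)
  expect_identical(nrow(emp), 0L)
})

test_that("round trip: planted echogram -> classify -> integrate", {
  # krill planted in half the pings; noise-free classification recovers the
  # mask exactly, and only krill bins carry NASC
  mask <- matrix(FALSE, 10, 80)
  mask[, 1:40] <- TRUE
  eg <- simulate_dual_frequency_echogram(mask, 13.15, noise_sd = 0, seed = 1,
                                         along_step_nmi = 0.025)
  cl <- db_difference_classify(eg$sv120, eg$sv38)
  expect_identical(cl, mask)  # recall = precision = 1
  rec <- echo_integrate_nasc(eg$sv120, cl, depth_min_m = 0,
                             depth_max_m = Inf, bin_nmi = 0.5)
  expect_true(all(rec$nasc[rec$bin_index < 2] > 0))
  expect_true(all(rec$nasc[rec$bin_index >= 2] == 0))
})

test_that("echogram text format round-trips", {
  sv <- matrix(rnorm(60, -70, 3), 6, 10)
  eg <- make_eg(sv)
  p <- tempfile(fileext = ".tsv")
  write_echogram(eg, p)
  back <- read_echogram(p)
  expect_equal(back$sv_db, unname(eg$sv_db), tolerance = 1e-9)
  expect_equal(back$depth_m, eg$depth_m)
  expect_equal(back$frequency_khz, 120)
})
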