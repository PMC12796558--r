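#' Simulation configuration for the synthetic survey world
#'
#' Collects every knob of the synthetic world in one validated object:
#' the projected grid, the survey years, the Matérn/AR1 latent-field
#' parameters and the Tweedie observation parameters. A single master
#' `seed` spawns fixed per-component substreams so each generator is a
#' pure function of (config, seed).
#'
#' @param grid_extent numeric `c(x_min, x_max, y_min, y_max)` in km;
#'   `cell_km` must divide both extents.
#' @param cell_km cell side length (km), default 3 as in the covariate grid.
#' @param years ordered integer years.
#' @param matern_range_km effective range of the latent fields (km).
#' @param sigma_spatial marginal SD of the time-invariant field.
#' @param sigma_st marginal SD of the AR1 spatiotemporal fields.
#' @param rho_ar1 AR1 year-to-year correlation, |rho| < 1.
#' @param tweedie_p Tweedie power, strictly in (1, 2).
#' @param tweedie_phi Tweedie dispersion, > 0.
#' @param seed master integer seed.
#' @export
sim_config <- function(grid_extent = c(0, 120, 0, 120), cell_km = 3,
                       years = 2007:2018, matern_range_km = 30,
                       sigma_spatial = 0.8, sigma_st = 0.8, rho_ar1 = 0.5,
                       tweedie_p = 1.5, tweedie_phi = 1.2, seed = 1) {
  stopifnot(length(grid_extent) == 4)
  ex <- grid_extent[2] - grid_extent[1]; ey <- grid_extent[4] - grid_extent[3]
  if (ex <= 0 || ey <= 0) stop("grid extent must be nonempty")
  if (abs(ex / cell_km - round(ex / cell_km)) > 1e-9 ||
      abs(ey / cell_km - round(ey / cell_km)) > 1e-9)
    stop("cell_km must divide both extent dimensions")
  if (tweedie_p <= 1 || tweedie_p >= 2) stop("tweedie_p must be in (1, 2)")
  if (tweedie_phi <= 0) stop("tweedie_phi must be positive")
  if (abs(rho_ar1) >= 1) stop("|rho_ar1| must be < 1")
  if (sigma_spatial < 0 || sigma_st < 0) stop("field SDs must be nonnegative")
  grid <- grid_spec(grid_extent[1], grid_extent[3], cell_km,
                    round(ex / cell_km), round(ey / cell_km))
  structure(list(grid = grid, years = as.integer(years),
                 matern_range_km = matern_range_km,
                 sigma_spatial = sigma_spatial, sigma_st = sigma_st,
                 rho_ar1 = rho_ar1, tweedie_p = tweedie_p,
                 tweedie_phi = tweedie_phi, seed = as.integer(seed)),
            class = "sim_config")
}

# fixed substream offsets off the master seed (kept < 2^31)
.sub_seed <- function(seed, component) {
  offs <- c(spatial = 101L, st = 211L, survey = 307L, echo = 401L,
            hotspot = 503L, covariate = 601L, layout = 701L)
  (as.integer(seed) + offs[[component]]) %% .Machine$integer.max
}

#' Parallel-transect survey layout of 0.5-nmi bins
#'
#' East-west transect lines with configurable north-south spacing, sampled
#' at 0.5-nautical-mile bins (0.926 km), mimicking coastwide acoustic
#' survey designs. Arbitrary layouts can be supplied anywhere a layout is
#' accepted as a data.frame with `x`, `y` columns.
#'
#' @param grid a [grid_spec()] giving the extent to cover.
#' @param spacing_km distance between transect lines (km).
#' @param bin_nmi along-track bin length in nautical miles (default 0.5).
#' @return data.frame with `transect`, `bin`, `x`, `y` (bin midpoints, km).
#' @export
transect_layout <- function(grid, spacing_km = 10, bin_nmi = 0.5) {
  stopifnot(inherits(grid, "grid_spec"))
  bin_km <- bin_nmi * 1.852
  ys <- seq(grid$y0 + spacing_km / 2, grid$y0 + grid$ny * grid$cell_km,
            by = spacing_km)
  xs <- seq(grid$x0 + bin_km / 2, grid$x0 + grid$nx * grid$cell_km - bin_km / 2,
            by = bin_km)
  out <- expand.grid(x = xs, y = ys)
  out$transect <- match(out$y, ys)
  out$bin <- stats::ave(out$x, out$transect, FUN = seq_along)
  out[, c("transect", "bin", "x", "y")]
}

#' Simulate a Tweedie-sampled acoustic survey over a truth surface
#'
#' Draws one observation per in-grid transect bin with
#' `y ~ Tweedie(mu, p, phi)` where `mu` is the (strictly positive,
#' response-scale) truth surface at the bin's containing cell. Bins
#' falling outside the grid are dropped with a message reporting the count.
#'
#' @param truth a [grid_field()] (single layer, recorded as year 0) or
#'   [grid_stack()] of positive mean surfaces.
#' @param transects layout data.frame with `x`, `y` (e.g.
#'   [transect_layout()]); each bin is visited in every truth year.
#' @param p,phi Tweedie power and dispersion.
#' @param seed integer seed.
#' @return data.frame (`ObservationTable`) with `x_km`, `y_km`, `year`,
#'   `nasc`, `bin_index`.
#' @export
simulate_survey <- function(truth, transects, p, phi, seed) {
  if (inherits(truth, "grid_field"))
    truth <- grid_stack(truth$spec, 0L, matrix(truth$values, ncol = 1))
  stopifnot(inherits(truth, "grid_stack"))
  cell <- point_to_cell(truth$spec, transects$x, transects$y)
  drop <- is.na(cell)
  if (any(drop))
    message(sum(drop), " bins outside the grid extent were dropped")
  keep <- which(!drop)
  mu_all <- truth$values[cell[keep], , drop = FALSE]
  if (any(!is.finite(mu_all)) || any(mu_all <= 0))
    stop("truth must be strictly positive on the response scale")
  withr_seed(seed, {
    do.call(rbind, lapply(seq_along(truth$years), function(j) {
      data.frame(x_km = transects$x[keep], y_km = transects$y[keep],
                 year = truth$years[j],
                 nasc = rtweedie(length(keep), mu_all[, j], p, phi),
                 bin_index = keep)
    }))
  })
}

#' Simulate a dual-frequency echogram pair with planted krill cells
#'
#' Builds co-registered 38 and 120 kHz Sv grids (already at the MVBS cell
#' resolution) in which planted cells have
#' `MVBS120 - MVBS38 = db_diff_target + N(0, noise_sd)` and background
#' cells have a difference outside the classification window.
#'
#' @param krill_mask logical matrix (depth cells x along-track cells);
#'   `TRUE` marks planted krill cells. An empty (all-FALSE) mask is allowed.
#' @param db_diff_target target dB difference for planted cells; should lie
#'   inside the classification window.
#' @param noise_sd Gaussian SD added to the planted difference (dB).
#' @param seed integer seed.
#' @param sv38_db background 38 kHz Sv level (dB).
#' @param background_diff_db dB difference of non-krill cells (must be
#'   outside the window; default 2 dB, weak-scatterer-like).
#' @param depth0_m,depth_step_m depth of the first cell center and vertical
#'   cell size (m).
#' @param along_step_nmi along-track cell size (nmi).
#' @return list with elements `sv38`, `sv120` (both [echogram_grid()]) and
#'   `mask` (the planted mask).
#' @export
simulate_dual_frequency_echogram <- function(krill_mask, db_diff_target = 13.15,
                                             noise_sd = 0, seed = 1,
                                             sv38_db = -80,
                                             background_diff_db = 2,
                                             depth0_m = 55, depth_step_m = 10,
                                             along_step_nmi = 0.05) {
  krill_mask <- as.matrix(krill_mask)
  nr <- nrow(krill_mask); np <- ncol(krill_mask)
  depth <- depth0_m + (seq_len(nr) - 1) * depth_step_m
  along <- (seq_len(np) - 0.5) * along_step_nmi
  sv38 <- matrix(sv38_db, nr, np)
  diffs <- matrix(background_diff_db, nr, np)
  if (any(krill_mask)) {
    noise <- withr_seed(.sub_seed(seed, "echo"),
                        stats::rnorm(sum(krill_mask), 0, noise_sd))
    diffs[krill_mask] <- db_diff_target + noise
    sv38[krill_mask] <- sv38_db + 10  # krill scatter above background at 38
  }
  list(sv38 = echogram_grid(sv38, depth, along, 38),
       sv120 = echogram_grid(sv38 + diffs, depth, along, 120),
       mask = krill_mask)
}

#' Plant multi-species biomass surfaces with hotspots of known overlap
#'
#' Constructs one mean biomass surface per species with an elevated mean
#' inside a designed hotspot footprint occupying `hot_frac` of the grid, so
#' that the pairwise Jaccard overlap `|A n B| / |A u B|` of the true masks
#' matches `overlap` to within one cell. Two designs are constructible:
#' a scalar `overlap` shared by all pairs (any number of species, via a
#' shared core), or a full pairwise matrix for exactly two species.
#'
#' @param n_species number of species surfaces.
#' @param overlap target Jaccard intersection-over-union in `[0, 1]`;
#'   scalar, or a symmetric `n_species x n_species` matrix (2 species only).
#' @param grid a [grid_spec()].
#' @param seed integer seed (controls placement and surface texture).
#' @param hot_frac fraction of grid cells in each species' hotspot
#'   (default 0.10, matching the 90th-percentile hotspot rule downstream).
#' @param mu_background,mu_hot response-scale means outside/inside hotspots.
#' @param noise_sd SD of multiplicative log-normal texture on the surface.
#' @param regions optional list (one element per species) of
#'   `c(xmin, xmax, ymin, ymax)` fractions of the extent constraining where
#'   that species' non-shared hotspot cells are placed (e.g. north vs south).
#' @return list with `surfaces` (list of [grid_field()]) and `masks`
#'   (list of logical vectors, the true hotspot masks).
#' @export
plant_hotspot_surfaces <- function(n_species, overlap, grid, seed,
                                   hot_frac = 0.10, mu_background = 1,
                                   mu_hot = 20, noise_sd = 0.2,
                                   regions = NULL) {
  stopifnot(inherits(grid, "grid_spec"), n_species >= 1)
  n <- n_cells(grid)
  K <- max(1L, round(hot_frac * n))
  if (is.matrix(overlap)) {
    if (n_species != 2)
      stop("pairwise overlap matrices are only constructible for 2 species; ",
           "use a scalar design for more")
    J <- overlap[1, 2]
  } else J <- overlap[1]
  if (J < 0 || J > 1) stop("overlap must be in [0, 1]")
  # shared core size c so that pairwise |AnB|/|AuB| = c/(2K - c) = J
  core <- round(2 * K * J / (1 + J))
  need <- core + n_species * (K - core)
  if (need > n)
    stop(sprintf("infeasible design for pair (1, 2): %d cells needed, %d available",
                 need, n))
  cc <- grid_centers(grid)
  region_cells <- function(i) {
    if (is.null(regions)) return(seq_len(n))
    r <- regions[[i]]
    ex <- grid$nx * grid$cell_km; ey <- grid$ny * grid$cell_km
    which(cc$x >= grid$x0 + r[1] * ex & cc$x < grid$x0 + r[2] * ex &
          cc$y >= grid$y0 + r[3] * ey & cc$y < grid$y0 + r[4] * ey)
  }
  # species' non-shared blocks must stay well separated, or downstream
  # model smoothing + Gi* neighborhoods merge adjacent hotspots: carve the
  # grid into vertical strips, one per block (core first when present)
  n_zone <- n_species + (core > 0)
  zone_of <- pmin(floor((cc$col - 1) / (grid$nx / n_zone)) + 1, n_zone)
  # compact blob of m cells nearest the zone's centroid
  grow_block <- function(m, admissible, who) {
    if (length(admissible) < m)
      stop(sprintf("infeasible design for pair (1, %s): region too small", who))
    ctr <- c(mean(cc$col[admissible]), mean(cc$row[admissible]))
    d2 <- (cc$col[admissible] - ctr[1])^2 + (cc$row[admissible] - ctr[2])^2
    admissible[order(d2)][seq_len(m)]
  }
  masks <- vector("list", n_species)
  if (core > 0) {
    core_adm <- Reduce(intersect, c(list(which(zone_of == 1)),
                                    lapply(seq_len(n_species), region_cells)))
    if (length(core_adm) < core)
      stop("infeasible design for pair (1, 2): shared-core region too small")
    core_cells <- grow_block(core, core_adm, "2")
  } else core_cells <- integer(0)
  for (i in seq_len(n_species)) {
    own_adm <- intersect(which(zone_of == i + (core > 0)), region_cells(i))
    own <- grow_block(K - core, setdiff(own_adm, core_cells), as.character(i))
    m <- logical(n); m[c(core_cells, own)] <- TRUE
    masks[[i]] <- m
  }
  surfaces <- lapply(seq_len(n_species), function(i) {
    tex <- withr_seed(.sub_seed(seed, "hotspot") + i,
                      stats::rnorm(n, 0, noise_sd))
    mu <- ifelse(masks[[i]], mu_hot, mu_background) * exp(tex)
    grid_field(grid, mu)
  })
  list(surfaces = surfaces, masks = masks)
}

#' Simulate smooth environmental covariate layers
#'
#' Matérn fields optionally correlated with a supplied latent truth field,
#' standing in for ocean-model covariates (temperature-, stratification-,
#' production-like layers).
#'
#' @param grid a [grid_spec()].
#' @param names character vector of covariate names.
#' @param range_km Matérn effective range (km).
#' @param seed integer seed.
#' @param truth optional [grid_field()]; when supplied, each covariate is
#'   `cor_truth * scale(truth) + sqrt(1 - cor_truth^2) * noise`.
#' @param cor_truth correlation with the latent truth, recycled over names.
#' @return named list of [grid_field()] layers.
#' @export
simulate_covariates <- function(grid, names, range_km = 40, seed = 1,
                                truth = NULL, cor_truth = 0) {
  cor_truth <- rep_len(cor_truth, length(names))
  out <- lapply(seq_along(names), function(i) {
    f <- simulate_matern_grf(grid, range_km, 1,
                             .sub_seed(seed, "covariate") + i)
    if (!is.null(truth) && cor_truth[i] != 0) {
      z <- as.numeric(scale(truth$values))
      f$values <- cor_truth[i] * z + sqrt(1 - cor_truth[i]^2) * f$values
    }
    f
  })
  stats::setNames(out, names)
}
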