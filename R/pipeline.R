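#' Regrid a field to a coarser grid by area-weighted means
#'
#' Each coarse cell receives the mean of the fine-cell values it
#' contains, area-weighted when fine cells straddle coarse boundaries
#' (the grids need not be nested). Missing fine cells are excluded; a
#' coarse cell whose overlap is entirely missing stays missing. The
#' valid-area-weighted mean of the field is conserved exactly.
#'
#' @param fine a [grid_field()].
#' @param coarse a [grid_spec()] with `cell_km` >= the fine cell size.
#' @return a [grid_field()] on `coarse`.
#' @export
regrid_mean <- function(fine, coarse) {
  stopifnot(inherits(fine, "grid_field"), inherits(coarse, "grid_spec"))
  fs <- fine$spec
  if (coarse$cell_km < fs$cell_km)
    stop("coarse cell size must be >= fine cell size")
  # 1-D overlap-length matrices along each axis
  ov <- function(f0, fc, nf, c0, cc, nc) {
    flo <- f0 + (seq_len(nf) - 1) * fc; fhi <- flo + fc
    clo <- c0 + (seq_len(nc) - 1) * cc; chi <- clo + cc
    m <- outer(fhi, chi, pmin) - outer(flo, clo, pmax)
    pmax(m, 0)
  }
  Ox <- ov(fs$x0, fs$cell_km, fs$nx, coarse$x0, coarse$cell_km, coarse$nx)
  Oy <- ov(fs$y0, fs$cell_km, fs$ny, coarse$y0, coarse$cell_km, coarse$ny)
  if (sum(Ox) == 0 || sum(Oy) == 0) stop("grids do not overlap")
  V <- matrix(fine$values, fs$nx, fs$ny)         # [col, row] layout
  valid <- !is.na(V)
  V0 <- ifelse(valid, V, 0)
  num <- t(Ox) %*% V0 %*% Oy                      # [coarse_x, coarse_y]
  den <- t(Ox) %*% (valid * 1) %*% Oy
  out <- ifelse(den > 0, num / den, NA_real_)
  grid_field(coarse, as.numeric(out))
}

#' Cell-wise mean of a stack across years
#'
#' @param stack a [grid_stack()].
#' @param years_subset years to average (must be a subset of the stack's
#'   years); defaults to all.
#' @return a [grid_field()]; per cell, years with missing values are
#'   excluded.
#' @export
mean_across_years <- function(stack, years_subset = NULL) {
  stopifnot(inherits(stack, "grid_stack"))
  if (is.null(years_subset)) years_subset <- stack$years
  if (!length(years_subset)) stop("empty year subset")
  if (!all(years_subset %in% stack$years))
    stop("years_subset must be a subset of the stack years")
  cols <- match(years_subset, stack$years)
  m <- rowMeans(stack$values[, cols, drop = FALSE], na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  grid_field(stack$spec, m)
}

#' Truncate datasets to their common years and surveyed cells
#'
#' Temporal truncation keeps the years of the dataset with the fewest
#' years (intersected with every other dataset's years — e.g. a
#' 2007-2018 series compared against a single-year survey keeps only
#' that year); spatial truncation masks cells not surveyed (non-missing)
#' in all datasets. Both are applied before any averaging. Idempotent.
#'
#' @param stacks list of [grid_stack()]s on a common [grid_spec()].
#' @return list of truncated, aligned [grid_stack()]s.
#' @export
truncate_to_common <- function(stacks) {
  if (length(stacks) < 2) stop("need at least 2 datasets")
  for (s in stacks) stopifnot(inherits(s, "grid_stack"))
  spec <- stacks[[1]]$spec
  for (s in stacks[-1]) if (!same_grid(spec, s$spec))
    stop("datasets are not on a common grid; regrid first")
  years <- Reduce(intersect, lapply(stacks, function(s) s$years))
  if (!length(years)) stop("empty temporal intersection")
  surveyed <- Reduce(`&`, lapply(stacks, function(s)
    rowSums(!is.na(s$values)) > 0))
  if (!any(surveyed)) stop("empty spatial intersection")
  lapply(stacks, function(s) {
    v <- s$values[, match(years, s$years), drop = FALSE]
    v[!surveyed, ] <- NA_real_
    grid_stack(spec, years, v)
  })
}

#' Attach gridded covariates to an observation table
#'
#' Each observation gains the covariate values of its containing cell
#' (half-open cell convention shared with the whole package) for its
#' year; out-of-extent observations are dropped with a logged count.
#'
#' @param stacks named list of covariate layers ([grid_field()] for
#'   static, [grid_stack()] for yearly layers); names may carry a month
#'   tag, e.g. `sst_may`.
#' @param obs observation data.frame with `x_km`, `y_km`, `year`.
#' @param month_tag optional tag: only layers whose name ends in
#'   `_<month_tag>` are attached (an error names the tag when none match).
#' @return `obs` augmented with one column per attached layer.
#' @export
extract_covariates_at_obs <- function(stacks, obs, month_tag = NULL) {
  if (!is.null(month_tag)) {
    sel <- grepl(paste0("_", month_tag, "$"), names(stacks))
    if (!any(sel)) stop("no covariate layer with month tag: ", month_tag)
    stacks <- stacks[sel]
  }
  spec <- if (inherits(stacks[[1]], "grid_stack")) stacks[[1]]$spec
          else stacks[[1]]$spec
  cell <- point_to_cell(spec, obs$x_km, obs$y_km)
  drop <- is.na(cell)
  if (any(drop))
    message(sum(drop), " observations outside the grid extent were dropped")
  obs <- obs[!drop, , drop = FALSE]
  cell <- cell[!drop]
  for (nm in names(stacks)) {
    lay <- stacks[[nm]]
    if (inherits(lay, "grid_stack")) {
      j <- match(obs$year, lay$years)
      if (anyNA(j)) stop("covariate layer '", nm, "' missing years: ",
                         paste(unique(obs$year[is.na(j)]), collapse = ", "))
      obs[[nm]] <- lay$values[cbind(cell, j)]
    } else {
      obs[[nm]] <- lay$values[cell]
    }
  }
  obs
}

#' Stratification proxy: density difference between 50 m and the surface
#'
#' @param density_50m,density_surface co-registered [grid_field()]s
#'   (kg m^-3).
#' @return [grid_field()] of `density_50m - density_surface`; negative
#'   values (unstable column) pass through.
#' @export
derive_stratification <- function(density_50m, density_surface) {
  stopifnot(inherits(density_50m, "grid_field"),
            inherits(density_surface, "grid_field"))
  if (!same_grid(density_50m$spec, density_surface$spec))
    stop("fields are not co-registered")
  grid_field(density_50m$spec, density_50m$values - density_surface$values)
}

#' Write / read an observation table as headered delimited text
#'
#' @param obs observation data.frame (`x_km`, `y_km`, `year`, `nasc`,
#'   covariate columns).
#' @param path file path.
#' @export
write_obs_table <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_obs_table
#' @export
read_obs_table <- function(path) utils::read.csv(path)

# -- end-to-end orchestration ------------------------------------------------

.default_config <- function() {
  list(
    seed = 1,
    grid = list(extent = c(0, 90, 0, 90), cell_km = 3),
    species = list(n = 2, overlap = 0.4, hot_frac = 0.10,
                   mu_background = 1, mu_hot = 20, regions = NULL),
    survey = list(transect_spacing_km = 6, tweedie_p = 1.5, tweedie_phi = 1.2),
    fit = list(n_knots = 40, year = 2018),
    hotspots = list(percentile = 0.90, neighborhood_km = NULL,
                    correlogram_bins_km = NULL),
    rda = list(n_covariates = 3)
  )
}

#' Run the full synthetic-survey pipeline
#'
#' Orchestrates simulate -> survey -> fit -> predict -> Gi* hotspots ->
#' overlap / co-occurrence / binned areas -> RDA on a self-contained
#' synthetic world, writing every intermediate product, a structured log
#' and an md5 manifest to `out_dir`. Fully reproducible from config +
#' seed. Any stage failure aborts with a stage-tagged error; partial
#' outputs are retained.
#'
#' @param config a config list or path to a JSON config file; omitted
#'   entries take the defaults of the bundled demo configuration.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory artifacts (fits,
#'   masks, overlap report, RDA result) and the manifest path.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("krillscape_")) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(.default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  logline <- function(stage, msg)
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
        file = logf, append = TRUE)
  stage <- function(name, expr) {
    logline(name, "start")
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logline(name, "done")
    out
  }
  written <- character(0)
  put <- function(obj, name, writer) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    written <<- c(written, p)
    p
  }

  world <- stage("simulate", {
    ex <- cfg$grid$extent
    grid <- grid_spec(ex[1], ex[3], cfg$grid$cell_km,
                      round((ex[2] - ex[1]) / cfg$grid$cell_km),
                      round((ex[4] - ex[3]) / cfg$grid$cell_km))
    sp <- cfg$species
    planted <- plant_hotspot_surfaces(sp$n, sp$overlap, grid,
                                      seed = cfg$seed, hot_frac = sp$hot_frac,
                                      mu_background = sp$mu_background,
                                      mu_hot = sp$mu_hot, regions = sp$regions)
    covs <- simulate_covariates(grid, paste0("env", seq_len(cfg$rda$n_covariates)),
                                seed = cfg$seed,
                                truth = planted$surfaces[[1]],
                                cor_truth = c(0.7, rep(0, cfg$rda$n_covariates - 1)))
    logline("simulate", sprintf("grid %dx%d, %d species", grid$nx, grid$ny, sp$n))
    list(grid = grid, planted = planted, covs = covs)
  })
  for (i in seq_along(world$planted$surfaces))
    put(grid_stack(world$grid, cfg$fit$year,
                   matrix(world$planted$surfaces[[i]]$values, ncol = 1)),
        sprintf("truth_species%d.tsv", i), write_grid_stack)

  surveys <- stage("survey", {
    tl <- transect_layout(world$grid, cfg$survey$transect_spacing_km)
    lapply(seq_along(world$planted$surfaces), function(i) {
      tr <- world$planted$surfaces[[i]]
      tr_stack <- grid_stack(world$grid, cfg$fit$year,
                             matrix(tr$values, ncol = 1))
      ob <- simulate_survey(tr_stack, tl, cfg$survey$tweedie_p,
                            cfg$survey$tweedie_phi,
                            seed = cfg$seed + 17 * i)
      logline("survey", sprintf("species %d: %d records, %.1f%% zeros",
                                i, nrow(ob), 100 * mean(ob$nasc == 0)))
      ob
    })
  })
  for (i in seq_along(surveys))
    put(surveys[[i]], sprintf("obs_species%d.csv", i), write_obs_table)

  fits <- stage("fit", {
    lapply(seq_along(surveys), function(i) {
      fit <- fit_sdm(surveys[[i]],
                     sdm_spec(spatial_field = TRUE, st_ar1 = FALSE,
                              n_knots = cfg$fit$n_knots,
                              name = sprintf("species%d", i)),
                     control = list(hessian = FALSE))
      logline("fit", sprintf("species %d: logLik %.1f, range %.1f km",
                             i, fit$loglik, fit$range_km))
      fit
    })
  })

  preds <- stage("predict", {
    lapply(fits, function(f) predict_grid(f, world$grid, cfg$fit$year))
  })
  for (i in seq_along(preds))
    put(preds[[i]]$response, sprintf("pred_species%d.tsv", i), write_grid_stack)

  hot <- stage("hotspots", {
    cc <- grid_centers(world$grid)
    nb <- cfg$hotspots$neighborhood_km
    if (is.null(nb)) {
      bins <- cfg$hotspots$correlogram_bins_km
      if (is.null(bins))
        bins <- seq(world$grid$cell_km * 2, world$grid$cell_km * 12,
                    by = world$grid$cell_km * 2)
      cg <- correlogram(preds[[1]]$link$values[, 1], cc[, c("x", "y")], bins)
      nb <- suppressWarnings(choose_neighborhood(cg))
      logline("hotspots", sprintf("correlogram neighborhood: %.1f km", nb))
    }
    zf <- lapply(preds, function(p)
      gi_star(p$response$values[, 1], cc[, c("x", "y")], nb))
    masks <- lapply(zf, hotspot_mask, percentile = cfg$hotspots$percentile,
                    cell_km = world$grid$cell_km)
    list(z = zf, masks = masks, neighborhood_km = nb)
  })
  for (i in seq_along(hot$masks)) {
    mk <- data.frame(cell = which(hot$masks[[i]]))
    put(mk, sprintf("hotspot_species%d.csv", i),
        function(o, p) utils::write.csv(o, p, row.names = FALSE))
  }

  report <- stage("overlap", {
    cc <- grid_centers(world$grid)
    ov <- overlap_percentage(hot$masks[[1]], hot$masks[[2]],
                             cell_km = world$grid$cell_km)
    co <- cooccurrence_percent(hot$masks)
    bins <- binned_hotspot_area(hot$masks[[1]], cc$y, world$grid$cell_km,
                                mask2 = hot$masks[[2]])
    logline("overlap", sprintf("pct_overlap = %.1f", ov$pct_overlap))
    list(overlap = ov, cooccurrence = co, binned = bins)
  })
  put(report$binned, "binned_areas.csv",
      function(o, p) utils::write.csv(o, p, row.names = FALSE))

  rda <- stage("rda", {
    Y <- do.call(cbind, lapply(hot$z, function(z) z$z))
    colnames(Y) <- sprintf("species%d", seq_len(ncol(Y)))
    X <- do.call(cbind, lapply(world$covs, function(f) f$values))
    ok <- stats::complete.cases(Y) & stats::complete.cases(X)
    rda_fit(Y[ok, , drop = FALSE], X[ok, , drop = FALSE])
  })
  put(as.data.frame(rda$species_scores), "rda_species_scores.csv",
      function(o, p) utils::write.csv(o, p, row.names = TRUE))

  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    files = lapply(stats::setNames(written, basename(written)),
                   function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fits = fits, hotspots = hot, report = report, rda = rda,
                 out_dir = out_dir,
                 manifest = file.path(out_dir, "manifest.json")))
}

# -- command-line interface --------------------------------------------------

.cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      vals <- character(0)
      while (i < length(args) && !startsWith(args[i + 1], "--")) {
        vals <- c(vals, args[i + 1]); i <- i + 1
      }
      out[[key]] <- if (length(vals)) vals else TRUE
    }
    i <- i + 1
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `preprocess`, `hotspots`,
#' `overlap`, `cooccur`, `rda` and `run`. Designed to be called from an
#' `Rscript` wrapper (see `inst/cli/krillscape`); returns the exit code
#' (0 ok, 2 config/usage error, 3 stage failure) rather than quitting.
#'
#' @param args character vector of arguments, e.g.
#'   `c("overlap", "--a", "a.csv", "--b", "b.csv")`.
#' @export
krillscape_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: krillscape <command> [--options]",
    "  simulate   --config cfg.json --out dir/",
    "  preprocess --sv38 f1.tsv --sv120 f2.tsv [--low 10.0 --high 16.3]",
    "             [--depth 50 300] [--bin 0.5] --out nasc.csv",
    "  run        --config cfg.json --out dir/",
    "  overlap    --a maskA.csv --b maskB.csv [--cell 3]",
    "  cooccur    --masks m1.csv m2.csv ... --out co.csv",
    "  rda        --y z.csv --x env.csv --out scores.csv", sep = "\n")
  if (!length(args)) { message(usage); return(2L) }
  cmd <- args[1]
  opt <- .cli_args(args[-1])
  read_mask <- function(p) {
    df <- utils::read.csv(p)
    df[[1]]
  }
  code <- tryCatch({
    switch(cmd,
      simulate = , run = {
        if (is.null(opt$config) || is.null(opt$out)) { message(usage); return(2L) }
        run_pipeline(opt$config, opt$out)
        0L
      },
      preprocess = {
        if (is.null(opt$sv38) || is.null(opt$sv120) || is.null(opt$out)) {
          message(usage); return(2L)
        }
        sv38 <- read_echogram(opt$sv38); sv120 <- read_echogram(opt$sv120)
        lo <- if (is.null(opt$low)) 10.0 else as.numeric(opt$low)
        hi <- if (is.null(opt$high)) 16.3 else as.numeric(opt$high)
        dp <- if (is.null(opt$depth)) c(50, 300) else as.numeric(opt$depth)
        bin <- if (is.null(opt$bin)) 0.5 else as.numeric(opt$bin)
        mask <- db_difference_classify(sv120, sv38, lo, hi)
        rec <- echo_integrate_nasc(sv120, mask, dp[1], dp[2], bin)
        write_obs_table(rec, opt$out)
        0L
      },
      overlap = {
        if (is.null(opt$a) || is.null(opt$b)) { message(usage); return(2L) }
        cell <- if (is.null(opt$cell)) 1 else as.numeric(opt$cell)
        ov <- overlap_percentage(read_mask(opt$a), read_mask(opt$b), cell)
        cat(jsonlite::toJSON(ov, auto_unbox = TRUE, digits = NA), "\n")
        0L
      },
      cooccur = {
        if (is.null(opt$masks) || is.null(opt$out)) { message(usage); return(2L) }
        masks <- lapply(opt$masks, read_mask)
        co <- cooccurrence_percent(masks)
        utils::write.csv(data.frame(cell = seq_along(co), pct = co),
                         opt$out, row.names = FALSE)
        0L
      },
      rda = {
        if (is.null(opt$y) || is.null(opt$x) || is.null(opt$out)) {
          message(usage); return(2L)
        }
        res <- rda_fit(as.matrix(utils::read.csv(opt$y)),
                       as.matrix(utils::read.csv(opt$x)))
        utils::write.csv(as.data.frame(res$species_scores), opt$out)
        0L
      },
      { message("unknown command: ", cmd); message(usage); 2L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 3L })
  code
}
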