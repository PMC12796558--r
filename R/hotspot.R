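#' Global Moran's I
#'
#' Spatial autocorrelation statistic
#' \deqn{I = \frac{N}{\sum_{ij} w_{ij}} \cdot
#'   \frac{\sum_{ij} w_{ij}(x_i - \bar x)(x_j - \bar x)}{\sum_i (x_i - \bar x)^2}}
#' with expectation `-1/(N-1)` under no autocorrelation.
#'
#' @param values numeric vector (NA allowed; pairs with NA are dropped).
#' @param weights N x N spatial weight matrix (dense or `Matrix` sparse),
#'   typically binary; the diagonal is ignored.
#' @return list with `I`, `expected` (`-1/(N-1)`), `sd` (under the
#'   normality approximation), `n`.
#' @export
morans_i <- function(values, weights) {
  ok <- !is.na(values)
  x <- values[ok]
  W <- weights[ok, ok, drop = FALSE]
  n <- length(x)
  if (n < 3) stop("need at least 3 non-missing cells")
  Matrix::diag(W) <- 0
  S0 <- sum(W)
  if (S0 == 0) stop("total weight is zero")
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss == 0) stop("Moran's I undefined for a constant field")
  I <- (n / S0) * as.numeric(xc %*% (W %*% xc)) / ss
  # variance under normality
  Wt <- W + Matrix::t(W)
  S1 <- 0.5 * sum(Wt^2)
  S2 <- sum((Matrix::rowSums(W) + Matrix::colSums(W))^2)
  EI <- -1 / (n - 1)
  VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  list(I = I, expected = EI, sd = sqrt(max(VI, 0)), n = n)
}

# binary sparse weight matrix: w_ij = 1 iff 0 < d(i,j) <= radius; built with
# a spatial-bucket search so it scales to 10^4+ cells
.radius_weights <- function(coords, radius, include_self = FALSE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  bx <- floor(coords[, 1] / radius); by <- floor(coords[, 2] / radius)
  key <- paste(bx, by)
  buckets <- split(seq_len(n), key)
  bkey <- do.call(rbind, strsplit(names(buckets), " "))
  bxy <- matrix(as.numeric(bkey), ncol = 2)
  ii <- vector("list", length(buckets))
  r2 <- radius^2
  lookup <- new.env(hash = TRUE)
  for (k in seq_along(buckets)) assign(names(buckets)[k], k, envir = lookup)
  for (k in seq_along(buckets)) {
    pts <- buckets[[k]]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      nb <- paste(bxy[k, 1] + dx, bxy[k, 2] + dy)
      kk <- mget(nb, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(kk)) cand <- c(cand, buckets[[kk]])
    }
    d2 <- outer(coords[pts, 1], coords[cand, 1], "-")^2 +
      outer(coords[pts, 2], coords[cand, 2], "-")^2
    hit <- which(d2 <= r2, arr.ind = TRUE)
    ii[[k]] <- cbind(pts[hit[, 1]], cand[hit[, 2]])
  }
  ij <- do.call(rbind, ii)
  if (!include_self) ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1, dims = c(n, n))
}

#' Moran's I correlogram over distance bands
#'
#' Computes global Moran's I with binary distance-band weights for each
#' band, together with the null expectation and normal-approximation SE —
#' the tool used to find the distance at which similarity between biomass
#' values decays and hence to set the Gi* neighborhood.
#'
#' @param values numeric vector of cell values.
#' @param coords matrix/data.frame of cell x/y (km).
#' @param distance_bins increasing numeric vector of band edges (km);
#'   band b covers `(edges[b], edges[b+1]]` with the first band starting
#'   at 0 exclusive.
#' @param max_cells correlograms need all pairwise distances; larger
#'   fields are subsampled (fixed seed) to this many cells.
#' @return data.frame with `d_lo`, `d_hi`, `n_pairs`, `I`, `expected`, `se`.
#' @export
correlogram <- function(values, coords, distance_bins, max_cells = 2500) {
  coords <- as.matrix(coords)
  ok <- !is.na(values)
  values <- values[ok]; coords <- coords[ok, , drop = FALSE]
  if (length(values) > max_cells) {
    keep <- withr_seed(1, sample.int(length(values), max_cells))
    values <- values[keep]; coords <- coords[keep, , drop = FALSE]
  }
  D <- as.matrix(stats::dist(coords))
  edges <- c(0, distance_bins)
  out <- lapply(seq_len(length(edges) - 1), function(b) {
    Wb <- (D > edges[b] & D <= edges[b + 1]) * 1
    npairs <- sum(Wb) / 2
    if (npairs < 30) return(NULL)  # too few pairs for a stable estimate
    m <- morans_i(values, Wb)
    data.frame(d_lo = edges[b], d_hi = edges[b + 1], n_pairs = npairs,
               I = m$I, expected = m$expected, se = m$sd)
  })
  do.call(rbind, out)
}

#' Choose the Gi* neighborhood distance from a correlogram
#'
#' The neighborhood is the upper edge of the last band before the first
#' band whose Moran's I has decayed to the null, operationalized as
#' `I <= expected + 2 * se` under the normality approximation. A
#' white-noise field (first band already non-significant) returns the
#' first band edge with a warning, as does a field that never decays
#' (largest band edge).
#'
#' @param cg correlogram data.frame from [correlogram()].
#' @return neighborhood distance in km.
#' @export
choose_neighborhood <- function(cg) {
  dead <- which(cg$I <= cg$expected + 2 * cg$se)
  if (!length(dead)) {
    warning("Moran's I never decayed; using the largest band edge")
    return(cg$d_hi[nrow(cg)])
  }
  if (dead[1] == 1) {
    warning("no spatial autocorrelation in the first band; using its edge")
    return(cg$d_hi[1])
  }
  cg$d_hi[dead[1] - 1]
}

#' Getis-Ord Gi* hotspot statistic
#'
#' Per-cell standardized weighted neighborhood sum with binary
#' distance-band weights (`w_ij = 1` for `d(i,j) <= neighborhood_km`,
#' self included by default — the Gi* convention):
#' \deqn{Z_i = \frac{\sum_j w_{ij} x_j - \bar x W_i}
#'   {S \sqrt{(N \sum_j w_{ij}^2 - W_i^2) / (N - 1)}}}
#' where `x̄` and `S` (population SD) default to the field's own moments
#' but can be supplied pooled across years so hotspot intensity is
#' comparable between years.
#'
#' @param values numeric cell values (NA cells get NA Z).
#' @param coords matrix/data.frame of cell x/y (km).
#' @param neighborhood_km positive neighborhood radius.
#' @param pooled optional list with `mean`, `sd` for pooled
#'   standardization across years.
#' @param include_self include the focal cell in its own neighborhood
#'   (Gi*; set `FALSE` for plain Gi).
#' @return object of class `z_field`: list with `z`, `coords`,
#'   `pooled_mean`, `pooled_sd`, `neighborhood_km`.
#' @export
gi_star <- function(values, coords, neighborhood_km, pooled = NULL,
                    include_self = TRUE) {
  if (neighborhood_km <= 0) stop("neighborhood_km must be positive")
  coords <- as.matrix(coords)
  ok <- !is.na(values)
  if (length(unique(values[ok])) < 2) stop("need >= 2 distinct values")
  x <- values; x[!ok] <- 0
  W <- .radius_weights(coords, neighborhood_km, include_self = include_self)
  W <- W[, ok, drop = FALSE][ok, , drop = FALSE]
  xs <- values[ok]
  n <- if (!is.null(pooled$n)) pooled$n else length(xs)
  xbar <- if (!is.null(pooled)) pooled$mean else mean(xs)
  S <- if (!is.null(pooled)) pooled$sd else sqrt(mean(xs^2) - mean(xs)^2)
  if (S <= 0) stop("zero standard deviation (constant data)")
  Wi <- Matrix::rowSums(W)
  S1i <- Matrix::rowSums(W^2)  # = Wi for binary weights
  num <- as.numeric(W %*% xs) - xbar * Wi
  den <- S * sqrt(pmax(n * S1i - Wi^2, 0) / (n - 1))
  z <- rep(NA_real_, length(values))
  z[ok] <- num / den
  structure(list(z = z, coords = coords, pooled_mean = xbar, pooled_sd = S,
                 neighborhood_km = neighborhood_km), class = "z_field")
}

#' Gi* per year with pooled standardization
#'
#' Computes the pooled mean/SD over all cell-years of a prediction stack,
#' then applies [gi_star()] to each year with that pooled
#' standardization, so Z-scores (and hence hotspots) are comparable
#' between years and an anomalously weak year can contain no hotspot at
#' all.
#'
#' @param stack a [grid_stack()] of predictions (response scale).
#' @param neighborhood_km Gi* neighborhood radius (km).
#' @param include_self Gi* (TRUE) vs Gi (FALSE) convention.
#' @return list of `z_field`s, one per year, plus attributes
#'   `pooled_mean`, `pooled_sd`.
#' @export
pooled_gi_star_by_year <- function(stack, neighborhood_km, include_self = TRUE) {
  stopifnot(inherits(stack, "grid_stack"))
  cc <- grid_centers(stack$spec)
  vals <- stack$values
  if (ncol(vals) < 2) {
    warning("single year supplied; falling back to plain gi_star")
    zf <- gi_star(vals[, 1], cc[, c("x", "y")], neighborhood_km,
                  include_self = include_self)
    return(structure(stats::setNames(list(zf), colnames(vals)),
                     pooled_mean = zf$pooled_mean, pooled_sd = zf$pooled_sd))
  }
  all_v <- as.numeric(vals)
  all_v <- all_v[!is.na(all_v)]
  pm <- mean(all_v)
  ps <- sqrt(mean(all_v^2) - pm^2)
  out <- lapply(seq_len(ncol(vals)), function(j) {
    gi_star(vals[, j], cc[, c("x", "y")], neighborhood_km,
            pooled = list(mean = pm, sd = ps), include_self = include_self)
  })
  structure(stats::setNames(out, colnames(vals)),
            pooled_mean = pm, pooled_sd = ps)
}

#' Threshold Gi* Z-scores into a hotspot mask
#'
#' Cells with Z at or above the `percentile` quantile (90th by default) of
#' the Z distribution — pooled across years when a multi-year list is
#' supplied — are hotspots. Ties at the threshold are included.
#'
#' @param zfield a `z_field`, a list of `z_field`s (year list; pooled
#'   quantile), or a numeric vector of Z-scores.
#' @param percentile threshold quantile in (0, 1), default 0.90.
#' @param cell_km cell size used to report hotspot area (km).
#' @return for a single field, a logical vector with attributes
#'   `area_km2`, `threshold`, `percentile`; for a year list, a list of
#'   such masks sharing the pooled threshold.
#' @export
hotspot_mask <- function(zfield, percentile = 0.90, cell_km = NA) {
  if (inherits(zfield, "z_field")) zlist <- list(zfield$z)
  else if (is.list(zfield)) zlist <- lapply(zfield, function(f) f$z)
  else zlist <- list(as.numeric(zfield))
  zall <- unlist(zlist)
  zall <- zall[!is.na(zall)]
  if (length(zall) < 10) stop("need at least 10 cells")
  thr <- stats::quantile(zall, percentile, names = FALSE)
  if (min(zall) == max(zall))
    warning("all Z-scores equal; every cell ties at the threshold")
  masks <- lapply(zlist, function(z) {
    m <- !is.na(z) & z >= thr
    structure(m, area_km2 = sum(m) * cell_km^2, threshold = thr,
              percentile = percentile, cell_km = cell_km)
  })
  single <- inherits(zfield, "z_field") || !is.list(zfield)
  if (single) masks[[1]] else stats::setNames(masks, names(zfield))
}

#' Percentage overlap between two hotspot masks
#'
#' `100 * |A intersect B| / |A union B|` (the union denominator: the
#' proportion of total hotspot that is co-occurrence rather than a single
#' species). Set `denominator = "a"` or `"b"` for a per-species
#' denominator instead.
#'
#' @param mask_a,mask_b co-registered logical vectors/matrices.
#' @param cell_km cell size for area reporting (km).
#' @param denominator `"union"` (default), `"a"` or `"b"`.
#' @return list with `pct_overlap`, `area_both`, `area_a_only`,
#'   `area_b_only` (km^2 when `cell_km` given, else cell counts).
#' @export
overlap_percentage <- function(mask_a, mask_b, cell_km = 1,
                               denominator = c("union", "a", "b")) {
  denominator <- match.arg(denominator)
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  if (length(a) != length(b)) stop("masks are not co-registered")
  both <- sum(a & b); aonly <- sum(a & !b); bonly <- sum(!a & b)
  den <- switch(denominator, union = both + aonly + bonly,
                a = sum(a), b = sum(b))
  if (den == 0) {
    warning("both masks empty; overlap defined as 0")
    pct <- 0
  } else pct <- 100 * both / den
  list(pct_overlap = pct, area_both = both * cell_km^2,
       area_a_only = aonly * cell_km^2, area_b_only = bonly * cell_km^2)
}

#' Per-cell co-occurrence percentage across species
#'
#' For each grid cell, 100 times the number of species whose hotspot mask
#' is hot there divided by the number of species analyzed. Cells outside
#' the common surveyed area of all species are missing.
#'
#' @param masks named list of per-species logical masks (common grid).
#' @param surveyed optional list of logical coverage vectors per species;
#'   cells not surveyed by every species become `NA`.
#' @return numeric vector of co-occurrence percentages per cell.
#' @export
cooccurrence_percent <- function(masks, surveyed = NULL) {
  if (!length(masks)) stop("empty species list")
  n <- length(masks[[1]])
  for (m in masks) if (length(m) != n) stop("masks are not co-registered")
  hot <- Reduce(`+`, lapply(masks, function(m) as.numeric(m)))
  out <- 100 * hot / length(masks)
  if (!is.null(surveyed)) {
    common <- Reduce(`&`, surveyed)
    out[!common] <- NA_real_
  }
  out
}

#' Hotspot area binned by northing
#'
#' Partitions a hotspot mask into 100-km northing bins and reports the
#' hotspot area per bin (bin totals sum exactly to the overall mask
#' area); when a second mask is supplied, also reports per-bin areas of
#' each species alone and of their co-occurrence.
#'
#' @param mask logical hotspot mask.
#' @param northing_km per-cell northing coordinates (km).
#' @param cell_km cell size (km).
#' @param northing_bin_km bin width (km), default 100.
#' @param mask2 optional second species mask.
#' @return data.frame with `bin_lo`, `bin_hi`, `area_km2` (and with
#'   `mask2`: `area_a_only`, `area_b_only`, `area_co`).
#' @export
binned_hotspot_area <- function(mask, northing_km, cell_km,
                                northing_bin_km = 100, mask2 = NULL) {
  mask <- as.logical(mask)
  stopifnot(length(mask) == length(northing_km))
  b0 <- floor(min(northing_km) / northing_bin_km) * northing_bin_km
  bin <- floor((northing_km - b0) / northing_bin_km)
  bins <- seq(0, max(bin))
  area <- function(m) vapply(bins, function(b) sum(m & bin == b), 0) * cell_km^2
  out <- data.frame(bin_lo = b0 + bins * northing_bin_km,
                    bin_hi = b0 + (bins + 1) * northing_bin_km,
                    area_km2 = area(mask))
  if (!is.null(mask2)) {
    mask2 <- as.logical(mask2)
    out$area_a_only <- area(mask & !mask2)
    out$area_b_only <- area(mask2 & !mask)
    out$area_co <- area(mask & mask2)
  }
  out
}
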