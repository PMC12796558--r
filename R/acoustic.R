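#' Echogram grid of volume backscattering strength
#'
#' Container for a single-frequency Sv grid (dB re 1 m^-1), rows indexed
#' by depth sample and columns by ping / along-track position.
#'
#' @param sv_db numeric matrix of Sv values (dB); `NA` marks missing cells.
#' @param depth_m strictly increasing per-row depths (m).
#' @param along_track_nmi nondecreasing per-column cumulative distance (nmi).
#' @param frequency_khz acoustic frequency (38 or 120 in this workflow).
#' @export
echogram_grid <- function(sv_db, depth_m, along_track_nmi, frequency_khz) {
  sv_db <- as.matrix(sv_db)
  if (length(depth_m) != nrow(sv_db)) stop("depth_m must match rows of sv_db")
  if (length(along_track_nmi) != ncol(sv_db))
    stop("along_track_nmi must match columns of sv_db")
  if (any(diff(depth_m) <= 0)) stop("depths must be strictly increasing")
  if (any(diff(along_track_nmi) < 0))
    stop("along-track distance must be nondecreasing")
  structure(list(sv_db = sv_db, depth_m = as.numeric(depth_m),
                 along_track_nmi = as.numeric(along_track_nmi),
                 frequency_khz = frequency_khz),
            class = "echogram_grid")
}

#' @export
print.echogram_grid <- function(x, ...) {
  cat(sprintf("<echogram_grid> %g kHz, %d depth samples x %d pings\n",
              x$frequency_khz, nrow(x$sv_db), ncol(x$sv_db)))
  invisible(x)
}

#' Write / read an echogram as delimited text
#'
#' Tab-separated matrix with depths (m) in the first column and a header
#' row of along-track distances (nmi); the frequency is recorded in a
#' commented first line.
#'
#' @param eg an [echogram_grid()].
#' @param path file path.
#' @export
write_echogram <- function(eg, path) {
  stopifnot(inherits(eg, "echogram_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# echogram frequency_khz=%g", eg$frequency_khz), con)
  writeLines(paste(c("depth_m", format(eg$along_track_nmi, digits = 12)),
                   collapse = "\t"), con)
  utils::write.table(cbind(eg$depth_m, eg$sv_db), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_echogram
#' @export
read_echogram <- function(path) {
  hdr <- readLines(path, n = 2)
  if (!startsWith(hdr[1], "# echogram")) stop("not an echogram file: ", path)
  freq <- as.numeric(sub(".*frequency_khz=", "", hdr[1]))
  along <- as.numeric(strsplit(hdr[2], "\t")[[1]][-1])
  m <- unname(as.matrix(utils::read.table(path, sep = "\t", skip = 2)))
  echogram_grid(m[, -1, drop = FALSE], m[, 1], along, freq)
}

# mean of a dB quantity in the linear domain: 10*log10(mean(10^(x/10)))
.db_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  10 * log10(mean(10^(x / 10)))
}

#' Mean volume backscattering strength over ping x depth windows
#'
#' Averages Sv in the linear domain over windows of `window_pings` pings by
#' `window_depth_m` meters (40 pings by 10-m cells by default), the
#' resolution at which dB differencing is performed. Trailing partial
#' windows are averaged over the available samples rather than discarded,
#' so transect ends are kept. All-missing windows stay missing.
#'
#' @param echogram an [echogram_grid()].
#' @param window_pings pings per window (>= 1).
#' @param window_depth_m vertical window size in meters (>= one sample).
#' @return a coarse [echogram_grid()] of MVBS values; window centers carry
#'   the mean depth / along-track position of their samples.
#' @export
compute_mvbs <- function(echogram, window_pings = 40, window_depth_m = 10) {
  stopifnot(inherits(echogram, "echogram_grid"))
  if (window_pings < 1) stop("window_pings must be >= 1")
  dz <- stats::median(diff(echogram$depth_m))
  rows_per <- max(1L, round(window_depth_m / dz))
  if (window_depth_m < dz) stop("window_depth_m smaller than one depth sample")
  nr <- nrow(echogram$sv_db); np <- ncol(echogram$sv_db)
  rgrp <- (seq_len(nr) - 1) %/% rows_per + 1
  cgrp <- (seq_len(np) - 1) %/% window_pings + 1
  lin <- 10^(echogram$sv_db / 10)
  # window linear means via two grouped matrix products on indicator matrices
  out <- matrix(NA_real_, max(rgrp), max(cgrp))
  for (i in seq_len(max(rgrp))) for (j in seq_len(max(cgrp))) {
    block <- echogram$sv_db[rgrp == i, cgrp == j, drop = FALSE]
    out[i, j] <- .db_mean(block)
  }
  echogram_grid(out,
                tapply(echogram$depth_m, rgrp, mean),
                tapply(echogram$along_track_nmi, cgrp, mean),
                echogram$frequency_khz)
}

#' Classify krill-like cells by dual-frequency dB difference
#'
#' Marks co-registered MVBS cells whose 120 kHz minus 38 kHz difference
#' falls inside the closed interval `[low_db, high_db]` (10.0-16.3 dB by
#' default, the window for adult euphausiids). Cells missing at either
#' frequency are never classified as krill.
#'
#' @param mvbs120,mvbs38 co-registered [echogram_grid()]s (same cells).
#' @param low_db,high_db window bounds in dB; both ends inclusive.
#' @return logical matrix mask, `TRUE` for krill-classified cells.
#' @export
db_difference_classify <- function(mvbs120, mvbs38, low_db = 10.0,
                                   high_db = 16.3) {
  stopifnot(inherits(mvbs120, "echogram_grid"), inherits(mvbs38, "echogram_grid"))
  if (!all(dim(mvbs120$sv_db) == dim(mvbs38$sv_db)))
    stop("MVBS grids are not co-registered (shape mismatch)")
  d <- mvbs120$sv_db - mvbs38$sv_db
  mask <- d >= low_db & d <= high_db
  mask[is.na(mask)] <- FALSE
  mask
}

#' Echo-integrate masked backscatter to per-bin NASC
#'
#' Converts a masked Sv grid to the nautical area scattering coefficient
#' (NASC, m^2 nmi^-2) per along-track bin:
#' `NASC = 4 pi 1852^2 * mean over pings of sum_depth(10^(Sv/10) * dz)`,
#' summing only masked cells inside `[depth_min_m, depth_max_m]`. Bins with
#' no masked cells get `nasc = 0` — a valid absence observation.
#'
#' @param sv an [echogram_grid()].
#' @param mask logical matrix co-registered with `sv` (e.g. from
#'   [db_difference_classify()]); `NULL` integrates every cell.
#' @param depth_min_m,depth_max_m integration window (m); use `0, Inf` for
#'   the whole water column (hake-style integration). Euphausiid defaults
#'   are 50-300 m.
#' @param bin_nmi along-track bin length (nmi), default 0.5.
#' @param year year label attached to the records.
#' @param origin_km,direction unit geometry mapping along-track distance to
#'   plane coordinates: `xy = origin_km + along_km * direction`.
#' @return data.frame of `NascRecord`s: `x_km`, `y_km`, `year`, `nasc`,
#'   `bin_index`.
#' @export
echo_integrate_nasc <- function(sv, mask = NULL, depth_min_m = 50,
                                depth_max_m = 300, bin_nmi = 0.5,
                                year = NA_integer_, origin_km = c(0, 0),
                                direction = c(1, 0)) {
  stopifnot(inherits(sv, "echogram_grid"))
  if (depth_min_m >= depth_max_m) stop("depth_min_m must be < depth_max_m")
  if (ncol(sv$sv_db) == 0) {
    return(data.frame(x_km = numeric(0), y_km = numeric(0),
                      year = integer(0), nasc = numeric(0),
                      bin_index = integer(0)))
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(sv$sv_db), ncol(sv$sv_db))
  if (!all(dim(mask) == dim(sv$sv_db)))
    stop("mask is not co-registered with sv")
  depth <- sv$depth_m
  dz <- diff(depth)
  dz <- c(dz, dz[length(dz)])  # last layer thickness repeats the previous
  in_window <- depth >= depth_min_m & depth <= depth_max_m
  lin <- 10^(sv$sv_db / 10)
  lin[!mask | is.na(lin)] <- 0
  lin[!in_window, ] <- 0
  per_ping <- colSums(lin * dz)  # integrated s_v per ping (m^2 m^-2... x m)
  bin <- floor(sv$along_track_nmi / bin_nmi)
  sa <- tapply(per_ping, bin, mean) * 4 * pi * 1852^2
  bins <- as.integer(names(sa))
  mid_nmi <- (bins + 0.5) * bin_nmi
  direction <- direction / sqrt(sum(direction^2))
  data.frame(x_km = origin_km[1] + mid_nmi * 1.852 * direction[1],
             y_km = origin_km[2] + mid_nmi * 1.852 * direction[2],
             year = year, nasc = as.numeric(sa), bin_index = bins)
}
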