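#' Regular projected grid specification
#'
#' Defines a regular grid of square cells on a planar (projected, km)
#' coordinate system, the common spatial container for covariate layers,
#' model predictions and hotspot masks. Cells are half-open
#' `[lo, hi)` in both axes, indexed row-major with cell (1,1) at the
#' origin corner and centers at `origin + (i - 0.5) * cell_km`.
#'
#' @param x0_km,y0_km coordinates (km) of the grid origin corner.
#' @param cell_km positive cell side length in km.
#' @param nx,ny number of columns (x) and rows (y).
#' @param proj free-text projection tag carried along (no reprojection is
#'   ever performed); defaults to `"planar-km"`.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(x0_km = 0, y0_km = 0, cell_km = 3, nx, ny,
                      proj = "planar-km") {
  stopifnot(is.numeric(cell_km), length(cell_km) == 1, cell_km > 0)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1 || ny < 1) stop("grid must have at least one cell in each axis")
  structure(list(x0 = x0_km, y0 = y0_km, cell_km = cell_km,
                 nx = nx, ny = ny, proj = proj),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g km (%s), origin (%g, %g)\n",
              x$nx, x$ny, x$cell_km, x$proj, x$x0, x$y0))
  invisible(x)
}

n_cells <- function(spec) spec$nx * spec$ny

#' Cell center coordinates of a grid
#'
#' @param spec a [grid_spec()].
#' @return data.frame with `cell`, `col`, `row`, `x`, `y` (km); row-major,
#'   `cell = (row - 1) * nx + col`.
#' @export
grid_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  col <- rep(seq_len(spec$nx), times = spec$ny)
  row <- rep(seq_len(spec$ny), each = spec$nx)
  data.frame(cell = seq_len(n_cells(spec)), col = col, row = row,
             x = spec$x0 + (col - 0.5) * spec$cell_km,
             y = spec$y0 + (row - 0.5) * spec$cell_km)
}

#' Locate points on a grid (half-open cell convention)
#'
#' Maps points to containing cells using the shared half-open convention
#' `[x0 + i*c, x0 + (i+1)*c)`: a point on a shared edge belongs to the
#' cell on its upper side. Used identically by covariate extraction,
#' survey simulation and regridding.
#'
#' @param spec a [grid_spec()].
#' @param x,y point coordinates in km.
#' @return integer cell ids; `NA` for points outside the grid extent.
#' @export
point_to_cell <- function(spec, x, y) {
  stopifnot(inherits(spec, "grid_spec"), length(x) == length(y))
  col <- floor((x - spec$x0) / spec$cell_km) + 1
  row <- floor((y - spec$y0) / spec$cell_km) + 1
  ok <- col >= 1 & col <= spec$nx & row >= 1 & row <= spec$ny &
    is.finite(col) & is.finite(row)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((row[ok] - 1) * spec$nx + col[ok])
  out
}

#' Single spatial layer on a grid
#'
#' @param spec a [grid_spec()].
#' @param values numeric vector, one value per cell (row-major); `NA`
#'   encodes masked/unsurveyed cells.
#' @export
grid_field <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.numeric(values)
  if (length(values) != n_cells(spec))
    stop("values must have length nx * ny = ", n_cells(spec))
  structure(list(spec = spec, values = values), class = "grid_field")
}

#' Multi-year stack of layers on a grid
#'
#' @param spec a [grid_spec()].
#' @param years ordered integer vector of layer labels.
#' @param values numeric matrix, `n_cells x length(years)`.
#' @export
grid_stack <- function(spec, years, values) {
  stopifnot(inherits(spec, "grid_spec"))
  years <- as.integer(years)
  values <- as.matrix(values)
  if (nrow(values) != n_cells(spec) || ncol(values) != length(years))
    stop("values must be an n_cells x n_years matrix")
  colnames(values) <- as.character(years)
  structure(list(spec = spec, years = years, values = values),
            class = "grid_stack")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %d x %d cells of %g km; %d missing\n",
              x$spec$nx, x$spec$ny, x$spec$cell_km, sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d x %d cells of %g km; years %s\n",
              x$spec$nx, x$spec$ny, x$spec$cell_km,
              paste(range(x$years), collapse = "-")))
  invisible(x)
}

#' @export
as.data.frame.grid_field <- function(x, ...) {
  cbind(grid_centers(x$spec), value = x$values)
}

#' @export
as.data.frame.grid_stack <- function(x, ...) {
  cc <- grid_centers(x$spec)
  out <- do.call(rbind, lapply(seq_along(x$years), function(j) {
    cbind(cc, year = x$years[j], value = x$values[, j])
  }))
  rownames(out) <- NULL
  out
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol &&
    abs(a$cell_km - b$cell_km) < tol && a$nx == b$nx && a$ny == b$ny
}

#' Write / read a grid stack as long-format delimited text
#'
#' Columns: `cell_id`, `x`, `y`, `year`, `value`. The grid geometry is
#' stored in a commented header line so the stack round-trips exactly.
#'
#' @param stack a [grid_stack()] (a [grid_field()] is written as one year 0).
#' @param path file path.
#' @export
write_grid_stack <- function(stack, path) {
  if (inherits(stack, "grid_field"))
    stack <- grid_stack(stack$spec, 0L, matrix(stack$values, ncol = 1))
  s <- stack$spec
  hdr <- sprintf("# grid x0=%.10g y0=%.10g cell_km=%.10g nx=%d ny=%d proj=%s",
                 s$x0, s$y0, s$cell_km, s$nx, s$ny, s$proj)
  df <- as.data.frame(stack)[, c("cell", "x", "y")]
  long <- as.data.frame(stack)
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    long[, c("cell", "x", "y", "year", "value")], path, append = TRUE,
    sep = "\t", row.names = FALSE, quote = FALSE,
    col.names = c("cell_id", "x", "y", "year", "value")))
  invisible(path)
}

#' @rdname write_grid_stack
#' @param path file written by [write_grid_stack()].
#' @export
read_grid_stack <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# grid")) stop("not a grid stack file: ", path)
  kv <- strsplit(sub("^# grid ", "", hdr), " ")[[1]]
  kv <- strsplit(kv, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  spec <- grid_spec(as.numeric(vals["x0"]), as.numeric(vals["y0"]),
                    as.numeric(vals["cell_km"]), as.integer(vals["nx"]),
                    as.integer(vals["ny"]), vals[["proj"]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1)
  years <- sort(unique(df$year))
  vals_m <- matrix(NA_real_, n_cells(spec), length(years))
  for (j in seq_along(years)) {
    sub <- df[df$year == years[j], ]
    vals_m[sub$cell_id, j] <- sub$value
  }
  grid_stack(spec, years, vals_m)
}
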