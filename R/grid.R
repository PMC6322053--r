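#' Regular concentration grid
#'
#' Defines a regular grid of square cells, the spatial support shared by the
#' dispersion-model surrogate, the fused field and the municipality weights.
#' Cell indices `cell_i` (column) and `cell_j` (row) are 0-based; the centre of
#' cell (i, j) lies at `origin + (i + 0.5, j + 0.5) * cell_km`.
#'
#' @param nx,ny number of cells along x and y (>= 1).
#' @param cell_km cell edge length in km. The default 4 km matches the support
#'   of urban-background dispersion-model output.
#' @param origin numeric length 2, lower-left corner (x0, y0) in km.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(25, 20)
#' n_cells(g)
#' @export
grid_spec <- function(nx, ny, cell_km = 4, origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("nx and ny must be >= 1")
  if (!is.numeric(cell_km) || cell_km <= 0) stop("cell_km must be > 0")
  if (length(origin) != 2L) stop("origin must have length 2")
  structure(list(nx = nx, ny = ny, cell_km = cell_km,
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @export
n_cells <- function(grid) grid$nx * grid$ny

#' Cell centres of a grid
#'
#' @param grid a `grid_spec`.
#' @return data.frame with `cell_i`, `cell_j` (0-based) and centre coordinates
#'   `x`, `y` in km, ordered with `cell_i` varying fastest. All per-cell value
#'   vectors in the package follow this ordering.
#' @export
cell_centers <- function(grid) {
  i <- rep(seq_len(grid$nx) - 1L, times = grid$ny)
  j <- rep(seq_len(grid$ny) - 1L, each = grid$nx)
  data.frame(cell_i = i, cell_j = j,
             x = grid$origin[1] + (i + 0.5) * grid$cell_km,
             y = grid$origin[2] + (j + 0.5) * grid$cell_km)
}

#' @rdname cell_centers
#' @param cell_i,cell_j 0-based cell indices.
#' @return `cell_index()`: the 1-based position of cell (i, j) in the
#'   cell-centre ordering.
#' @export
cell_index <- function(grid, cell_i, cell_j) {
  stopifnot(all(cell_i >= 0 & cell_i < grid$nx),
            all(cell_j >= 0 & cell_j < grid$ny))
  cell_j * grid$nx + cell_i + 1L
}

# cell containing point (x, y); points on the upper/right edge clamp inward
cell_of_xy <- function(grid, x, y) {
  i <- pmin(pmax(floor((x - grid$origin[1]) / grid$cell_km), 0), grid$nx - 1L)
  j <- pmin(pmax(floor((y - grid$origin[2]) / grid$cell_km), 0), grid$ny - 1L)
  data.frame(cell_i = as.integer(i), cell_j = as.integer(j))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g km (origin %g, %g)\n",
              x$nx, x$ny, x$cell_km, x$origin[1], x$origin[2]))
  invisible(x)
}

same_grid <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny &&
    isTRUE(all.equal(a$cell_km, b$cell_km)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Annual-mean concentration field
#'
#' Container for per-cell annual mean pollutant concentrations on a
#' [grid_spec()]. Values are stored in cell-centre order (see
#' [cell_centers()]), are finite and non-negative.
#'
#' @param grid a `grid_spec`.
#' @param pollutant `"PM25"` or `"NO2"`.
#' @param year integer calendar year.
#' @param values numeric vector of length `n_cells(grid)`, in ug/m3.
#' @return An object of class `conc_field`.
#' @export
conc_field <- function(grid, pollutant, year, values) {
  pollutant <- match.arg(pollutant, c("PM25", "NO2"))
  values <- as.numeric(values)
  if (length(values) != n_cells(grid))
    stop("values must have one entry per grid cell")
  if (any(!is.finite(values))) stop("field values must be finite")
  if (any(values < 0)) stop("field values must be >= 0")
  structure(list(grid = grid, pollutant = pollutant,
                 year = as.integer(year), values = values),
            class = "conc_field")
}

#' @export
print.conc_field <- function(x, ...) {
  cat(sprintf("conc_field: %s %d on %dx%d grid; mean %.2f ug/m3 [%.2f, %.2f]\n",
              x$pollutant, x$year, x$grid$nx, x$grid$ny,
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname conc_field
#' @param field a `conc_field`.
#' @return `field_df()`: data.frame with cell indices, centre coordinates and
#'   `value` (plus `kriging_variance` for fused fields).
#' @export
field_df <- function(field) {
  out <- cell_centers(field$grid)
  out$value <- field$values
  if (!is.null(field$variance)) out$kriging_variance <- field$variance
  out
}
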