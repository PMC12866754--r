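#' Grid specification
#'
#' Defines a uniform raster grid in a planar km coordinate system: the
#' lower-left corner of cell `(1, 1)`, the cell side `delta_x` (km), and the
#' cell counts `nx`, `ny`. Cells are half-open, `[left, right) x [bottom,
#' top)`, indexed from 1, and a cell's location for all distance computations
#' is its centre. The default 0.03-km resolution matches the positional
#' accuracy of helicopter survey records.
#'
#' @param origin Numeric length 2, `c(x, y)` of the lower-left corner (km).
#' @param delta_x Cell side length, km (> 0).
#' @param nx,ny Number of cells in x (easting) and y (northing).
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(c(0, 0), delta_x = 0.5, nx = 40, ny = 40)
#' @export
grid_spec <- function(origin, delta_x = 0.03, nx, ny) {
  stopifnot(length(origin) == 2, is.finite(origin))
  if (delta_x <= 0) rlang::abort("delta_x must be positive.")
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1, ny >= 1)
  structure(list(origin = as.numeric(origin), delta_x = delta_x,
                 nx = nx, ny = ny),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param extent Numeric length 4, `c(xmin, xmax, ymin, ymax)` in km; the grid
#'   is the smallest cell-aligned cover of the extent.
#' @export
grid_spec_from_extent <- function(extent, delta_x = 0.03) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  grid_spec(origin = c(extent[1], extent[3]), delta_x = delta_x,
            nx = ceiling(round((extent[2] - extent[1]) / delta_x, 9)),
            ny = ceiling(round((extent[4] - extent[3]) / delta_x, 9)))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, delta_x = %g km, origin (%g, %g)\n",
              x$nx, x$ny, x$delta_x, x$origin[1], x$origin[2]))
  invisible(x)
}

grid_extent <- function(spec) {
  c(spec$origin[1], spec$origin[1] + spec$nx * spec$delta_x,
    spec$origin[2], spec$origin[2] + spec$ny * spec$delta_x)
}

#' Cell-centre coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return A list with vectors `x` (length `nx`) and `y` (length `ny`) of
#'   cell-centre coordinates, km.
#' @export
cell_centers <- function(spec) {
  list(x = spec$origin[1] + (seq_len(spec$nx) - 0.5) * spec$delta_x,
       y = spec$origin[2] + (seq_len(spec$ny) - 0.5) * spec$delta_x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) && a$delta_x == b$delta_x &&
    a$nx == b$nx && a$ny == b$ny
}

# cell indices under the half-open convention; values outside [1, n] flag
# out-of-extent records
point_cell_index <- function(points, spec) {
  list(ix = floor((points$x_km - spec$origin[1]) / spec$delta_x) + 1L,
       iy = floor((points$y_km - spec$origin[2]) / spec$delta_x) + 1L)
}

new_year_grid <- function(counts, spec, year = NA_integer_, layer = "I") {
  structure(counts, class = c("year_grid", "matrix", "array"),
            spec = spec, year = year, layer = layer)
}

#' Rasterize point records onto a count grid
#'
#' Sums `n_trees` into half-open grid cells: cell index
#' `floor((coord - origin)/delta_x) + 1`, so a record exactly on an interior
#' cell boundary belongs to the higher-index cell. Total trees are conserved
#' for in-extent records.
#'
#' `rasterize_counts()` grids one set of records into a single `ny x nx`
#' matrix (row 1 = southernmost row). `rasterize_points()` grids a point
#' table per `(year, status)` and returns a tibble with a list-column of
#' grids.
#'
#' @param points A point-record tibble with columns `x_km`, `y_km`, `year`,
#'   `n_trees`, `status` (`rasterize_counts()` needs only `x_km`, `y_km`,
#'   `n_trees`).
#' @param spec A [grid_spec()].
#' @param out_of_extent `"drop"` (default; drops with a warning) or `"error"`.
#' @return `rasterize_counts()`: a `year_grid` count matrix.
#'   `rasterize_points()`: a tibble with columns `year`, `status`, `grid`.
#' @export
rasterize_counts <- function(points, spec,
                             out_of_extent = c("drop", "error")) {
  out_of_extent <- match.arg(out_of_extent)
  stopifnot(inherits(spec, "grid_spec"))
  if (nrow(points) > 0 && any(points$n_trees < 1))
    rlang::abort("n_trees must be >= 1 for every record.")
  idx <- point_cell_index(points, spec)
  inside <- idx$ix >= 1L & idx$ix <= spec$nx & idx$iy >= 1L & idx$iy <= spec$ny
  if (any(!inside)) {
    msg <- sprintf("%d record(s) fall outside the grid extent", sum(!inside))
    if (out_of_extent == "error")
      rlang::abort(msg, class = "pestkern_error_extent")
    rlang::warn(paste0(msg, "; dropped."))
  }
  counts <- matrix(0, nrow = spec$ny, ncol = spec$nx)
  if (any(inside)) {
    lin <- (idx$ix[inside] - 1L) * spec$ny + idx$iy[inside]
    tot <- rowsum(as.numeric(points$n_trees[inside]), lin)
    counts[as.integer(rownames(tot))] <- tot[, 1]
  }
  new_year_grid(counts, spec)
}

#' @rdname rasterize_counts
#' @export
rasterize_points <- function(points, spec,
                             out_of_extent = c("drop", "error")) {
  out_of_extent <- match.arg(out_of_extent)
  points |>
    dplyr::group_by(.data$year, .data$status) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(grid = purrr::map2(
      .data$data, .data$year,
      function(d, yr) {
        g <- rasterize_counts(d, spec, out_of_extent)
        attr(g, "year") <- yr
        g
      })) |>
    dplyr::select("year", "status", "grid") |>
    dplyr::arrange(.data$year, .data$status)
}

#' Assemble per-year infested and uncontrolled count surfaces
#'
#' The survey bookkeeping identity is `I_t(x) = c_t(x) + r_{t+1}(x)`: the
#' trees infested (attacked) in year `t` are those found and controlled in
#' year `t` plus those observed as red-tops the following year. The
#' uncontrolled infestations, which seed the next generation, are
#' `I*_t(x) = I_t(x) - c_t(x) = r_{t+1}(x)`.
#'
#' `build_stack()` applies the identity to per-year rasters of red-top counts
#' (`r`, indexed by observation year) and controlled counts (`c`, indexed by
#' control year). A year `t` enters the stack only if red-top counts for
#' `t + 1` exist.
#'
#' `infestation_stack()` is the high-level path from a point table. Under the
#' `"attack"` convention records are dated by attack year and `I_t` is all
#' year-`t` records while `I*_t` is the uncontrolled (`status == "red"`)
#' subset. Under the `"survey"` convention records are dated as surveyed
#' (red-tops carry year `t + 1`) and the identity above is applied.
#'
#' @param red,controlled Named lists of count matrices (names = years).
#' @param spec A [grid_spec()].
#' @param points Point-record tibble (see [rasterize_counts()]).
#' @param convention `"attack"` or `"survey"`.
#' @param out_of_extent Passed to [rasterize_counts()].
#' @return A `year_stack`: list with `spec`, integer `years`, and named lists
#'   `I` and `I_star` of count matrices.
#' @export
build_stack <- function(red, controlled, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  ry <- as.integer(names(red))
  years <- sort(ry) - 1L                      # I_t needs r_{t+1}
  zero <- matrix(0, spec$ny, spec$nx)
  I <- I_star <- stats::setNames(vector("list", length(years)),
                                 as.character(years))
  for (t in years) {
    ct <- controlled[[as.character(t)]]
    if (is.null(ct)) ct <- zero
    rt1 <- red[[as.character(t + 1L)]]
    if (!isTRUE(all(dim(ct) == dim(zero))) || !isTRUE(all(dim(rt1) == dim(zero))))
      rlang::abort("Grids in a stack must share the grid definition.",
                   class = "pestkern_error_alignment")
    I[[as.character(t)]] <- unclass(ct) + unclass(rt1)
    I_star[[as.character(t)]] <- unclass(rt1)
  }
  structure(list(spec = spec, years = years, I = I, I_star = I_star),
            class = "year_stack")
}

#' @rdname build_stack
#' @export
infestation_stack <- function(points, spec,
                              convention = c("attack", "survey"),
                              out_of_extent = c("drop", "error")) {
  convention <- match.arg(convention)
  out_of_extent <- match.arg(out_of_extent)
  stopifnot(inherits(spec, "grid_spec"))
  if (convention == "attack") {
    years <- sort(unique(points$year))
    I <- I_star <- stats::setNames(vector("list", length(years)),
                                   as.character(years))
    for (t in years) {
      yr <- points[points$year == t, , drop = FALSE]
      I[[as.character(t)]] <-
        unclass(rasterize_counts(yr, spec, out_of_extent))
      I_star[[as.character(t)]] <-
        unclass(rasterize_counts(yr[yr$status == "red", , drop = FALSE],
                                 spec, out_of_extent))
    }
    structure(list(spec = spec, years = as.integer(years),
                   I = I, I_star = I_star),
              class = "year_stack")
  } else {
    split_g <- function(d) {
      yrs <- sort(unique(d$year))
      stats::setNames(lapply(yrs, function(t)
        unclass(rasterize_counts(d[d$year == t, , drop = FALSE], spec,
                                 out_of_extent))), yrs)
    }
    build_stack(red = split_g(points[points$status == "red", , drop = FALSE]),
                controlled = split_g(points[points$status == "controlled", ,
                                            drop = FALSE]),
                spec = spec)
  }
}

#' @export
print.year_stack <- function(x, ...) {
  cat(sprintf("<year_stack> years %s on a %d x %d grid (delta_x = %g km)\n",
              paste(range(x$years), collapse = "-"), x$spec$nx, x$spec$ny,
              x$spec$delta_x))
  invisible(x)
}

#' Re-express attack-year records as survey tables
#'
#' Converts records dated by attack year into the form surveys produce:
#' controlled trees are reported in the attack year, while uncontrolled trees
#' appear as red-tops one year later.
#'
#' @param points Attack-year point table.
#' @return A point table under the `"survey"` dating convention.
#' @export
as_survey_table <- function(points) {
  dplyr::mutate(points,
                year = ifelse(.data$status == "red",
                              .data$year + 1L, .data$year)) |>
    dplyr::arrange(.data$year, .data$x_km, .data$y_km)
}
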