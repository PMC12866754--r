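#' Read and write point-record tables
#'
#' Point records are plain comma-separated tables with header columns
#' `x_km`, `y_km`, `year`, `n_trees`, `status` (`status` is `"red"` for
#' uncontrolled infestations or `"controlled"` for trees that were cut and
#' burned/chipped).
#'
#' @param path File path.
#' @param points Point-record tibble.
#' @return `read_points()` returns a tibble; `write_points()` returns `points`
#'   invisibly.
#' @export
read_points <- function(path) {
  pts <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           x_km = readr::col_double(),
                           y_km = readr::col_double(),
                           year = readr::col_integer(),
                           n_trees = readr::col_integer(),
                           status = readr::col_character()))
  validate_points(pts)
  pts
}

#' @rdname read_points
#' @export
write_points <- function(points, path) {
  validate_points(points)
  readr::write_csv(points, path)
  invisible(points)
}

validate_points <- function(points) {
  need <- c("x_km", "y_km", "year", "n_trees", "status")
  missing <- setdiff(need, names(points))
  if (length(missing) > 0)
    rlang::abort(paste0("Point table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  if (nrow(points) > 0) {
    if (!all(is.finite(points$x_km)) || !all(is.finite(points$y_km)))
      rlang::abort("Point coordinates must be finite.")
    if (any(points$n_trees < 1)) rlang::abort("n_trees must be >= 1.")
    if (!all(points$status %in% c("red", "controlled")))
      rlang::abort('status must be "red" or "controlled".')
  }
  invisible(points)
}

#' Read and write count grids as Esri ASCII rasters
#'
#' Serialises a count matrix with its georeferencing as a plain-text Esri
#' ASCII grid (`ncols/nrows/xllcorner/yllcorner/cellsize` header, rows from
#' north to south). Zeros are written explicitly; no nodata sentinel is used.
#'
#' @param grid A count matrix carrying a grid spec (as returned by
#'   [rasterize_counts()]), or a plain matrix plus `spec`.
#' @param spec A [grid_spec()] (taken from `grid` when absent).
#' @param path File path.
#' @return `read_grid_asc()` returns a `year_grid` matrix with the spec
#'   attached; `write_grid_asc()` returns `grid` invisibly.
#' @export
write_grid_asc <- function(grid, path, spec = attr(grid, "spec")) {
  stopifnot(inherits(spec, "grid_spec"), nrow(grid) == spec$ny,
            ncol(grid) == spec$nx)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", spec$nx), paste("nrows", spec$ny),
    paste("xllcorner", format(spec$origin[1], digits = 15)),
    paste("yllcorner", format(spec$origin[2], digits = 15)),
    paste("cellsize", format(spec$delta_x, digits = 15))), con)
  m <- unclass(grid)
  for (i in rev(seq_len(nrow(m)))) {
    writeLines(paste(format(m[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(grid)
}

#' @rdname write_grid_asc
#' @export
read_grid_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  spec <- grid_spec(origin = c(hdr$xllcorner, hdr$yllcorner),
                    delta_x = hdr$cellsize, nx = hdr$ncols, ny = hdr$nrows)
  rows <- lapply(lines[i:(i + spec$ny - 1)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rev(rows))
  new_year_grid(m, spec)
}

#' Read a polygon from a GeoJSON file
#'
#' Reads the first (outer) ring of the first `Polygon` geometry found in a
#' GeoJSON file and returns its vertices. Coordinates are taken as planar km,
#' matching the rest of the package.
#'
#' @param path File path.
#' @return A two-column matrix of vertex coordinates `(x, y)`.
#' @export
read_polygon_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  find_poly <- function(node) {
    if (is.list(node) && identical(node$type, "Polygon"))
      return(node$coordinates)
    if (is.list(node)) {
      for (child in node) {
        res <- find_poly(child)
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  coords <- find_poly(g)
  if (is.null(coords)) rlang::abort("No Polygon geometry found.",
                                    class = "pestkern_error_polygon")
  ring <- if (is.array(coords)) coords[1, , ] else coords[[1]]
  m <- matrix(as.numeric(ring), ncol = 2,
              dimnames = list(NULL, c("x", "y")))
  m
}
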