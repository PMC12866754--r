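#' Configuration for synthetic infestation histories
#'
#' Bundles everything needed to generate a multi-year infestation point
#' pattern with the statistical structure the redistribution analysis
#' assumes: each year's offspring infestations scatter around the previous
#' year's *uncontrolled* infestations according to a known dispersal kernel.
#'
#' Defaults mirror helicopter-survey data: a 0.03-km grid resolution and
#' 0.03-km isotropic positional jitter (the surveys' stated +/- 30 m
#' accuracy), and a fraction of each year's infestations found and controlled
#' by ground crews.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in km.
#' @param years Strictly increasing, consecutive integer years. Year
#'   `years[1]` holds the seed infestations.
#' @param yearly_counts Positive integers, one per year: the number of
#'   infestation records to place in each year (`yearly_counts[1]` seeds are
#'   placed uniformly over habitat).
#' @param kernel A [dispersal_kernel()] generating parent-to-offspring
#'   displacements.
#' @param delta_x Grid resolution, km; used when a habitat mask is given and
#'   by downstream gridding.
#' @param control_fraction Probability in `[0, 1]` that a record is flagged
#'   `"controlled"` (removed from the parental pool).
#' @param jitter_sd Isotropic positional noise SD, km.
#' @param habitat Optional habitat mask from [generate_habitat()]; offspring
#'   falling off-habitat are resampled.
#' @param seed Integer RNG seed; always recorded so histories are
#'   reproducible.
#' @return A `synth_config` object.
#' @export
synth_config <- function(extent, years, yearly_counts, kernel,
                         delta_x = 0.03, control_fraction = 0.2,
                         jitter_sd = 0.03, habitat = NULL, seed = 1L) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  if (delta_x <= 0) rlang::abort("delta_x must be positive.")
  years <- as.integer(years)
  if (length(years) < 1 || any(diff(years) != 1L))
    rlang::abort("years must be strictly increasing and consecutive.")
  if (length(yearly_counts) != length(years) || any(yearly_counts < 1))
    rlang::abort("yearly_counts must supply a positive count for every year.")
  if (control_fraction < 0 || control_fraction > 1)
    rlang::abort("control_fraction must lie in [0, 1].")
  if (jitter_sd < 0) rlang::abort("jitter_sd must be non-negative.")
  validate_kernel(kernel)
  if (!is.null(habitat)) stopifnot(inherits(habitat, "habitat_grid"))
  structure(list(extent = as.numeric(extent), years = years,
                 yearly_counts = as.integer(yearly_counts), kernel = kernel,
                 delta_x = delta_x, control_fraction = control_fraction,
                 jitter_sd = jitter_sd, habitat = habitat,
                 seed = as.integer(seed)),
            class = "synth_config")
}

on_habitat <- function(x, y, habitat) {
  if (is.null(habitat)) return(rep(TRUE, length(x)))
  spec <- attr(habitat, "spec")
  idx <- point_cell_index(list(x_km = x, y_km = y), spec)
  ok <- idx$ix >= 1L & idx$ix <= spec$nx & idx$iy >= 1L & idx$iy <= spec$ny
  ok[ok] <- unclass(habitat)[cbind(idx$iy[ok], idx$ix[ok])] == 1
  ok
}

#' Generate a multi-year synthetic infestation history
#'
#' Seeds `yearly_counts[1]` records uniformly over habitat in the first year;
#' for each later year `t`, every offspring location is the location of a
#' parent drawn uniformly among year `t - 1` *uncontrolled* records, plus a
#' displacement sampled from the configured kernel, plus isotropic Gaussian
#' jitter. Offspring landing outside the extent (or off-habitat) are
#' resampled, so the realised pattern honestly exercises downstream
#' buffer-zone logic. Each record is independently flagged `"controlled"`
#' with probability `control_fraction`, and carries a count of one tree
#' (tree multiplicity is a gridding concern, exercised separately).
#'
#' Records are dated by *attack year*: a real survey would report the
#' uncontrolled records as red-tops one year later (see [as_survey_table()]).
#'
#' @param config A [synth_config()].
#' @param initial Optional tibble of seed locations (`x_km`, `y_km`)
#'   overriding uniform placement.
#' @param max_tries Resampling cap per record before erroring.
#' @return A point-record tibble (`x_km`, `y_km`, `year`, `n_trees`,
#'   `status`) ordered by year.
#' @export
generate_history <- function(config, initial = NULL, max_tries = 1000L) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_history_impl(config, initial,
                                                      max_tries))
}

generate_history_impl <- function(config, initial, max_tries) {
  ext <- config$extent
  draw_uniform <- function(n) {
    for (try in seq_len(max_tries)) {
      x <- stats::runif(n, ext[1], ext[2])
      y <- stats::runif(n, ext[3], ext[4])
      ok <- on_habitat(x, y, config$habitat)
      if (try == 1) {
        keep_x <- x[ok]; keep_y <- y[ok]
      } else {
        keep_x <- c(keep_x, x[ok]); keep_y <- c(keep_y, y[ok])
      }
      if (length(keep_x) >= n)
        return(list(x = keep_x[1:n], y = keep_y[1:n]))
    }
    rlang::abort("Could not place seed records on habitat.",
                 class = "pestkern_error_habitat")
  }

  years <- config$years
  out <- vector("list", length(years))
  if (is.null(initial)) {
    seeds <- draw_uniform(config$yearly_counts[1])
  } else {
    stopifnot(nrow(initial) >= 1)
    seeds <- list(x = initial$x_km, y = initial$y_km)
  }
  out[[1]] <- tibble::tibble(
    x_km = seeds$x, y_km = seeds$y, year = years[1],
    n_trees = 1L,
    status = ifelse(stats::runif(length(seeds$x)) < config$control_fraction,
                    "controlled", "red"))

  for (k in seq_along(years)[-1]) {
    parents <- out[[k - 1]][out[[k - 1]]$status == "red", , drop = FALSE]
    if (nrow(parents) == 0)
      rlang::abort(paste0("No uncontrolled parents remain in year ",
                          years[k - 1],
                          "; control_fraction is too high for this history."),
                   class = "pestkern_error_no_parents")
    n <- config$yearly_counts[k]
    pid <- sample.int(nrow(parents), n, replace = TRUE)
    x <- y <- rep(NA_real_, n)
    pending <- seq_len(n)
    for (try in seq_len(max_tries)) {
      m <- length(pending)
      disp <- kernel_sample(config$kernel, m)
      jx <- if (config$jitter_sd > 0) stats::rnorm(m, 0, config$jitter_sd) else 0
      jy <- if (config$jitter_sd > 0) stats::rnorm(m, 0, config$jitter_sd) else 0
      px <- parents$x_km[pid[pending]] + disp$dx + jx
      py <- parents$y_km[pid[pending]] + disp$dy + jy
      ok <- px >= ext[1] & px < ext[2] & py >= ext[3] & py < ext[4] &
        on_habitat(px, py, config$habitat)
      x[pending[ok]] <- px[ok]
      y[pending[ok]] <- py[ok]
      pending <- pending[!ok]
      if (length(pending) == 0) break
    }
    if (length(pending) > 0)
      rlang::abort("Offspring resampling cap reached; kernel mass may lie almost entirely outside the extent.",
                   class = "pestkern_error_habitat")
    out[[k]] <- tibble::tibble(
      x_km = x, y_km = y, year = years[k], n_trees = 1L,
      status = ifelse(stats::runif(n) < config$control_fraction,
                      "controlled", "red"))
  }
  dplyr::bind_rows(out)
}

#' Generate a habitat mask
#'
#' Produces a `{0, 1}` raster on the configured grid, standing in for host
#' availability (e.g. the extent of dominant lodgepole pine). `"uniform"` is
#' all ones; `"banded"` alternates habitat bands along the easting axis;
#' `"patchy"` thresholds smoothed Gaussian noise at a quantile, so a
#' `threshold_quantile` of 0.6 leaves roughly 40% of cells as habitat.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in km.
#' @param delta_x Cell size, km.
#' @param pattern `"uniform"`, `"banded"` or `"patchy"`.
#' @param seed RNG seed (patchy noise); identical seeds give identical masks.
#' @param threshold_quantile Quantile of the smoothed noise above which a
#'   cell is habitat (`"patchy"` only).
#' @param band_km Band width for `"banded"`, km.
#' @param smooth_cells Moving-average half-width (cells) for `"patchy"`.
#' @return A `habitat_grid`: a `{0,1}` matrix with the [grid_spec()] attached.
#' @export
generate_habitat <- function(extent, delta_x = 0.03,
                             pattern = c("uniform", "banded", "patchy"),
                             seed = 1L, threshold_quantile = 0.6,
                             band_km = (extent[2] - extent[1]) / 8,
                             smooth_cells = 5L) {
  pattern <- match.arg(pattern)
  spec <- grid_spec_from_extent(extent, delta_x)
  cc <- cell_centers(spec)
  mask <- switch(pattern,
    uniform = matrix(1, spec$ny, spec$nx),
    banded = {
      band <- floor((cc$x - extent[1]) / band_km) %% 2 == 0
      matrix(rep(as.numeric(band), each = spec$ny), spec$ny, spec$nx)
    },
    patchy = withr::with_seed(seed, {
      z <- matrix(stats::rnorm(spec$ny * spec$nx), spec$ny, spec$nx)
      sm <- smooth_matrix(z, smooth_cells)
      (sm > stats::quantile(sm, threshold_quantile)) + 0
    }))
  structure(mask, class = c("habitat_grid", "matrix", "array"), spec = spec)
}

# separable moving-average smoother (circular edges keep the window complete)
smooth_matrix <- function(z, half_width) {
  if (half_width < 1) return(z)
  k <- rep(1 / (2 * half_width + 1), 2 * half_width + 1)
  smooth_rows <- function(m)
    t(apply(m, 1, function(row)
      as.numeric(stats::filter(row, k, sides = 2, circular = TRUE))))
  t(smooth_rows(t(smooth_rows(z))))
}
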