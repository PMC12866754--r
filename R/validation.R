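#' Distance from each offspring to the nearest parental infestation
#'
#' Euclidean nearest-neighbour distances computed on the point records
#' themselves (not on rasterised cells), so no quantisation is added. A
#' lower bound on true redistribution distance, and the empirical quantity
#' the marginal kernel `2*pi*r*D(r)` is compared against.
#'
#' @param offspring,parents Point tables with `x_km`, `y_km`.
#' @return Numeric vector, one distance (km) per offspring record.
#' @export
nearest_parent_distances <- function(offspring, parents) {
  if (nrow(parents) == 0)
    rlang::abort("Parent set is empty.", class = "pestkern_error_no_parents")
  n <- nrow(offspring)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / nrow(parents)))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    d2 <- outer(offspring$x_km[idx], parents$x_km, "-")^2 +
      outer(offspring$y_km[idx], parents$y_km, "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' True positive rate of a probability surface
#'
#' A cell is *observed positive* when it holds at least one offspring
#' infestation, and *predicted positive* when the probability of one or more
#' infestations exceeds 1/2 — the complement of the Bernoulli probability of
#' zero successes in `N_t` trials with per-trial probability `pi(x)`:
#' `1 - (1 - pi(x))^N_t > 1/2`. The TPR is the fraction of observed-positive
#' interior cells that are predicted positive.
#'
#' @param surface A [likelihood_surface()].
#' @param offspring Offspring count matrix `I_t`.
#' @param N_t Trial count: total infestations observed in the focal year
#'   (defaults to `sum(offspring)`).
#' @return Scalar TPR in `[0, 1]`, or `NA` (with a warning) when no interior
#'   cell is observed positive.
#' @export
true_positive_rate <- function(surface, offspring, N_t = NULL) {
  stopifnot(inherits(surface, "lik_surface"))
  I <- unclass(offspring)
  if (is.null(N_t)) N_t <- sum(I)
  obs <- surface$interior & I >= 1
  if (!any(obs)) {
    rlang::warn("No observed positives in the interior; TPR undefined.")
    return(NA_real_)
  }
  if (N_t == 0) return(0)
  # P(>= 1 infestation) = 1 - (1 - pi)^N, computed stably
  p_any <- -expm1(N_t * log1p(-pmin(surface$pi[obs], 1)))
  mean(p_any > 0.5)
}

#' Log-scale correlation between observed and expected infestation counts
#'
#' Pearson correlation of `log(observed count)` against `log(expected
#' count)`, where the expected count is the per-trial probability times the
#' focal year's total, `N_t * pi(x)`. Restricted to interior cells with at
#' least one observed infestation (`log 0` is undefined and no offset is
#' assumed); `mode = "log1p"` instead uses `log(1 + x)` on all interior
#' cells. Expected values are floored at the smallest positive double before
#' taking logs.
#'
#' @inheritParams true_positive_rate
#' @param mode `"positive"` (default) or `"log1p"`.
#' @return Pearson correlation, or `NA` (with a warning) for degenerate
#'   inputs (< 2 qualifying cells or zero variance).
#' @export
log_correlation <- function(surface, offspring, N_t = NULL,
                            mode = c("positive", "log1p")) {
  mode <- match.arg(mode)
  stopifnot(inherits(surface, "lik_surface"))
  I <- unclass(offspring)
  if (is.null(N_t)) N_t <- sum(I)
  if (mode == "positive") {
    sel <- surface$interior & I >= 1
    x <- log(I[sel])
    y <- log(pmax(N_t * surface$pi[sel], .Machine$double.xmin))
  } else {
    sel <- surface$interior
    x <- log1p(I[sel])
    y <- log1p(N_t * surface$pi[sel])
  }
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("Degenerate inputs; log-scale correlation undefined.")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Distance-stratified log likelihood
#'
#' Assigns each interior offspring record to a distance class by its
#' nearest-parent distance, and sums `n_trees * log(pi)` within each class.
#' The classes partition the records, so the per-bin sums add up to the
#' year's total log likelihood — this decomposition shows *where* (in
#' dispersal distance) a kernel earns or loses its fit.
#'
#' @param surface A [likelihood_surface()].
#' @param offspring_points Offspring point records (`x_km`, `y_km`,
#'   `n_trees`).
#' @param parent_points Parent point records.
#' @param breaks Increasing distance bin edges covering `[0, Inf)`.
#' @param spec Grid spec used to locate records in cells.
#' @return Tibble with `bin`, `lower`, `upper`, `loglik`, `n_trees`.
#' @export
stratified_loglik <- function(surface, offspring_points, parent_points,
                              breaks = c(0, 0.1, 0.5, 1, 5, Inf), spec) {
  stopifnot(inherits(surface, "lik_surface"), inherits(spec, "grid_spec"))
  if (breaks[1] != 0 || !is.infinite(breaks[length(breaks)]))
    rlang::abort("breaks must start at 0 and end at Inf.")
  d <- nearest_parent_distances(offspring_points, parent_points)
  idx <- point_cell_index(offspring_points, spec)
  ok <- idx$ix >= 1 & idx$ix <= spec$nx & idx$iy >= 1 & idx$iy <= spec$ny
  lin <- cbind(idx$iy, idx$ix)
  interior <- ok
  interior[ok] <- surface$interior[lin[ok, , drop = FALSE]]
  contrib <- rep(NA_real_, nrow(offspring_points))
  contrib[interior] <- offspring_points$n_trees[interior] *
    log(surface$pi[lin[interior, , drop = FALSE]])
  bin <- cut(d, breaks, right = FALSE, include.lowest = TRUE)
  tibble::tibble(bin = levels(bin),
                 lower = breaks[-length(breaks)], upper = breaks[-1]) |>
    dplyr::left_join(
      tibble::tibble(bin = as.character(bin[interior]),
                     ll = contrib[interior],
                     n = offspring_points$n_trees[interior]) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(loglik = sum(.data$ll), n_trees = sum(.data$n)),
      by = "bin") |>
    dplyr::mutate(loglik = dplyr::coalesce(.data$loglik, 0),
                  n_trees = dplyr::coalesce(.data$n_trees, 0))
}

#' Observed distance histogram against marginal kernels
#'
#' Density-normalised histogram of nearest-parent distances together with
#' each candidate kernel's marginal distance density `2*pi*r*D(r)` evaluated
#' at the bin midpoints, for visual model comparison.
#'
#' @param distances Nearest-parent distances, km.
#' @param kernels Named list of [dispersal_kernel()]s.
#' @param breaks Histogram bin edges (finite); defaults to 40 equal bins to
#'   the 99th percentile.
#' @return A `kernel_histogram` list: `histogram` tibble (`mid`, `lower`,
#'   `upper`, `density`) and `curves` tibble (`kernel`, `r`, `density`).
#' @export
histogram_vs_marginal <- function(distances, kernels, breaks = NULL) {
  if (length(distances) == 0) rlang::abort("No distances supplied.")
  if (is.null(breaks))
    breaks <- seq(0, stats::quantile(distances, 0.99), length.out = 41)
  h <- graphics::hist(pmin(distances, max(breaks)), breaks = breaks,
                      plot = FALSE)
  hist_tbl <- tibble::tibble(mid = h$mids, lower = breaks[-length(breaks)],
                             upper = breaks[-1], density = h$density)
  curves <- purrr::imap_dfr(kernels, function(k, nm)
    tibble::tibble(kernel = nm, r = h$mids,
                   density = 2 * pi * h$mids * kernel_pdf(k, h$mids)))
  structure(list(histogram = hist_tbl, curves = curves),
            class = "kernel_histogram")
}

#' Model-quality report for a fitted kernel
#'
#' Assembles the validation statistics for one kernel on one year stack:
#' total and per-year log likelihood, pooled true positive rate and
#' log-scale correlation across years, and the kernel's distance summaries
#' (mean and 50/75/95% quantiles) under a stated truncation radius.
#'
#' @inheritParams total_loglik
#' @param truncation Truncation radius (km) for the distance summaries, or
#'   `Inf`.
#' @return A list of class `validation_report` with elements `loglik`,
#'   `per_year`, `tpr`, `log_cor`, `distances` (tibble) and `truncation`.
#' @export
validation_report <- function(stack, kernel, years = NULL, buffer_km = 10,
                              half_width = NULL, truncation = Inf) {
  stopifnot(inherits(stack, "year_stack"))
  validate_kernel(kernel)
  spec <- stack$spec
  if (is.null(half_width)) half_width <- default_half_width(spec)
  stn <- kernel_stencil(kernel, spec$delta_x, half_width)
  interior <- interior_mask(spec, buffer_km)
  focal <- usable_transitions(stack, years)
  obs_all <- exp_all <- panyobs <- list()
  per <- purrr::map_dfr(focal, function(t) {
    par <- stack$I_star[[as.character(t - 1L)]]
    off <- unclass(stack$I[[as.character(t)]])
    surf <- likelihood_surface(beetle_potential(par, stn, spec = spec),
                               sum(par), interior, year = t)
    N_t <- sum(off)
    sel <- interior & off >= 1
    obs_all[[as.character(t)]] <<- off[sel]
    exp_all[[as.character(t)]] <<- pmax(N_t * surf$pi[sel],
                                        .Machine$double.xmin)
    panyobs[[as.character(t)]] <<-
      -expm1(N_t * log1p(-pmin(surf$pi[sel], 1)))
    tibble::tibble(year = t, loglik = year_loglik(surf, off),
                   n_obs = sum(off[interior]))
  })
  obs <- unlist(obs_all); expc <- unlist(exp_all); pany <- unlist(panyobs)
  tpr <- if (length(obs) == 0) NA_real_ else mean(pany > 0.5)
  r <- if (length(obs) < 2 || stats::sd(log(obs)) == 0) NA_real_ else
    stats::cor(log(obs), log(expc))
  qs <- c(0.5, 0.75, 0.95)
  distances <- tibble::tibble(
    statistic = c("mean", "q50", "q75", "q95"),
    km = c(kernel_mean_distance(kernel, truncation),
           kernel_quantile(kernel, qs, truncation)))
  structure(list(kernel = kernel, loglik = sum(per$loglik), per_year = per,
                 tpr = tpr, log_cor = r, distances = distances,
                 truncation = truncation, buffer_km = buffer_km),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$kernel$family, "\n", sep = "")
  cat(sprintf("  log likelihood %.4f | TPR %.3f | r(log) %.3f\n",
              x$loglik, x$tpr, x$log_cor))
  d <- stats::setNames(x$distances$km, x$distances$statistic)
  cat(sprintf("  distances (km): mean %.3g, median %.3g, 75%% %.3g, 95%% %.3g",
              d["mean"], d["q50"], d["q75"], d["q95"]),
      if (is.finite(x$truncation))
        sprintf(" (truncated at %g km)\n", x$truncation) else "\n")
  invisible(x)
}
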