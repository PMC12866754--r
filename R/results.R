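#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted kernel
#'
#' @param x A `kernel_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`);
#'   `glance()`: a one-row model summary (`family`, `logLik`, `n_params`,
#'   `n_obs`, `n_years`, `converged`, `evaluations`, `method`).
#' @export
tidy.kernel_fit <- function(x, ...) {
  tibble::tibble(term = names(x$kernel$params),
                 estimate = unlist(x$kernel$params, use.names = FALSE))
}

#' @rdname tidy.kernel_fit
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(family = x$kernel$family, logLik = x$loglik,
                 n_params = x$n_params, n_obs = x$n_obs,
                 n_years = nrow(x$per_year),
                 converged = x$trace$converged,
                 evaluations = x$trace$evaluations,
                 method = x$trace$method)
}

#' @export
tidy.validation_report <- function(x, ...) {
  tibble::tibble(
    statistic = c("loglik", "tpr", "log_cor", x$distances$statistic),
    value = c(x$loglik, x$tpr, x$log_cor, x$distances$km))
}

#' Plot methods for fitted kernels and diagnostics
#'
#' `autoplot.kernel_fit()` shows the likelihood profile (single-parameter
#' fits) or the per-year log-likelihood contributions.
#' `autoplot.kernel_histogram()` overlays candidate marginal kernels
#' `2*pi*r*D(r)` on the observed nearest-parent distance histogram.
#' `autoplot.spread_sim()` shows the invasion front (maximum easting by
#' year).
#'
#' @param object The object to plot.
#' @param polygon Optional polygon passed to [max_easting()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kernel_fit <- function(object, ...) {
  if (!is.null(object$profile)) {
    keep <- is.finite(object$profile$loglik)
    ggplot2::ggplot(object$profile[keep, ],
                    ggplot2::aes(x = .data$rho, y = .data$loglik)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$kernel$params$rho,
                          linetype = "dashed") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = expression(rho ~ "(km)"), y = "log likelihood",
                    title = paste("Likelihood profile:",
                                  object$kernel$family)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$per_year,
                    ggplot2::aes(x = factor(.data$year), y = .data$loglik)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "year", y = "log likelihood",
                    title = paste("Per-year fit:", object$kernel$family)) +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.kernel_fit
#' @export
autoplot.kernel_histogram <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_col(data = object$histogram,
                      ggplot2::aes(x = .data$mid, y = .data$density),
                      width = object$histogram$upper - object$histogram$lower,
                      fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = object$curves,
                       ggplot2::aes(x = .data$r, y = .data$density,
                                    colour = .data$kernel)) +
    ggplot2::labs(x = "nearest-parent distance (km)", y = "density",
                  colour = "kernel") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kernel_fit
#' @export
autoplot.spread_sim <- function(object, polygon = NULL, ...) {
  me <- max_easting(object, polygon)
  ggplot2::ggplot(me, ggplot2::aes(x = .data$year, y = .data$max_easting)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "simulation year", y = "maximum easting (km)",
                  title = paste("Range front:", object$kernel$family)) +
    ggplot2::theme_minimal()
}

#' Serialise a synthetic-history configuration
#'
#' Writes/reads a [synth_config()] as a YAML key-value file; the RNG seed is
#' always written explicitly so histories are reproducible from the file
#' alone. Habitat masks are not serialised (write them with
#' [write_grid_asc()]).
#'
#' @param config A [synth_config()].
#' @param path File path.
#' @return `read_synth_config()` returns a [synth_config()];
#'   `write_synth_config()` returns `config` invisibly.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  yaml::write_yaml(list(
    extent = config$extent, years = config$years,
    yearly_counts = config$yearly_counts,
    kernel = c(list(family = config$kernel$family), config$kernel$params),
    delta_x = config$delta_x, control_fraction = config$control_fraction,
    jitter_sd = config$jitter_sd, seed = config$seed), path)
  invisible(config)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  kern <- dispersal_kernel(y$kernel$family,
                           params = y$kernel[setdiff(names(y$kernel),
                                                     "family")])
  synth_config(extent = unlist(y$extent), years = unlist(y$years),
               yearly_counts = unlist(y$yearly_counts), kernel = kern,
               delta_x = y$delta_x, control_fraction = y$control_fraction,
               jitter_sd = y$jitter_sd, seed = y$seed)
}
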