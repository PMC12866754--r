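#' Interior (buffer) mask for a grid
#'
#' Marks cells whose centres lie at least `buffer_km` from every edge of the
#' grid's domain. Log-likelihood terms are restricted to this interior so
#' every modelled infestation can receive redistribution mass from all
#' directions; cells exactly at the buffer distance are included.
#'
#' @param spec A [grid_spec()].
#' @param buffer_km Buffer width, km (default 10, the width used for the
#'   roughly 50 x 50 km survey study areas; use less on smaller domains).
#' @return Logical `ny x nx` matrix.
#' @export
interior_mask <- function(spec, buffer_km = 10) {
  stopifnot(inherits(spec, "grid_spec"), buffer_km >= 0)
  ext <- grid_extent(spec)
  cc <- cell_centers(spec)
  okx <- cc$x - ext[1] >= buffer_km & ext[2] - cc$x >= buffer_km
  oky <- cc$y - ext[3] >= buffer_km & ext[4] - cc$y >= buffer_km
  m <- outer(oky, okx, "&")
  if (!any(m))
    rlang::abort("Buffer consumes the entire domain.",
                 class = "pestkern_error_buffer")
  m
}

#' Beetle-potential surface by kernel convolution
#'
#' Convolves a parent (uncontrolled-infestation) count grid with a kernel
#' stencil: `B(y) = sum over x of Istar(x) * w(y - x)`, the expected number
#' of offspring infestations arriving in each cell. The default FFT path
#' (zero-padded, so no wrap-around) agrees with direct summation to within
#' 1e-10 relative error; the `"direct"` path is O(n^2 K^2) and intended for
#' small grids and cross-checks.
#'
#' @param parents Parent count matrix (`ny x nx`).
#' @param stencil A [kernel_stencil()] whose `delta_x` matches the grid.
#' @param method `"fft"` or `"direct"`.
#' @param spec Optional [grid_spec()] for a `delta_x` consistency check.
#' @return Matrix of expected arrivals, same dimensions as `parents`.
#' @export
beetle_potential <- function(parents, stencil, method = c("fft", "direct"),
                             spec = attr(parents, "spec")) {
  method <- match.arg(method)
  stopifnot(inherits(stencil, "kernel_stencil"))
  if (!is.null(spec) && !isTRUE(all.equal(spec$delta_x,
                                          attr(stencil, "delta_x"))))
    rlang::abort("Stencil and grid delta_x differ.",
                 class = "pestkern_error_alignment")
  P <- unclass(parents)
  w <- unclass(stencil)
  K <- attr(stencil, "half_width")
  if (method == "fft") {
    ny <- nrow(P); nx <- ncol(P)
    py <- stats::nextn(ny + 2 * K, c(2, 3, 5))
    px <- stats::nextn(nx + 2 * K, c(2, 3, 5))
    A <- matrix(0, py, px); A[1:ny, 1:nx] <- P
    S <- matrix(0, py, px); S[1:(2 * K + 1), 1:(2 * K + 1)] <- w
    conv <- Re(stats::fft(stats::fft(A) * stats::fft(S), inverse = TRUE)) /
      (py * px)
    B <- conv[(K + 1):(K + ny), (K + 1):(K + nx), drop = FALSE]
    B[B < 0] <- 0  # clip FFT round-off
    B
  } else {
    ny <- nrow(P); nx <- ncol(P)
    B <- matrix(0, ny, nx)
    nz <- which(P > 0, arr.ind = TRUE)
    for (q in seq_len(nrow(nz))) {
      i <- nz[q, 1]; j <- nz[q, 2]
      ri <- max(1, i - K):min(ny, i + K)
      rj <- max(1, j - K):min(nx, j + K)
      B[ri, rj] <- B[ri, rj] +
        P[i, j] * w[ri - i + K + 1, rj - j + K + 1, drop = FALSE]
    }
    B
  }
}

#' Probability surface for offspring infestations
#'
#' Rescales a beetle-potential surface by the total number of parent
#' infestations, `pi_t(x) = B_t(x) / sum(Istar_{t-1})`, yielding the
#' probability mass function from which each offspring infestation is an
#' i.i.d. draw. With a full-width stencil the surface sums to one.
#'
#' @param B Beetle-potential matrix from [beetle_potential()].
#' @param source_total Total parent count `sum(Istar_{t-1})` (> 0).
#' @param interior Logical interior mask from [interior_mask()] (optional;
#'   defaults to all-`TRUE`).
#' @param year Focal year label.
#' @return A `lik_surface`: list with `pi`, `interior`, `source_total`,
#'   `year`.
#' @export
likelihood_surface <- function(B, source_total, interior = NULL,
                               year = NA_integer_) {
  if (source_total <= 0)
    rlang::abort("source_total must be positive (no parents: drop the year).",
                 class = "pestkern_error_no_parents")
  if (is.null(interior)) interior <- matrix(TRUE, nrow(B), ncol(B))
  structure(list(pi = unclass(B) / source_total, interior = interior,
                 source_total = source_total, year = year),
            class = "lik_surface")
}

#' Per-year log likelihood
#'
#' `L_t = sum over interior cells with I_t(x) > 0 of I_t(x) * log(pi_t(x))`.
#' An observed infestation in a cell where the model places zero probability
#' yields `-Inf` — the near-infinite penalty that distinguishes the
#' likelihood approach from least-squares fitting.
#'
#' @param surface A [likelihood_surface()].
#' @param offspring Offspring count matrix `I_t` (same dimensions).
#' @return Scalar log likelihood (possibly `-Inf`).
#' @export
year_loglik <- function(surface, offspring) {
  stopifnot(inherits(surface, "lik_surface"))
  I <- unclass(offspring)
  if (!all(dim(I) == dim(surface$pi)))
    rlang::abort("Offspring grid and surface are misaligned.",
                 class = "pestkern_error_alignment")
  sel <- surface$interior & I > 0
  if (!any(sel)) return(0)
  sum(I[sel] * log(surface$pi[sel]))
}

usable_transitions <- function(stack, years = NULL) {
  yrs <- stack$years
  if (!is.null(years)) yrs <- intersect(yrs, as.integer(years))
  focal <- yrs[(yrs - 1L) %in% yrs]
  keep <- vapply(focal, function(t)
    sum(stack$I_star[[as.character(t - 1L)]]) > 0, logical(1))
  if (any(!keep))
    rlang::warn(paste0("Dropping year(s) with no uncontrolled parents: ",
                       paste(focal[!keep], collapse = ", ")))
  focal[keep]
}

default_half_width <- function(spec) max(spec$nx, spec$ny) - 1L

#' Total log likelihood of a kernel over a year stack
#'
#' Builds the stencil once, then for each usable year transition convolves
#' the previous year's uncontrolled counts `Istar_{t-1}`, normalises to a
#' probability surface and accumulates `L_t` over interior offspring cells.
#' The total is `L = sum over t of L_t`.
#'
#' @param stack A [infestation_stack()] / [build_stack()] result.
#' @param kernel A [dispersal_kernel()].
#' @param years Optional subset of focal years.
#' @param buffer_km Buffer width, km.
#' @param half_width Stencil half-width in cells; default spans the grid.
#' @param method Convolution method (see [beetle_potential()]).
#' @return List with `total`, `per_year` (tibble: `year`, `loglik`, `n_obs`)
#'   and `n_obs`.
#' @export
total_loglik <- function(stack, kernel, years = NULL, buffer_km = 10,
                         half_width = NULL, method = "fft") {
  stopifnot(inherits(stack, "year_stack"))
  validate_kernel(kernel)
  spec <- stack$spec
  if (is.null(half_width)) half_width <- default_half_width(spec)
  stn <- kernel_stencil(kernel, spec$delta_x, half_width)
  interior <- interior_mask(spec, buffer_km)
  focal <- usable_transitions(stack, years)
  per <- purrr::map_dfr(focal, function(t) {
    par <- stack$I_star[[as.character(t - 1L)]]
    off <- stack$I[[as.character(t)]]
    B <- beetle_potential(par, stn, method = method, spec = spec)
    surf <- likelihood_surface(B, sum(par), interior, year = t)
    tibble::tibble(year = t, loglik = year_loglik(surf, off),
                   n_obs = sum(off[interior]))
  })
  list(total = sum(per$loglik), per_year = per, n_obs = sum(per$n_obs))
}

# ---- sparse likelihood path used for fitting --------------------------------
#
# The likelihood only needs pi at interior cells holding offspring, and pi
# there is a sum over occupied parent cells. Distances between those cell
# centres are fixed across optimizer iterations, so they are computed once;
# each evaluation is then one vectorised pdf call plus the stencil
# renormalisation total (octant decomposition). The result is algebraically
# identical to the full-grid stencil convolution, including the centre-cell
# mass at zero distance.
prep_transitions <- function(stack, years = NULL, buffer_km = 10,
                             half_width = NULL) {
  spec <- stack$spec
  if (is.null(half_width)) half_width <- default_half_width(spec)
  interior <- interior_mask(spec, buffer_km)
  cc <- cell_centers(spec)
  focal <- usable_transitions(stack, years)
  trans <- lapply(focal, function(t) {
    par <- stack$I_star[[as.character(t - 1L)]]
    off <- stack$I[[as.character(t)]]
    pidx <- which(par > 0, arr.ind = TRUE)
    oidx <- which(off > 0 & interior, arr.ind = TRUE)
    dmat <- if (nrow(oidx) > 0 && nrow(pidx) > 0) {
      sqrt(outer(cc$x[oidx[, 2]], cc$x[pidx[, 2]], "-")^2 +
           outer(cc$y[oidx[, 1]], cc$y[pidx[, 1]], "-")^2)
    } else matrix(0, 0, 0)
    list(year = t, dmat = dmat, zero = dmat == 0,
         pcount = par[pidx], ocount = off[oidx],
         N = sum(par), n_obs = sum(off[oidx]))
  })
  list(spec = spec, trans = trans,
       octant = stencil_octant(spec$delta_x, half_width))
}

loglik_sparse <- function(kernel, prep, per_year = FALSE) {
  dx2 <- prep$spec$delta_x^2
  raw <- stencil_raw_sum(kernel, prep$octant)
  cmass <- kernel_cell_mass(kernel, prep$spec$delta_x)
  rows <- lapply(prep$trans, function(tr) {
    if (length(tr$ocount) == 0)
      return(list(year = tr$year, loglik = 0, n_obs = 0))
    W <- kernel_pdf(kernel, tr$dmat) * dx2
    if (any(tr$zero)) W[tr$zero] <- cmass
    p <- as.numeric(W %*% tr$pcount) / (raw * tr$N)
    ll <- if (any(p == 0)) -Inf else sum(tr$ocount * log(p))
    list(year = tr$year, loglik = ll, n_obs = tr$n_obs)
  })
  total <- sum(vapply(rows, `[[`, numeric(1), "loglik"))
  if (!per_year) return(total)
  list(total = total,
       per_year = tibble::tibble(
         year = vapply(rows, `[[`, numeric(1), "year"),
         loglik = vapply(rows, `[[`, numeric(1), "loglik"),
         n_obs = vapply(rows, `[[`, numeric(1), "n_obs")))
}

# ---- parameter transforms ---------------------------------------------------

kernel_to_unconstrained <- function(kernel) {
  p <- kernel$params
  switch(kernel$family,
    gaussian = , laplace = , bessel = c(log_rho = log(p$rho)),
    wmy = c(log_rho = log(p$rho), log_kappa = log(p$kappa)),
    student_t = , pareto = c(log_rho = log(p$rho), log_num1 = log(p$nu - 1)),
    c(logit_theta = stats::qlogis(p$theta), log_rho1 = log(p$rho1),
      log_gap = log(p$rho2 - p$rho1)))
}

unconstrained_to_kernel <- function(family, v) {
  params <- switch(family,
    gaussian = , laplace = , bessel = list(rho = exp(v[1])),
    wmy = list(rho = exp(v[1]), kappa = exp(v[2])),
    student_t = , pareto = list(rho = exp(v[1]), nu = 1 + exp(v[2])),
    list(theta = stats::plogis(v[1]), rho1 = exp(v[2]),
         rho2 = exp(v[2]) + exp(v[3])))
  structure(list(family = family, params = params),
            class = "dispersal_kernel")
}

default_init <- function(family, prep) {
  # crude scale guess: median distance from offspring cells to the nearest
  # occupied parent cell in the first usable transition
  tr <- prep$trans[[1]]
  rho0 <- if (length(tr$ocount) > 0 && ncol(tr$dmat) > 0) {
    stats::median(apply(tr$dmat, 1, min))
  } else prep$spec$delta_x * 10
  rho0 <- max(rho0, prep$spec$delta_x / 2)
  switch(family,
    gaussian = , laplace = , bessel = dispersal_kernel(family, rho = rho0),
    wmy = dispersal_kernel(family, rho = rho0, kappa = 1),
    student_t = , pareto = dispersal_kernel(family, rho = rho0, nu = 2),
    dispersal_kernel(family, theta = 0.5, rho1 = rho0, rho2 = 10 * rho0))
}

#' Fit a dispersal kernel by maximum likelihood
#'
#' Maximises the total convolution log likelihood over the kernel's
#' parameters. Single-parameter families (`gaussian`, `laplace`, `bessel`)
#' are optimised on a high-resolution log-spaced likelihood profile (default
#' 200 points from `delta_x/10` to the domain width) followed by local
#' refinement; multi-parameter families use Nelder-Mead on unconstrained
#' transforms (`log` for scales, `log(nu - 1)`, `logit(theta)`, and
#' `rho2 = rho1 + exp(gap)` so the mixture ordering holds by construction),
#' with restarts from perturbed optima.
#'
#' @inheritParams total_loglik
#' @param family Kernel family name (see [dispersal_kernel()]).
#' @param init Optional [dispersal_kernel()] giving starting parameters.
#' @param profile_points Number of profile-grid points (1-parameter families).
#' @param restarts Nelder-Mead restarts from perturbed optima.
#' @param reltol,maxit Nelder-Mead control.
#' @return A `kernel_fit` object: fitted `kernel`, `loglik`, `per_year`
#'   tibble, `n_obs`, `trace` diagnostics and (for 1-parameter families) the
#'   likelihood `profile`.
#' @export
fit_kernel <- function(stack, family, init = NULL, years = NULL,
                       buffer_km = 10, half_width = NULL,
                       profile_points = 200, restarts = 3,
                       reltol = 1e-8, maxit = 2000) {
  stopifnot(inherits(stack, "year_stack"))
  family <- match.arg(family, kernel_families())
  prep <- prep_transitions(stack, years, buffer_km, half_width)
  if (length(prep$trans) == 0)
    rlang::abort("No usable year transitions.",
                 class = "pestkern_error_no_parents")
  if (is.null(init)) init <- default_init(family, prep)
  if (init$family != family) rlang::abort("init kernel family mismatch.")

  n_eval <- 0L
  objective <- function(v) {
    n_eval <<- n_eval + 1L
    k <- unconstrained_to_kernel(family, v)
    ok <- tryCatch({ validate_kernel(k); TRUE }, error = function(e) FALSE)
    if (!ok) return(-1e300)
    ll <- loglik_sparse(k, prep)
    if (!is.finite(ll)) -1e300 else ll
  }

  one_param <- family %in% c("gaussian", "laplace", "bessel")
  profile <- NULL
  if (one_param) {
    ext <- grid_extent(prep$spec)
    hi <- max(ext[2] - ext[1], ext[4] - ext[3])
    grid <- exp(seq(log(prep$spec$delta_x / 10), log(hi),
                    length.out = profile_points))
    ll <- vapply(grid, function(r) objective(log(r)), numeric(1))
    profile <- tibble::tibble(rho = grid, loglik = ll)
    best <- which.max(ll)
    lo <- log(grid[max(1, best - 1)]); up <- log(grid[min(length(grid), best + 1)])
    opt <- stats::optimize(objective, lower = lo, upper = up, maximum = TRUE,
                           tol = 1e-8)
    vhat <- opt$maximum
    Lhat <- opt$objective
    converged <- TRUE
    method <- "profile"
  } else {
    v0 <- kernel_to_unconstrained(init)
    best_fit <- NULL
    start <- v0
    for (s in seq_len(restarts + 1)) {
      o <- stats::optim(start, objective, method = "Nelder-Mead",
                        control = list(fnscale = -1, reltol = reltol,
                                       maxit = maxit))
      if (is.null(best_fit) || o$value > best_fit$value) best_fit <- o
      # deterministic perturbation of the incumbent optimum
      start <- best_fit$par + 0.5 * (-1)^(s + seq_along(v0))
    }
    vhat <- best_fit$par
    Lhat <- best_fit$value
    converged <- best_fit$convergence == 0
    method <- "nelder_mead"
  }

  khat <- unconstrained_to_kernel(family, vhat)
  validate_kernel(khat)
  per <- loglik_sparse(khat, prep, per_year = TRUE)
  structure(list(kernel = khat, loglik = per$total, per_year = per$per_year,
                 n_obs = sum(per$per_year$n_obs),
                 n_params = length(kernel_param_names(family)),
                 trace = list(evaluations = n_eval, converged = converged,
                              method = method),
                 profile = profile, buffer_km = buffer_km,
                 delta_x = prep$spec$delta_x),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit> ", x$kernel$family, "\n", sep = "")
  pars <- paste(names(x$kernel$params), signif(unlist(x$kernel$params), 4),
                sep = " = ", collapse = ", ")
  cat("  parameters: ", pars, "\n", sep = "")
  cat(sprintf("  log likelihood: %.4f over %d offspring trees (%d year(s))\n",
              x$loglik, x$n_obs, nrow(x$per_year)))
  invisible(x)
}

#' Two-generation (multivoltine) probability surface
#'
#' Extends the single-generation model to bivoltine species: the first
#' kernel is convolved with the uncontrolled parents to give the
#' first-generation surface `pi1`; convolving `pi1` with the second kernel
#' gives the second-generation surface; the prediction is the mixture
#' `w1 * pi1 + w2 * (pi1 conv stencil2)`, weighted by the expected
#' reproductive output of each generation.
#'
#' @param parents Parent count matrix `Istar_{t-1}`.
#' @param kernel1,kernel2 Generation-specific [dispersal_kernel()]s.
#' @param w1,w2 Non-negative generation weights summing to one.
#' @inheritParams total_loglik
#' @param spec Grid spec of `parents`.
#' @return A `lik_surface`.
#' @export
two_generation_surface <- function(parents, kernel1, kernel2, w1, w2,
                                   spec = attr(parents, "spec"),
                                   buffer_km = 10, half_width = NULL,
                                   method = "fft") {
  if (w1 < 0 || w2 < 0 || abs(w1 + w2 - 1) > 1e-9)
    rlang::abort("Weights must be non-negative and sum to one.",
                 class = "pestkern_error_params")
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(half_width)) half_width <- default_half_width(spec)
  s1 <- kernel_stencil(kernel1, spec$delta_x, half_width)
  s2 <- kernel_stencil(kernel2, spec$delta_x, half_width)
  N <- sum(parents)
  pi1 <- beetle_potential(parents, s1, method = method, spec = spec) / N
  pi2 <- beetle_potential(pi1, s2, method = method, spec = spec)
  # the second convolution can push mass past the grid edge; renormalise it
  # back to the first surface's total, as the stencil itself does
  pi2 <- pi2 * (sum(pi1) / sum(pi2))
  structure(list(pi = w1 * pi1 + w2 * pi2,
                 interior = interior_mask(spec, buffer_km),
                 source_total = N, year = NA_integer_),
            class = "lik_surface")
}
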