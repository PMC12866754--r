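# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms and fast paths.

# marginal-distance normalisation / CDF by adaptive quadrature of 2*pi*r*D(r)
quad_marginal <- function(kernel, lower = 0, upper = Inf) {
  stats::integrate(function(r) 2 * pi * r * kernel_pdf(kernel, r),
                   lower, upper, rel.tol = 1e-10)$value
}

# Gaussian-scale-mixture samplers: the diffusion derivations of the kernels,
# independent of the inverse-CDF sampling path.
# Student's t: 2D normal with inverse-gamma variances,
#   sigma^2 = (nu*rho^2/2) / Gamma((nu - 1)/2, rate = 1)
sample_t_mixture <- function(n, rho, nu) {
  s2 <- (nu * rho^2 / 2) / stats::rgamma(n, shape = (nu - 1) / 2, rate = 1)
  sqrt(stats::rnorm(n, 0, sqrt(s2))^2 + stats::rnorm(n, 0, sqrt(s2))^2)
}

# Bessel: 2D Fickian diffusion with exponential settling time,
#   position ~ N(0, 2*rho^2*t), t ~ Exp(1)
sample_bessel_mixture <- function(n, rho) {
  s <- sqrt(2 * rho^2 * stats::rexp(n))
  sqrt(stats::rnorm(n, 0, s)^2 + stats::rnorm(n, 0, s)^2)
}

# brute-force convolution + likelihood pipeline: literal double loops over
# the defining sums (B, pi, L) with D evaluated between cell centres and the
# same centre-cell mass and stencil renormalisation contract
brute_force_pipeline <- function(parents, offspring, kernel, spec,
                                 buffer_km) {
  K <- max(spec$nx, spec$ny) - 1L
  off <- seq(-K, K)
  r <- spec$delta_x * sqrt(outer(off^2, off^2, "+"))
  w <- kernel_pdf(kernel, r) * spec$delta_x^2
  w[K + 1, K + 1] <- kernel_cell_mass(kernel, spec$delta_x)
  w <- w / sum(w)
  cc <- cell_centers(spec)
  B <- matrix(0, spec$ny, spec$nx)
  for (iy in seq_len(spec$ny)) for (ix in seq_len(spec$nx)) {
    acc <- 0
    for (jy in seq_len(spec$ny)) for (jx in seq_len(spec$nx)) {
      if (parents[jy, jx] > 0) {
        acc <- acc + parents[jy, jx] * w[iy - jy + K + 1, ix - jx + K + 1]
      }
    }
    B[iy, ix] <- acc
  }
  pi_t <- B / sum(parents)
  ext <- c(spec$origin[1], spec$origin[1] + spec$nx * spec$delta_x,
           spec$origin[2], spec$origin[2] + spec$ny * spec$delta_x)
  L <- 0
  for (iy in seq_len(spec$ny)) for (ix in seq_len(spec$nx)) {
    inside <- cc$x[ix] - ext[1] >= buffer_km && ext[2] - cc$x[ix] >= buffer_km &&
      cc$y[iy] - ext[3] >= buffer_km && ext[4] - cc$y[iy] >= buffer_km
    if (inside && offspring[iy, ix] > 0) {
      L <- L + offspring[iy, ix] * log(pi_t[iy, ix])
    }
  }
  list(B = B, pi = pi_t, loglik = L)
}

# quick synthetic stack for likelihood tests
make_history <- function(kernel, extent = c(0, 10, 0, 10), delta_x = 0.1,
                         years = 2001:2004, counts = c(80, 300, 300, 300),
                         control_fraction = 0.2, jitter_sd = 0, seed = 42,
                         habitat = NULL) {
  cfg <- synth_config(extent = extent, years = years, yearly_counts = counts,
                      kernel = kernel, delta_x = delta_x,
                      control_fraction = control_fraction,
                      jitter_sd = jitter_sd, habitat = habitat, seed = seed)
  generate_history(cfg)
}

random_valid_kernel <- function(family) {
  rho <- stats::runif(1, 0.05, 2)
  switch(family,
    gaussian = , laplace = , bessel = dispersal_kernel(family, rho = rho),
    wmy = dispersal_kernel(family, rho = rho,
                           kappa = stats::runif(1, 0.1, 3)),
    student_t = , pareto = dispersal_kernel(family, rho = rho,
                                            nu = stats::runif(1, 1.1, 5)),
    dispersal_kernel(family, theta = stats::runif(1, 0.05, 0.95),
                     rho1 = rho, rho2 = rho * stats::runif(1, 1.5, 20)))
}
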