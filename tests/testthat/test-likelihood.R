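small_spec <- function(n = 20, dx = 0.5) grid_spec(c(0, 0), dx, n, n)

test_that("interior mask keeps cells at least the buffer from every edge", {
  spec <- grid_spec(c(0, 0), delta_x = 1, nx = 50, ny = 50)
  m <- interior_mask(spec, buffer_km = 10)
  # 50 x 50 km domain with a 10 km buffer leaves the central 30 x 30 block
  expect_equal(sum(m), 30 * 30)
  cc <- cell_centers(spec)
  expect_true(all(cc$x[colSums(m) > 0] >= 10 & cc$x[colSums(m) > 0] <= 40))
  expect_true(all(interior_mask(spec, 0)))
  # centres exactly at the buffer distance are included
  spec2 <- grid_spec(c(0, 0), delta_x = 1, nx = 21, ny = 21)
  m2 <- interior_mask(spec2, buffer_km = 10.5)
  expect_equal(sum(m2), 1)
  expect_error(interior_mask(spec2, buffer_km = 11),
               class = "pestkern_error_buffer")
})

test_that("a single unit parent reproduces the stencil; convolution is linear", {
  spec <- small_spec(21, 0.5)
  k <- dispersal_kernel("gaussian", rho = 1)
  stn <- kernel_stencil(k, 0.5, 10)
  P <- matrix(0, 21, 21); P[11, 11] <- 1
  B <- beetle_potential(P, stn, spec = spec)
  expect_equal(B, unclass(stn), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(B), 1, tolerance = 1e-9)
  B2 <- beetle_potential(2 * P, stn, spec = spec)
  expect_equal(B2, 2 * B, tolerance = 1e-12)
})

test_that("FFT convolution equals direct summation", {
  withr::local_seed(41)
  spec <- grid_spec(c(0, 0), 0.25, 64, 64)
  P <- matrix(rpois(64 * 64, 0.2), 64, 64)
  for (family in c("gaussian", "student_t")) {
    k <- if (family == "gaussian") dispersal_kernel(family, rho = 1) else
      dispersal_kernel(family, rho = 0.3, nu = 1.6)
    stn <- kernel_stencil(k, 0.25, 63)
    Bf <- beetle_potential(P, stn, method = "fft", spec = spec)
    Bd <- beetle_potential(P, stn, method = "direct", spec = spec)
    expect_lt(max(abs(Bf - Bd)) / max(Bd), 1e-10)
  }
})

test_that("translation equivariance: shifting parents shifts the potential", {
  spec <- small_spec(30, 0.5)
  k <- dispersal_kernel("laplace", rho = 0.8)
  stn <- kernel_stencil(k, 0.5, 29)
  P <- matrix(0, 30, 30); P[8, 9] <- 2; P[12, 15] <- 1
  Ps <- matrix(0, 30, 30); Ps[8 + 3, 9 + 4] <- 2; Ps[12 + 3, 15 + 4] <- 1
  B <- beetle_potential(P, stn, spec = spec)
  Bs <- beetle_potential(Ps, stn, spec = spec)
  expect_equal(Bs[(1 + 3):30, (1 + 4):30], B[1:(30 - 3), 1:(30 - 4)],
               tolerance = 1e-10)
})

test_that("probability surfaces normalise and average shifted stencils", {
  spec <- small_spec(21, 0.5)
  k <- dispersal_kernel("gaussian", rho = 1)
  # stencil window kept inside the grid so no mass escapes the domain
  stn <- kernel_stencil(k, 0.5, 8)
  P <- matrix(0, 21, 21); P[10, 10] <- 1; P[12, 9] <- 1; P[11, 13] <- 1
  B <- beetle_potential(P, stn, spec = spec)
  surf <- likelihood_surface(B, sum(P), year = 2001L)
  expect_equal(sum(surf$pi), 1, tolerance = 1e-9)
  # pi is the average of one stencil per parent
  manual <- matrix(0, 21, 21)
  for (ij in list(c(10, 10), c(12, 9), c(11, 13))) {
    Pi <- matrix(0, 21, 21); Pi[ij[1], ij[2]] <- 1
    manual <- manual + beetle_potential(Pi, stn, spec = spec) / 3
  }
  expect_equal(surf$pi, manual, tolerance = 1e-10)
  # a corner parent loses mass past the domain edge: sum strictly below one
  Pc <- matrix(0, 21, 21); Pc[1, 1] <- 1
  Bc <- beetle_potential(Pc, kernel_stencil(k, 0.5, 20), spec = spec)
  expect_lt(sum(Bc), 1)
  expect_error(likelihood_surface(B, 0), class = "pestkern_error_no_parents")
})

test_that("year log likelihood follows the masked weighted-log contract", {
  spec <- small_spec(10, 1)
  pi_t <- matrix(1e-6, 10, 10); pi_t[5, 5] <- 0.01; pi_t[5, 6] <- 0.02
  interior <- interior_mask(spec, 2)
  surf <- structure(list(pi = pi_t, interior = interior, source_total = 10,
                         year = 2001L), class = "lik_surface")
  I <- matrix(0, 10, 10); I[5, 5] <- 1
  expect_equal(year_loglik(surf, I), log(0.01))
  I[5, 5] <- 2
  expect_equal(year_loglik(surf, I), 2 * log(0.01))
  I[5, 6] <- 3
  expect_equal(year_loglik(surf, I), 2 * log(0.01) + 3 * log(0.02))
  # offspring only in the buffer contribute nothing
  Ib <- matrix(0, 10, 10); Ib[1, 1] <- 5
  expect_equal(year_loglik(surf, Ib), 0)
  # zero probability at an observed cell is an infinite penalty
  surf$pi[5, 5] <- 0
  expect_identical(year_loglik(surf, I), -Inf)
})

test_that("composed pipeline equals the brute-force double loop", {
  withr::local_seed(42)
  spec <- grid_spec(c(0, 0), 0.5, 12, 12)
  parents <- matrix(rpois(144, 0.15), 12, 12)
  offspring <- matrix(rpois(144, 0.2), 12, 12)
  while (sum(parents) == 0) parents <- matrix(rpois(144, 0.15), 12, 12)
  k <- dispersal_kernel("laplace", rho = 0.7)
  oracle <- brute_force_pipeline(parents, offspring, k, spec, buffer_km = 1)
  stn <- kernel_stencil(k, 0.5, 11)
  B <- beetle_potential(parents, stn, spec = spec)
  expect_equal(B, oracle$B, tolerance = 1e-9)
  surf <- likelihood_surface(B, sum(parents), interior_mask(spec, 1))
  expect_equal(year_loglik(surf, offspring), oracle$loglik, tolerance = 1e-9)
})

test_that("total log likelihood adds per-year terms and ignores year order", {
  k <- dispersal_kernel("gaussian", rho = 0.5)
  h <- make_history(k, delta_x = 0.2, seed = 43)
  spec <- grid_spec_from_extent(c(0, 10, 0, 10), 0.2)
  st <- infestation_stack(h, spec)
  tl <- total_loglik(st, k, buffer_km = 1)
  expect_equal(tl$total, sum(tl$per_year$loglik))
  # independent per-year recomputation
  stn <- kernel_stencil(k, 0.2, pestkern:::default_half_width(spec))
  interior <- interior_mask(spec, 1)
  for (i in seq_len(nrow(tl$per_year))) {
    t <- tl$per_year$year[i]
    par <- st$I_star[[as.character(t - 1)]]
    surf <- likelihood_surface(beetle_potential(par, stn, spec = spec),
                               sum(par), interior)
    expect_equal(tl$per_year$loglik[i],
                 year_loglik(surf, st$I[[as.character(t)]]),
                 tolerance = 1e-9)
  }
  # reordering years in the stack changes nothing
  st2 <- st
  ord <- rev(seq_along(st$years))
  st2$years <- st$years[ord]
  expect_equal(total_loglik(st2, k, buffer_km = 1)$total, tl$total)
})

test_that("sparse fitting path equals the full-grid convolution likelihood", {
  h <- make_history(dispersal_kernel("laplace", rho = 0.4), delta_x = 0.2,
                    seed = 44)
  spec <- grid_spec_from_extent(c(0, 10, 0, 10), 0.2)
  st <- infestation_stack(h, spec)
  prep <- pestkern:::prep_transitions(st, buffer_km = 1)
  for (k in list(dispersal_kernel("laplace", rho = 0.4),
                 dispersal_kernel("student_t", rho = 0.1, nu = 1.5),
                 dispersal_kernel("bessel", rho = 0.3))) {
    expect_equal(pestkern:::loglik_sparse(k, prep),
                 total_loglik(st, k, buffer_km = 1)$total,
                 tolerance = 1e-10, info = k$family)
  }
})

test_that("likelihood is invariant to splitting counts across records", {
  spec <- grid_spec(c(0, 0), 0.5, 10, 10)
  base <- tibble::tibble(x_km = c(2.2, 3.1), y_km = c(2.4, 2.9),
                         year = c(2001L, 2002L), n_trees = c(2L, 3L),
                         status = "red")
  split <- tibble::tibble(x_km = c(2.2, 2.2, 3.1, 3.1, 3.1),
                          y_km = c(2.4, 2.4, 2.9, 2.9, 2.9),
                          year = c(2001L, 2001L, rep(2002L, 3)),
                          n_trees = 1L, status = "red")
  k <- dispersal_kernel("gaussian", rho = 0.8)
  t1 <- total_loglik(infestation_stack(base, spec), k, buffer_km = 0.5)
  t2 <- total_loglik(infestation_stack(split, spec), k, buffer_km = 0.5)
  expect_equal(t1$total, t2$total)
})

test_that("profile and Nelder-Mead agree for a single-parameter family", {
  k <- dispersal_kernel("gaussian", rho = 0.5)
  h <- make_history(k, delta_x = 0.1, counts = c(80, 400, 400, 400),
                    seed = 45)
  spec <- grid_spec_from_extent(c(0, 10, 0, 10), 0.1)
  st <- infestation_stack(h, spec)
  fit_p <- fit_kernel(st, "gaussian", buffer_km = 1, profile_points = 120)
  expect_equal(fit_p$trace$method, "profile")
  expect_false(is.null(fit_p$profile))
  # direct 1D optimisation over log(rho) as cross-check
  prep <- pestkern:::prep_transitions(st, buffer_km = 1)
  opt <- stats::optimize(function(lr)
    pestkern:::loglik_sparse(dispersal_kernel("gaussian", rho = exp(lr)), prep),
    lower = log(0.05), upper = log(5), maximum = TRUE, tol = 1e-9)
  expect_equal(fit_p$kernel$params$rho, exp(opt$maximum), tolerance = 1e-3)
  expect_equal(fit_p$loglik, opt$objective, tolerance = 1e-6)
})

test_that("fitting is robust to a far-off initial guess", {
  k <- dispersal_kernel("student_t", rho = 0.1, nu = 2)
  h <- make_history(k, delta_x = 0.1, counts = c(60, 300, 300, 300),
                    jitter_sd = 0, seed = 46)
  spec <- grid_spec_from_extent(c(0, 10, 0, 10), 0.1)
  st <- infestation_stack(h, spec)
  f1 <- fit_kernel(st, "student_t", buffer_km = 1)
  f2 <- fit_kernel(st, "student_t", buffer_km = 1,
                   init = dispersal_kernel("student_t",
                                           rho = 0.1 * 100, nu = 4))
  expect_equal(f2$kernel$params$rho, f1$kernel$params$rho, tolerance = 0.02)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-5)
})

test_that("tidy and glance summarise fits in broom style", {
  k <- dispersal_kernel("gaussian", rho = 0.5)
  h <- make_history(k, delta_x = 0.2, seed = 47)
  st <- infestation_stack(h, grid_spec_from_extent(c(0, 10, 0, 10), 0.2))
  fit <- fit_kernel(st, "gaussian", buffer_km = 1, profile_points = 60)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, "rho")
  gl <- glance(fit)
  expect_equal(gl$n_params, 1)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("two-generation surfaces stay normalised and reduce correctly", {
  spec <- small_spec(15, 0.5)
  P <- matrix(0, 15, 15); P[8, 8] <- 3; P[7, 9] <- 1
  k1 <- dispersal_kernel("gaussian", rho = 0.5)
  k2 <- dispersal_kernel("laplace", rho = 0.3)
  s12 <- two_generation_surface(P, k1, k2, w1 = 0.7, w2 = 0.3, spec = spec,
                                buffer_km = 0.5)
  expect_equal(sum(s12$pi), 1, tolerance = 1e-9)
  # w2 = 0 reduces to the single-generation surface
  s1 <- two_generation_surface(P, k1, k2, w1 = 1, w2 = 0, spec = spec,
                               buffer_km = 0.5)
  stn1 <- kernel_stencil(k1, 0.5, pestkern:::default_half_width(spec))
  ref <- beetle_potential(P, stn1, spec = spec) / sum(P)
  expect_equal(s1$pi, ref, tolerance = 1e-10)
  # a point-mass second kernel is an identity convolution
  s_pt <- two_generation_surface(P, k1,
                                 dispersal_kernel("gaussian", rho = 1e-8),
                                 w1 = 0.4, w2 = 0.6, spec = spec,
                                 buffer_km = 0.5)
  expect_equal(s_pt$pi, ref, tolerance = 1e-7)
  expect_error(two_generation_surface(P, k1, k2, w1 = 0.5, w2 = 0.6,
                                      spec = spec),
               class = "pestkern_error_params")
})
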