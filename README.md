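# pestkern

Dispersal-kernel estimation and stochastic spread simulation for forest
pests surveyed as yearly infestation maps.

Aerial surveys of pests like the mountain pine beetle record where trees
were killed each year. Those maps carry a dispersal signal: this year's
infestations scatter around last year's according to a *redistribution
kernel* — a radially symmetric 2D density `D(r)` over offspring
displacement. `pestkern` is for ecologists and forest managers who want to
estimate that kernel from survey point records, compare thin-tailed,
fat-tailed and mixture kernel families, and project multi-year spread.

The core model: rasterise point records into per-year counts `I_t(x)`
(infested = controlled this year + red-topped next year,
`I_t = c_t + r_{t+1}`), convolve the uncontrolled parents with the kernel
to get the expected arrivals

    B_t(y) = sum_x I*_{t-1}(x) D(||y - x||) dx^2,

normalise to a probability surface `pi_t = B_t / sum(I*_{t-1})`, and score

    L_t = sum_{x : I_t(x) > 0} I_t(x) log pi_t(x)

over cells a buffer distance from the domain edge, summed across years.
Kernels are fit by maximum likelihood (likelihood profiles for 1-parameter
families, Nelder-Mead on transformed parameters otherwise). Nine families
are implemented — Gaussian, Laplace, Bessel, Whittle-Matérn-Yasuda,
Student's t ("2Dt"), Pareto, and Gaussian/Laplace/Bessel mixtures — with
exact normalisation, closed-form marginal CDFs, quantiles, means, samplers
and grid stencils. Because real survey data are access-restricted, the
package includes a first-class synthetic-data generator with the same
statistical structure, so the whole pipeline is testable end to end.

## Worked example

Generate a five-year synthetic epidemic from a fat-tailed kernel, fit two
candidate families, and compare them:

```r
library(pestkern)

kt <- dispersal_kernel("student_t", rho = 0.012, nu = 1.45)
cfg <- synth_config(extent = c(0, 10, 0, 10), years = 2015:2019,
                    yearly_counts = c(200, 600, 800, 1000, 1200),
                    kernel = kt, delta_x = 0.03, seed = 42)
history <- generate_history(cfg)   # tibble: x_km, y_km, year, n_trees, status

spec  <- grid_spec_from_extent(c(0, 10, 0, 10), delta_x = 0.03)
stack <- infestation_stack(history, spec)

fit_t <- fit_kernel(stack, "student_t", buffer_km = 1)
fit_g <- fit_kernel(stack, "gaussian",  buffer_km = 1)
dplyr::bind_rows(glance(fit_t), glance(fit_g))
#> # A tibble: 2 × 8
#>   family     logLik n_params n_obs n_years converged evaluations method
#>   <chr>       <dbl>    <int> <dbl>   <int> <lgl>           <int> <chr>
#> 1 student_t -24056.        2  2284       4 TRUE              178 nelder_mead
#> 2 gaussian  -25003.        1  2284       4 TRUE              210 profile
```

The fat-tailed Student's t beats the Gaussian by ~950 log-likelihood units
on the same 2,284 offspring trees: the Gaussian must inflate its scale to
`rho = 0.207` km to avoid near-infinite penalties at the few long-distance
infestations, while the Student's t keeps most mass at short range.
`tidy(fit_t)` gives `rho = 0.0346`, `nu = 2.02` — larger than the
generating `rho = 0.012` because the estimate absorbs the generator's 30 m
positional jitter and the 30 m cell size (see the vignette on sub-pixel
bias).

```r
report <- validation_report(stack, fit_t$kernel, buffer_km = 1,
                            truncation = 10)
report
#> <validation_report> student_t
#>   log likelihood -24055.6529 | TPR 0.000 | r(log) 0.113
#>   distances (km): mean 0.239, median 0.0831, 75% 0.182, 95% 0.855  (truncated at 10 km)
```

The report gives the true-positive rate under the Bernoulli-complement
rule (a cell is predicted positive when the chance of at least one of the
year's `N_t` infestations landing there exceeds 1/2), the log-scale
correlation between observed and expected counts, and the kernel's distance
summaries under a stated truncation. `autoplot()` methods plot likelihood
profiles, nearest-parent distance histograms against candidate marginal
kernels (`histogram_vs_marginal()`), and simulated invasion fronts.

To project spread, `simulate_spread()` draws each year's (exogenously
prescribed) infestation total as a multinomial over the current
redistribution surface, constrained to a habitat mask, and `max_easting()`
tracks the invasion front inside an analysis polygon — fat-tailed kernels
produce the occasional long jump that founds new patches ahead of the
front, where thin-tailed fronts only creep.

Thin command-line wrappers over these functions (`fit.R`, `validate.R`,
`simulate.R`) live in `inst/cli/`.

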