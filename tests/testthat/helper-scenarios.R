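# Shared fixtures, built in code.  Heavier objects are memoised per test
# file so parameterised blocks can reuse them.

# analytic Gompertz hazard completed into a smooth_hazard on a fine grid
gompertz_hazard <- function(a, b, lo = 31, hi = 110, step = 0.01) {
  grid <- seq(lo, hi, by = step)
  survival_and_density(grid, a * exp(b * grid))
}

# constant-hazard smooth_hazard
constant_hazard <- function(mu, lo = 31, hi = 110, step = 0.01) {
  grid <- seq(lo, hi, by = step)
  survival_and_density(grid, rep(mu, length(grid)))
}

# reduced two-stratum scenario for pipeline-level tests: full age range,
# shorter calendar window, one class per sex
small_params <- function(years = 1991:2010, exposure = 2e4, seed = 7L) {
  p <- finnish_like_params(years = years, exposure = exposure, seed = seed)
  keep <- p$strata$stratum %in% c("male_upper_nonmanual", "female_manual")
  scenario_params(p$strata[keep, ], ages = p$ages, years = years,
                  exposure = exposure, seed = seed)
}

local_small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(small_params())
      cache <<- list(
        ds = ds,
        run = suppressMessages(run_full(ds, pipeline_config(
          reference_class = NULL, verbose = FALSE))))
    }
    cache
  }
})

# reference Gompertz used throughout the analytic-oracle tests
GOMP_A <- 1.068e-5
GOMP_B <- 0.11
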