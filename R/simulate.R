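#' Gompertz-Makeham scenario parameters for a stratified mortality surface
#'
#' Each stratum follows a Gompertz-Makeham hazard with proportional annual
#' improvement in the senescent (Gompertz) level:
#' \deqn{\mu_s(x, t) = c_s (1 - r_{c,s})^{t - t_0} +
#'       a_s (1 - r_s)^{t - t_0} e^{b_s x}}
#' where \eqn{x} is age, \eqn{t} calendar year and \eqn{t_0} the first year.
#' With \eqn{c = 0} the age-at-death mode has the closed form
#' \eqn{\log(b/a(t))/b}, which moves upward approximately linearly in time —
#' the mechanism used to emulate steadily improving period mortality.
#'
#' @param strata `data.frame` with columns `stratum`, `sex`, `class`,
#'   `a` (Gompertz level at the reference year, deaths per person-year),
#'   `b` (Gompertz slope per year of age), `c` (Makeham background level,
#'   default 0), `r` (proportional annual decline in `a`, in `[0, 1)`),
#'   `r_c` (annual decline in `c`, default 0).
#' @param ages Consecutive integer ages, at least 10 of them (default 31:110).
#' @param years Consecutive integer calendar years, at least 2.
#' @param exposure Person-years per cell: a scalar or a vector over `ages`.
#' @param seed Integer seed used when deaths are sampled.
#' @return An object of class `scenario_params`.
#' @export
scenario_params <- function(strata, ages = 31:110, years, exposure = 2e4,
                            seed = 1L) {
  stopifnot(is.data.frame(strata),
            all(c("stratum", "sex", "class", "a", "b", "r") %in% names(strata)))
  if (is.null(strata$c)) strata$c <- 0
  if (is.null(strata$r_c)) strata$r_c <- 0
  if (any(strata$a <= 0) || any(strata$b <= 0)) {
    stop("Gompertz parameters `a` and `b` must be strictly positive")
  }
  if (any(strata$c < 0)) stop("Makeham level `c` must be nonnegative")
  if (any(strata$r < 0 | strata$r >= 1) || any(strata$r_c < 0 | strata$r_c >= 1)) {
    stop("improvement rates must lie in [0, 1)")
  }
  if (anyDuplicated(strata$stratum)) stop("stratum labels must be unique")
  ages <- as.integer(ages); years <- as.integer(years)
  if (length(ages) < 10L) stop("need at least 10 ages")
  if (length(years) < 2L) stop("need at least 2 years")
  if (any(diff(ages) != 1L) || any(diff(years) != 1L)) {
    stop("ages and years must be consecutive single-year grids")
  }
  if (length(exposure) == 1L) exposure <- rep(exposure, length(ages))
  if (length(exposure) != length(ages) || any(exposure < 0)) {
    stop("`exposure` must be a nonnegative scalar or one value per age")
  }
  p <- structure(list(strata = strata, ages = ages, years = years,
                      exposure = exposure, seed = as.integer(seed)),
                 class = "scenario_params")
  # every stratum's true mode must sit strictly inside the age range in
  # every year, otherwise downstream mode estimates hit the grid boundary
  for (s in strata$stratum) {
    for (yr in range(years)) {
      M <- true_modal_age(p, s, yr)
      if (M <= min(ages) + 1 || M >= max(ages) - 1) {
        stop(sprintf("true modal age %.1f for stratum '%s' in %d is not interior",
                     M, s, yr))
      }
    }
  }
  p
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf("Gompertz-Makeham scenario: %d strata, ages %d-%d, years %d-%d\n",
              nrow(x$strata), min(x$ages), max(x$ages),
              min(x$years), max(x$years)))
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' True hazard surface for one stratum of a scenario
#'
#' @param params A [scenario_params()].
#' @param stratum Stratum label.
#' @return Matrix of hazards, ages in rows, years in columns.
#' @export
hazard_surface <- function(params, stratum) {
  stopifnot(inherits(params, "scenario_params"))
  i <- match(stratum, params$strata$stratum)
  if (is.na(i)) stop(sprintf("unknown stratum '%s'", stratum))
  s <- params$strata[i, ]
  tt <- params$years - params$years[1]
  gomp <- outer(exp(s$b * params$ages), s$a * (1 - s$r)^tt)
  make <- matrix(s$c * (1 - s$r_c)^tt, nrow = length(params$ages),
                 ncol = length(params$years), byrow = TRUE)
  mu <- gomp + make
  dimnames(mu) <- list(age = params$ages, year = params$years)
  mu
}

#' Closed-form mode of an untruncated Gompertz age-at-death density
#'
#' For hazard \eqn{a e^{bx}} the density \eqn{\mu(x) S(x)} is maximal at
#' \eqn{\log(b/a)/b}.
#' @param a,b Gompertz level and slope.
#' @export
gompertz_mode <- function(a, b) log(b / a) / b

#' Analytic Gompertz survival from a radix age
#'
#' \eqn{S(x) = \exp(-(a/b)(e^{bx} - e^{b x_0}))}, survival conditional on
#' being alive at `x0`.
#' @param x Ages at which to evaluate.
#' @param a,b Gompertz level and slope.
#' @param x0 Radix age (default 31).
#' @export
gompertz_survival <- function(x, a, b, x0 = 31) {
  exp(-(a / b) * (exp(b * x) - exp(b * x0)))
}

#' True modal age at death implied by a scenario
#'
#' Pure Gompertz strata (`c = 0`) use the closed form; otherwise the mode is
#' found by fine-grid maximization of \eqn{\mu(x)\exp(-\int\mu)} over the
#' age range.
#'
#' @param params A [scenario_params()].
#' @param stratum Stratum label.
#' @param year Calendar year (may be a vector).
#' @export
true_modal_age <- function(params, stratum, year) {
  i <- match(stratum, params$strata$stratum)
  if (is.na(i)) stop(sprintf("unknown stratum '%s'", stratum))
  s <- params$strata[i, ]
  if (any(!year %in% params$years)) stop("year outside scenario range")
  tt <- year - params$years[1]
  if (s$c == 0) {
    vapply(tt, function(d) gompertz_mode(s$a * (1 - s$r)^d, s$b), numeric(1))
  } else {
    vapply(tt, function(d) {
      xg <- seq(min(params$ages), max(params$ages), by = 0.001)
      mu <- s$c * (1 - s$r_c)^d + s$a * (1 - s$r)^d * exp(s$b * xg)
      f <- mu * exp(-pracma::cumtrapz(xg, mu)[, 1])
      xg[which.max(f)]
    }, numeric(1))
  }
}

#' Assemble a stratified mortality dataset
#'
#' The container for a stratified Lexis surface: death counts and
#' person-year exposures on a common rectangular age-by-year grid for each
#' stratum, with the generating hazard retained when the data are synthetic.
#'
#' @param strata `data.frame` with columns `stratum`, `sex`, `class`.
#' @param ages,years Consecutive integer grids shared by all strata.
#' @param deaths,exposures Named lists (one age-by-year matrix per stratum).
#' @param true_hazard Optional named list of hazard matrices.
#' @param params Optional generating [scenario_params()].
#' @return An object of class `mort_dataset`.
#' @export
mort_dataset <- function(strata, ages, years, deaths, exposures,
                         true_hazard = NULL, params = NULL) {
  ds <- structure(list(strata = strata, ages = as.integer(ages),
                       years = as.integer(years), deaths = deaths,
                       exposures = exposures, true_hazard = true_hazard,
                       params = params),
                  class = "mort_dataset")
  validate_mort_dataset(ds)
  ds
}

#' Validate a mortality dataset's structural invariants
#'
#' Checks rectangularity, consecutive single-year grids, nonnegativity, and
#' that no deaths occur in cells with zero exposure.
#' @param ds A [mort_dataset()].
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_mort_dataset <- function(ds) {
  stopifnot(inherits(ds, "mort_dataset"))
  if (any(diff(ds$ages) != 1L) || any(diff(ds$years) != 1L)) {
    stop("ages and years must be consecutive single-year grids")
  }
  dm <- c(length(ds$ages), length(ds$years))
  for (s in ds$strata$stratum) {
    D <- ds$deaths[[s]]; E <- ds$exposures[[s]]
    if (is.null(D) || is.null(E)) stop(sprintf("stratum '%s' missing data", s))
    if (!all(dim(D) == dm) || !all(dim(E) == dm)) {
      stop(sprintf("stratum '%s': deaths/exposures not on the common grid", s))
    }
    if (any(D < 0) || any(E < 0)) {
      stop(sprintf("stratum '%s': negative deaths or exposures", s))
    }
    if (any(D[E == 0] != 0)) {
      stop(sprintf("stratum '%s': deaths in zero-exposure cells", s))
    }
  }
  invisible(ds)
}

#' @export
print.mort_dataset <- function(x, ...) {
  cat(sprintf("Mortality dataset: %d strata, ages %d-%d, years %d-%d (%s)\n",
              nrow(x$strata), min(x$ages), max(x$ages), min(x$years),
              max(x$years),
              if (is.null(x$true_hazard)) "observed" else "synthetic"))
  invisible(x)
}

#' Draw Poisson death counts given hazards and exposures
#'
#' Deaths in each cell are Poisson with mean `hazard * exposure`, the
#' canonical observation model for count/exposure mortality data.  Cells
#' with zero exposure have zero deaths with probability one.
#'
#' @param hazards Named list of age-by-year hazard matrices (or one matrix,
#'   taken as a single unnamed stratum).
#' @param exposures Exposures matching `hazards` in shape, or a scalar, or
#'   one value per age.
#' @param ages,years Integer grids labelling the matrix dimensions.
#' @param strata Optional `data.frame` (`stratum`, `sex`, `class`); derived
#'   from the hazard names when omitted.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param params Optional generating [scenario_params()], stored on the result.
#' @return A [mort_dataset()] with `true_hazard` retained.
#' @export
sample_deaths <- function(hazards, exposures, ages, years, strata = NULL,
                          seed = 1L, params = NULL) {
  if (is.matrix(hazards)) hazards <- list(all = hazards)
  nm <- names(hazards)
  if (is.null(strata)) {
    strata <- data.frame(stratum = nm, sex = NA_character_,
                         class = NA_character_)
  }
  dm <- c(length(ages), length(years))
  expand <- function(E) {
    if (length(E) == 1L) E <- rep(E, dm[1])
    if (is.vector(E) && length(E) == dm[1]) E <- matrix(E, dm[1], dm[2])
    E
  }
  if (is.matrix(exposures) || !is.list(exposures)) {
    exposures <- stats::setNames(rep(list(expand(exposures)), length(nm)), nm)
  } else {
    exposures <- lapply(exposures, expand)
  }
  for (s in nm) {
    if (any(exposures[[s]] < 0)) stop("negative exposure")
    if (!all(dim(hazards[[s]]) == dm)) stop("hazard grid does not conform")
  }
  set.seed(seed)
  deaths <- lapply(nm, function(s) {
    D <- matrix(stats::rpois(prod(dm), hazards[[s]] * exposures[[s]]),
                dm[1], dm[2], dimnames = list(age = ages, year = years))
    D
  })
  names(deaths) <- nm
  mort_dataset(strata, ages, years, deaths, exposures,
               true_hazard = hazards, params = params)
}

#' Simulate the full dataset a scenario describes
#'
#' @param params A [scenario_params()].
#' @param seed Seed for the Poisson draw; defaults to the scenario's seed.
#' @param noise_free If `TRUE`, deaths are the Poisson expectations
#'   `hazard * exposure` (no sampling) — useful for exactness checks.
#' @return A [mort_dataset()].
#' @export
simulate_dataset <- function(params, seed = params$seed, noise_free = FALSE) {
  stopifnot(inherits(params, "scenario_params"))
  nm <- params$strata$stratum
  hazards <- stats::setNames(lapply(nm, hazard_surface, params = params), nm)
  E <- matrix(params$exposure, length(params$ages), length(params$years))
  dimnames(E) <- list(age = params$ages, year = params$years)
  if (noise_free) {
    deaths <- lapply(hazards, function(mu) mu * E)
    mort_dataset(params$strata, params$ages, params$years, deaths,
                 stats::setNames(rep(list(E), length(nm)), nm),
                 true_hazard = hazards, params = params)
  } else {
    sample_deaths(hazards, E, params$ages, params$years,
                  strata = params$strata, seed = seed, params = params)
  }
}

#' Scenario parameters emulating the Finnish occupational-class surfaces
#'
#' Three occupational classes by two sexes, ages 31-110, with pure Gompertz
#' hazards (`c = 0`) and steady proportional improvement, calibrated so that
#' true modal ages start in the mid-to-high 70s in 1971 and rise into the
#' mid 80s by 2017, with the upper non-manual class about 4 (men) and 2
#' (women) years ahead of the manual class.
#'
#' @param years Calendar years (default 1971:2017).
#' @param exposure Person-years per age-year cell (default 2e4).
#' @param seed Integer seed.
#' @export
finnish_like_params <- function(years = 1971:2017, exposure = 2e4, seed = 1L) {
  cls <- c("upper_nonmanual", "lower_nonmanual", "manual")
  b_m <- 0.105; b_f <- 0.115
  m0_m <- c(78, 76, 74)          # male modal ages at the first year
  m0_f <- c(80.5, 79.5, 78.5)    # female modal ages at the first year
  strata <- data.frame(
    stratum = c(paste0("male_", cls), paste0("female_", cls)),
    sex = rep(c("male", "female"), each = 3),
    class = rep(cls, 2),
    a = c(b_m * exp(-b_m * m0_m), b_f * exp(-b_f * m0_f)),
    b = rep(c(b_m, b_f), each = 3),
    c = 0,
    r = rep(c(0.019, 0.013), each = 3),
    r_c = 0)
  scenario_params(strata, ages = 31:110, years = years, exposure = exposure,
                  seed = seed)
}

#' Simulated dataset emulating the Finnish occupational-class registers
#'
#' Convenience wrapper: [finnish_like_params()] followed by
#' [simulate_dataset()].
#' @inheritParams finnish_like_params
#' @export
finnish_like_scenario <- function(seed = 1L, years = 1971:2017,
                                  exposure = 2e4) {
  simulate_dataset(finnish_like_params(years = years, exposure = exposure,
                                       seed = seed))
}

#' Age-shaped exposure profile
#'
#' Flat up to age 80, then declining geometrically — a stylized population
#' pyramid tail for scenarios wanting thinner old-age exposures.
#' @param ages Integer ages.
#' @param base Person-years below age 80.
#' @param decline Proportional decline per year of age above 80.
#' @export
age_shaped_exposure <- function(ages, base = 2e4, decline = 0.12) {
  base * pmin(1, (1 - decline)^(ages - 80))
}

#' Subset a mortality dataset
#'
#' @param ds A [mort_dataset()].
#' @param strata,ages,years Values to keep (defaults: all).
#' @export
subset_dataset <- function(ds, strata = ds$strata$stratum, ages = ds$ages,
                           years = ds$years) {
  stopifnot(inherits(ds, "mort_dataset"))
  ia <- match(intersect(ds$ages, ages), ds$ages)
  iy <- match(intersect(ds$years, years), ds$years)
  keep <- ds$strata$stratum %in% strata
  pick <- function(lst) {
    if (is.null(lst)) return(NULL)
    lapply(lst[ds$strata$stratum[keep]], function(m) m[ia, iy, drop = FALSE])
  }
  mort_dataset(ds$strata[keep, , drop = FALSE], ds$ages[ia], ds$years[iy],
               pick(ds$deaths), pick(ds$exposures), pick(ds$true_hazard),
               params = ds$params)
}

#' Write a mortality dataset as long-format delimited text
#'
#' Columns: `stratum, sex, class, age, year, deaths, exposure`.  A sidecar
#' `<path>.meta` key-value file records the generating scenario (if any) and
#' its seed.  The same long format is the ingestion path for user-supplied
#' data, e.g. Human Mortality Database death and exposure tables reshaped to
#' these columns.
#'
#' @param ds A [mort_dataset()].
#' @param path Output file path (CSV).
#' @export
write_mort_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "mort_dataset"))
  rows <- do.call(rbind, lapply(seq_len(nrow(ds$strata)), function(i) {
    s <- ds$strata[i, ]
    data.frame(stratum = s$stratum, sex = s$sex, class = s$class,
               age = rep(ds$ages, times = length(ds$years)),
               year = rep(ds$years, each = length(ds$ages)),
               deaths = as.vector(ds$deaths[[s$stratum]]),
               exposure = as.vector(ds$exposures[[s$stratum]]))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  meta <- c(sprintf("ages: %d %d", min(ds$ages), max(ds$ages)),
            sprintf("years: %d %d", min(ds$years), max(ds$years)))
  if (!is.null(ds$params)) {
    p <- ds$params
    meta <- c(meta, sprintf("seed: %d", p$seed),
              vapply(seq_len(nrow(p$strata)), function(i) {
                s <- p$strata[i, ]
                sprintf("stratum %s: a=%.10g b=%.10g c=%.10g r=%.10g r_c=%.10g",
                        s$stratum, s$a, s$b, s$c, s$r, s$r_c)
              }, character(1)))
  }
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a mortality dataset from long-format delimited text
#'
#' @param path CSV written by [write_mort_dataset()] or user-supplied data
#'   in the same columns.
#' @return A [mort_dataset()] (without true hazards).
#' @export
read_mort_dataset <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "sex", "class", "age", "year", "deaths", "exposure")
  if (!all(need %in% names(rows))) {
    stop("expected columns: ", paste(need, collapse = ", "))
  }
  ages <- sort(unique(rows$age)); years <- sort(unique(rows$year))
  strata <- unique(rows[, c("stratum", "sex", "class")])
  rownames(strata) <- NULL
  grab <- function(s, col) {
    sub <- rows[rows$stratum == s, ]
    m <- matrix(NA_real_, length(ages), length(years),
                dimnames = list(age = ages, year = years))
    m[cbind(match(sub$age, ages), match(sub$year, years))] <- sub[[col]]
    if (anyNA(m)) stop(sprintf("stratum '%s' does not cover the full grid", s))
    m
  }
  deaths <- stats::setNames(lapply(strata$stratum, grab, col = "deaths"),
                            strata$stratum)
  expo <- stats::setNames(lapply(strata$stratum, grab, col = "exposure"),
                          strata$stratum)
  mort_dataset(strata, ages, years, deaths, expo)
}
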