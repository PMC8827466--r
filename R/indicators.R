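#' Complete a hazard curve into survival and age-at-death density
#'
#' Given a strictly positive hazard \eqn{\mu(x)} on a uniform fine age grid,
#' computes the survival function \eqn{S(x) = \exp(-\int_{x_0}^x \mu(u) du)}
#' by cumulative trapezoidal integration (radix 1 at the first grid age) and
#' the age-at-death density \eqn{f(x) = \mu(x) S(x)}.  Together these are
#' the continuous representation of the life-table distribution of deaths
#' by age from which all indicators are read.
#'
#' @param ages Uniform fine age grid (step no larger than 0.01 years for
#'   indicator-grade precision).
#' @param hazard Positive hazard values on `ages`.
#' @param stratum,year Optional labels.
#' @return An object of class `smooth_hazard` with elements `ages`,
#'   `hazard`, `survival`, `density`.
#' @export
survival_and_density <- function(ages, hazard, stratum = NULL, year = NULL) {
  stopifnot(length(ages) == length(hazard), length(ages) >= 3)
  if (any(hazard <= 0)) stop("hazard must be strictly positive everywhere")
  steps <- diff(ages)
  if (max(steps) - min(steps) > 1e-9) stop("age grid must be uniform")
  H <- as.vector(pracma::cumtrapz(ages, hazard))
  S <- exp(-H)
  structure(list(stratum = stratum, year = year, ages = ages,
                 hazard = hazard, survival = S, density = hazard * S),
            class = "smooth_hazard")
}

#' @export
print.smooth_hazard <- function(x, ...) {
  cat(sprintf("Smooth hazard%s%s: ages %.4g-%.4g (step %.4g), S(end) = %.3g\n",
              if (is.null(x$stratum)) "" else paste0(" [", x$stratum, "]"),
              if (is.null(x$year)) "" else paste0(" year ", x$year),
              min(x$ages), max(x$ages), x$ages[2] - x$ages[1],
              x$survival[length(x$survival)]))
  invisible(x)
}

# linear interpolation of a smooth_hazard component at arbitrary ages
.hz_interp <- function(hz, what, x) {
  stats::approx(hz$ages, hz[[what]], xout = x, rule = 1)$y
}

#' Modal age at death from a smooth density
#'
#' Locates the maximum of the age-at-death density on `[floor, max age]`
#' and refines it by quadratic interpolation through the three grid points
#' around the discrete maximum, giving sub-grid precision.  Exact ties are
#' broken toward the older age.  A maximum on the boundary of the search
#' range (at the floor or at the oldest age) is flagged rather than
#' silently returned: such a mode is not interior and the number is not
#' a trustworthy modal age.
#'
#' @param hz A [smooth_hazard].
#' @param floor Lower bound of the mode search (default 45, safely above
#'   the radix age and below any plausible old-age mode).
#' @return List with elements `M` (years), `boundary` (logical flag) and
#'   `density_at_M`.
#' @export
modal_age <- function(hz, floor = 45) {
  stopifnot(inherits(hz, "smooth_hazard"))
  if (floor < min(hz$ages)) stop("mode search floor below the age grid")
  idx <- which(hz$ages >= floor)
  f <- hz$density[idx]
  i <- max(which(f == max(f)))            # ties toward the older age
  boundary <- i == 1L || i == length(idx)
  gi <- idx[i]
  if (boundary) {
    return(list(M = hz$ages[gi], boundary = TRUE, density_at_M = f[i]))
  }
  h <- hz$ages[2] - hz$ages[1]
  f0 <- hz$density[gi - 1L]; f1 <- hz$density[gi]; f2 <- hz$density[gi + 1L]
  denom <- f0 - 2 * f1 + f2
  delta <- if (abs(denom) < .Machine$double.eps * max(abs(c(f0, f1, f2)), 1)) {
    0
  } else {
    max(-0.5, min(0.5, 0.5 * (f0 - f2) / denom))
  }
  list(M = hz$ages[gi] + delta * h, boundary = FALSE,
       density_at_M = f1)
}

#' Standard deviation of ages at death above the mode, SD(M+)
#'
#' Root-mean-square deviation from `M` among deaths occurring above `M`:
#' \deqn{SD(M+) = \sqrt{\int_M^{\omega} (x - M)^2 f(x) dx /
#'                      \int_M^{\omega} f(x) dx}.}
#' Dispersion is measured about the mode itself (the Kannisto convention),
#' not about the conditional mean above it; falling SD(M+) alongside rising
#' M diagnoses old-age mortality compression.
#'
#' @param hz A [smooth_hazard].
#' @param M Interior modal age (from [modal_age()]).
#' @return SD(M+) in years.
#' @export
sd_above_mode <- function(hz, M) {
  stopifnot(inherits(hz, "smooth_hazard"))
  if (M <= min(hz$ages) || M >= max(hz$ages)) stop("M must be interior")
  above <- hz$ages > M
  x <- c(M, hz$ages[above])
  f <- c(.hz_interp(hz, "density", M), hz$density[above])
  mass <- pracma::trapz(x, f)
  if (mass < 1e-6) stop("negligible density mass above the mode")
  sqrt(pracma::trapz(x, (x - M)^2 * f) / mass)
}

#' Conditional life expectancy on the attained-age scale
#'
#' Average attained age at death among those surviving to age `x`:
#' \deqn{e_x = x + \frac{1}{S(x)} \int_x^{\omega} S(t) dt,}
#' i.e. the threshold age plus remaining life expectancy at that age.  The
#' upper end of the age grid is treated as a hard endpoint of the integral.
#'
#' @param hz A [smooth_hazard].
#' @param x Threshold age within `[min age, max age)`.
#' @return \eqn{e_x} in years of attained age.
#' @export
conditional_attained_expectancy <- function(hz, x) {
  stopifnot(inherits(hz, "smooth_hazard"))
  if (x < min(hz$ages) || x >= max(hz$ages)) {
    stop("threshold must lie within the age grid (strictly below its top)")
  }
  Sx <- .hz_interp(hz, "survival", x)
  if (Sx < 1e-10) stop("survival at the threshold is numerically zero")
  beyond <- hz$ages > x
  xs <- c(x, hz$ages[beyond])
  Ss <- c(Sx, hz$survival[beyond])
  x + pracma::trapz(xs, Ss) / Sx
}

#' Proportion of the radix surviving to a target age
#'
#' `S(target)` with radix 1 at the first grid age (here: the proportion of
#' 31-year-olds surviving), linearly interpolated when the target (e.g. the
#' modal age) falls between grid points.
#'
#' @param hz A [smooth_hazard].
#' @param target Age within the grid.
#' @export
proportion_surviving <- function(hz, target) {
  stopifnot(inherits(hz, "smooth_hazard"))
  if (target < min(hz$ages) || target > max(hz$ages)) {
    stop("target age outside the age grid")
  }
  .hz_interp(hz, "survival", target)
}

#' Age at which survival crosses a given probability
#'
#' The unique age where `S(x) = p`, by monotone linear interpolation of the
#' (strictly decreasing) survival curve; e.g. `p = 0.80` gives the age a
#' cohort member has an 80% chance of reaching.
#'
#' @param hz A [smooth_hazard].
#' @param p Probability strictly between `S(max age)` and 1.
#' @export
age_at_survival_quantile <- function(hz, p) {
  stopifnot(inherits(hz, "smooth_hazard"))
  S <- hz$survival
  if (p >= 1 || p <= S[length(S)]) {
    stop("p must lie strictly between S(max age) and 1")
  }
  stats::approx(rev(S), rev(hz$ages), xout = p, rule = 1)$y
}

#' All old-age mortality indicators for one stratum-year
#'
#' @param hz A [smooth_hazard].
#' @param mode_floor Mode-search floor passed to [modal_age()].
#' @param thresholds Ages for conditional attained-age expectancies and
#'   survivorship columns (default `c(65, 75)`).
#' @param quantile_p Optional survival probability for an age-at-quantile
#'   column (e.g. 0.80); `NULL` to skip.
#' @return One-row `data.frame`: `stratum, year, M, boundary_mode,
#'   sd_above_M, e<threshold>..., p_surv_M, p_surv_<threshold>...`
#'   (boundary modes leave the mode-dependent columns `NA`).
#' @export
indicator_set <- function(hz, mode_floor = 45, thresholds = c(65, 75),
                          quantile_p = NULL) {
  m <- modal_age(hz, floor = mode_floor)
  out <- data.frame(stratum = if (is.null(hz$stratum)) NA_character_ else hz$stratum,
                    year = if (is.null(hz$year)) NA_integer_ else hz$year,
                    M = m$M, boundary_mode = m$boundary,
                    sd_above_M = if (m$boundary) NA_real_ else
                      sd_above_mode(hz, m$M))
  for (th in thresholds) {
    out[[paste0("e", th)]] <- conditional_attained_expectancy(hz, th)
  }
  out$p_surv_M <- if (m$boundary) NA_real_ else proportion_surviving(hz, m$M)
  for (th in thresholds) {
    out[[paste0("p_surv_", th)]] <- proportion_surviving(hz, th)
  }
  if (!is.null(quantile_p)) {
    out[[sprintf("age_at_S%g", 100 * quantile_p)]] <-
      age_at_survival_quantile(hz, quantile_p)
  }
  out
}

#' Indicator trends across strata and calendar years
#'
#' Evaluates each fitted stratum at every requested year and tabulates the
#' full indicator set, optionally with per-year gap columns (reference
#' class minus stratum, within sex) for `M` and the expectancy columns.
#' Rows whose mode hit the search boundary are flagged and excluded from
#' gap computation with a warning.
#'
#' @param fits List of converged `pspline_fit` objects, one per stratum.
#' @param years Years to tabulate (default: every fitted year).
#' @param strata Optional `data.frame` (`stratum`, `sex`, `class`) enabling
#'   within-sex gaps.
#' @param reference_class Class label used as gap reference (e.g.
#'   `"upper_nonmanual"`); `NULL` skips gap columns.
#' @param step Fine-grid step for hazard evaluation.
#' @inheritParams indicator_set
#' @return Long-format `data.frame`, one row per stratum-year.
#' @export
indicator_trends <- function(fits, years = NULL, strata = NULL,
                             reference_class = NULL, mode_floor = 45,
                             thresholds = c(65, 75), quantile_p = NULL,
                             step = 0.01) {
  if (inherits(fits, "pspline_fit")) fits <- list(fits)
  if (any(!vapply(fits, `[[`, logical(1), "converged"))) {
    stop("all fits must have converged")
  }
  rows <- do.call(rbind, lapply(fits, function(fit) {
    yrs <- if (is.null(years)) fit$years else intersect(years, fit$years)
    do.call(rbind, lapply(yrs, function(yr) {
      indicator_set(evaluate_hazard(fit, year = yr, step = step),
                    mode_floor = mode_floor, thresholds = thresholds,
                    quantile_p = quantile_p)
    }))
  }))
  rownames(rows) <- NULL
  if (!is.null(reference_class) && !is.null(strata)) {
    rows <- merge(rows, strata, by = "stratum", sort = FALSE)
    if (any(rows$boundary_mode)) {
      warning("boundary-mode rows excluded from gap columns")
    }
    gap_cols <- c("M", paste0("e", thresholds))
    for (col in gap_cols) {
      ref <- rows[rows$class == reference_class & !rows$boundary_mode,
                  c("sex", "year", col)]
      names(ref)[3] <- "ref_value"
      rows <- merge(rows, ref, by = c("sex", "year"), all.x = TRUE,
                    sort = FALSE)
      rows[[paste0("gap_", col)]] <-
        ifelse(rows$boundary_mode, NA_real_, rows$ref_value - rows[[col]])
      rows$ref_value <- NULL
    }
    rows <- rows[order(match(rows$stratum, unique(rows$stratum)), rows$year), ]
    rownames(rows) <- NULL
  }
  rows
}
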