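#' Configuration for the full analysis pipeline
#'
#' Collects the tunable settings of every stage: basis and penalty layout,
#' the BIC lambda grid, fine-grid and mode-search settings for the
#' indicators, left-truncation start ages for the sensitivity check, and
#' the gap reference class.
#'
#' @param spacing Knot spacing (years) for both basis dimensions.
#' @param degree Spline degree.
#' @param order Difference-penalty order.
#' @param lambda_grid Candidate penalty weights per dimension.
#' @param smoother `"2d"` (age-year tensor product, the default) or `"1d"`
#'   (independent yearly fits over age).
#' @param step Fine age-grid step for indicator evaluation (years).
#' @param mode_floor Mode-search floor (years).
#' @param thresholds Conditional-expectancy/survivorship threshold ages.
#' @param quantile_p Optional survival probability for an age-at-quantile
#'   column; `NULL` to skip.
#' @param truncation_ages Start ages for [truncation_sensitivity()]; all
#'   must lie below `mode_floor`.
#' @param reference_class Gap reference class label (`NULL`: no gaps).
#' @param out_dir Optional directory for cached fits and tables.
#' @param verbose Log per-stratum progress via `message()`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spacing = 5, degree = 3, order = 2,
                            lambda_grid = 10^seq(-2, 6), smoother = "2d",
                            step = 0.01, mode_floor = 45,
                            thresholds = c(65, 75), quantile_p = NULL,
                            truncation_ages = c(31, 35, 40),
                            reference_class = "upper_nonmanual",
                            out_dir = NULL, verbose = TRUE) {
  smoother <- match.arg(smoother, c("2d", "1d"))
  if (any(truncation_ages >= mode_floor)) {
    stop("all truncation start ages must lie below the mode-search floor")
  }
  structure(list(spacing = spacing, degree = degree, order = order,
                 lambda_grid = lambda_grid, smoother = smoother, step = step,
                 mode_floor = mode_floor, thresholds = thresholds,
                 quantile_p = quantile_p, truncation_ages = truncation_ages,
                 reference_class = reference_class, out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

.log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

# BIC-selected 2D fit for one stratum of a dataset
.fit_stratum_2d <- function(ds, s, config) {
  fit <- tryCatch(
    select_lambda(ds$deaths[[s]], ds$exposures[[s]], ds$ages, ds$years,
                  lambda_grid = config$lambda_grid,
                  spec_age = basis_spec(min(ds$ages), max(ds$ages),
                                        config$spacing, config$degree),
                  spec_year = basis_spec(min(ds$years), max(ds$years),
                                         config$spacing, config$degree),
                  order = config$order, stratum = s),
    error = function(e) {
      stop(sprintf("stratum '%s': %s", s, conditionMessage(e)), call. = FALSE)
    })
  .log(config, "stratum %s: lambda = %s, ED = %.1f, BIC = %.1f", s,
       paste(signif(fit$lambda, 3), collapse = "/"), fit$ed, fit$bic)
  fit
}

#' Run the full analysis: per-stratum smoothing, then indicator trends
#'
#' For each stratum of the dataset, selects the smoothing parameters by BIC
#' (independently per stratum, each with its own lambda) and fits the
#' two-dimensional P-spline hazard; then evaluates the indicator set for
#' every stratum-year.  Entirely deterministic given the dataset and
#' configuration.
#'
#' @param ds A [mort_dataset()].
#' @param config A [pipeline_config()].
#' @return A list of class `modalmort_run` with elements `fits` (named list
#'   of `pspline_fit`), `indicators` (long-format table), and `config`.
#'   With `config$out_dir` set, fit archives and the indicator table are
#'   also written there as text.
#' @export
run_full <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "mort_dataset"), inherits(config, "pipeline_config"))
  if (any(config$thresholds < min(ds$ages) | config$thresholds >= max(ds$ages))) {
    stop("indicator thresholds must lie inside the age domain")
  }
  nm <- ds$strata$stratum
  fits <- stats::setNames(
    lapply(nm, function(s) .fit_stratum_2d(ds, s, config)), nm)
  tbl <- indicator_trends(fits, strata = ds$strata,
                          reference_class = config$reference_class,
                          mode_floor = config$mode_floor,
                          thresholds = config$thresholds,
                          quantile_p = config$quantile_p, step = config$step)
  nb <- sum(tbl$boundary_mode)
  if (nb > 0) {
    warning(sprintf("%d stratum-year(s) have boundary modes", nb))
  }
  .log(config, "indicators tabulated for %d stratum-years", nrow(tbl))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in nm) {
      write_fit(fits[[s]], file.path(config$out_dir,
                                     paste0("fit_", s, ".txt")))
    }
    utils::write.csv(tbl, file.path(config$out_dir, "indicators.csv"),
                     row.names = FALSE)
  }
  structure(list(fits = fits, indicators = tbl, config = config),
            class = "modalmort_run")
}

#' @export
print.modalmort_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d strata, %d indicator rows\n",
              length(x$fits), nrow(x$indicators)))
  invisible(x)
}

#' Sensitivity of the modal age to left truncation of the age domain
#'
#' Refits the surface with the data left-truncated at each start age and
#' re-derives M for every stratum-year.  When every start age lies well
#' below the mode, M should be essentially unchanged; the check reports the
#' maximum spread of M across start ages per stratum-year and a pass flag
#' at the stated tolerance.
#'
#' @param ds A [mort_dataset()].
#' @param config A [pipeline_config()]; `config$truncation_ages` gives the
#'   start ages (all below `config$mode_floor`).
#' @param tolerance Pass threshold on the M spread in years (default 0.1).
#' @return List of class `truncation_sensitivity`: `M_table` (one column
#'   `M_<start>` per requested start age), `summary` (per stratum-year
#'   `delta_max` and `pass`), and `tolerance`.
#' @export
truncation_sensitivity <- function(ds, config = pipeline_config(),
                                   tolerance = 0.1) {
  stopifnot(inherits(ds, "mort_dataset"))
  starts <- config$truncation_ages
  if (any(starts >= config$mode_floor)) {
    stop("truncation start ages must lie below the mode-search floor")
  }
  if (any(starts < min(ds$ages))) {
    stop("truncation start ages must be within the observed age range")
  }
  uniq <- sort(unique(starts))
  per_start <- lapply(uniq, function(a0) {
    .log(config, "left truncation at age %d", a0)
    sub <- subset_dataset(ds, ages = ds$ages[ds$ages >= a0])
    run <- run_full(sub, pipeline_config(
      spacing = config$spacing, degree = config$degree, order = config$order,
      lambda_grid = config$lambda_grid, step = config$step,
      mode_floor = config$mode_floor, thresholds = config$thresholds,
      truncation_ages = config$truncation_ages,
      reference_class = NULL, verbose = config$verbose))
    run$indicators[, c("stratum", "year", "M")]
  })
  base <- per_start[[1]][, c("stratum", "year")]
  M_mat <- vapply(match(starts, uniq), function(i) per_start[[i]]$M,
                  numeric(nrow(base)))
  colnames(M_mat) <- make.unique(paste0("M_", starts))
  uniq_M <- vapply(seq_along(uniq), function(i) per_start[[i]]$M,
                   numeric(nrow(base)))
  delta <- apply(as.matrix(uniq_M), 1, function(v) diff(range(v)))
  summary <- cbind(base, delta_max = delta, pass = delta <= tolerance)
  structure(list(M_table = cbind(base, as.data.frame(M_mat)),
                 summary = summary, tolerance = tolerance),
            class = "truncation_sensitivity")
}

#' @export
print.truncation_sensitivity <- function(x, ...) {
  cat(sprintf("Left-truncation sensitivity: max |dM| = %.4f years, %s (tol %.2g)\n",
              max(x$summary$delta_max),
              if (all(x$summary$pass)) "all pass" else
                sprintf("%d FAIL", sum(!x$summary$pass)), x$tolerance))
  invisible(x)
}

# mean squared second difference of a (possibly gappy) yearly series
series_roughness <- function(m) {
  d2 <- diff(m, differences = 2)
  mean(d2^2, na.rm = TRUE)
}

#' Compare modal-age trends from 1D and 2D smoothing
#'
#' For each stratum, derives the yearly M series twice: from independent
#' one-dimensional (age-only) fits per calendar year, and from a single
#' two-dimensional age-year fit — each with its own BIC-selected lambda.
#' Fluctuation of each series is summarized as the mean squared second
#' difference (roughness); smoothing across years should leave the trend
#' similar but markedly less jagged.
#'
#' @param ds A [mort_dataset()] with at least 10 years.
#' @param config A [pipeline_config()].
#' @return List of class `smoother_comparison`: `series` (per stratum-year
#'   `M_1d`, `M_2d`, and `M_true` when the dataset is synthetic) and
#'   `roughness` (per stratum, with the 2D/1D ratio).  Years whose 1D fit
#'   fails to converge at every lambda are marked missing.
#' @export
compare_1d_2d <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "mort_dataset"))
  if (length(ds$years) < 10) stop("need at least 10 years of data")
  spec_age <- basis_spec(min(ds$ages), max(ds$ages), config$spacing,
                         config$degree)
  rows <- list(); rough <- list()
  for (s in ds$strata$stratum) {
    fit2 <- .fit_stratum_2d(ds, s, config)
    m2 <- vapply(ds$years, function(yr) {
      modal_age(evaluate_hazard(fit2, year = yr, step = config$step),
                floor = config$mode_floor)$M
    }, numeric(1))
    m1 <- vapply(seq_along(ds$years), function(j) {
      fit1 <- tryCatch(
        select_lambda(ds$deaths[[s]][, j], ds$exposures[[s]][, j], ds$ages,
                      lambda_grid = config$lambda_grid, spec = spec_age,
                      order = config$order, stratum = s),
        error = function(e) NULL)
      if (is.null(fit1)) return(NA_real_)
      fit1$year <- ds$years[j]
      modal_age(evaluate_hazard(fit1, step = config$step),
                floor = config$mode_floor)$M
    }, numeric(1))
    if (anyNA(m1)) {
      warning(sprintf("stratum '%s': %d year(s) non-convergent in 1D, marked missing",
                      s, sum(is.na(m1))))
    }
    row <- data.frame(stratum = s, year = ds$years, M_1d = m1, M_2d = m2)
    if (!is.null(ds$params)) {
      row$M_true <- true_modal_age(ds$params, s, ds$years)
    }
    rows[[s]] <- row
    rough[[s]] <- data.frame(stratum = s,
                             roughness_1d = series_roughness(m1),
                             roughness_2d = series_roughness(m2))
  }
  rough <- do.call(rbind, rough)
  rough$ratio_2d_1d <- rough$roughness_2d / rough$roughness_1d
  rownames(rough) <- NULL
  structure(list(series = do.call(rbind, c(rows, make.row.names = FALSE)),
                 roughness = rough),
            class = "smoother_comparison")
}

#' @export
print.smoother_comparison <- function(x, ...) {
  cat("1D vs 2D smoothing of the modal-age trend:\n")
  print(x$roughness, row.names = FALSE)
  invisible(x)
}

#' Plot indicator trends by stratum
#'
#' Trend panels in the style of the occupational-class figures: one line
#' per stratum over calendar year for each requested indicator column.
#' Requires ggplot2.
#'
#' @param tbl Indicator table from [run_full()] / [indicator_trends()].
#' @param columns Indicator columns to facet (default
#'   `c("M", "e65", "e75")`).
#' @return A ggplot object.
#' @export
plot_indicator_trends <- function(tbl, columns = c("M", "e65", "e75")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_indicator_trends requires ggplot2")
  }
  columns <- intersect(columns, names(tbl))
  long <- do.call(rbind, lapply(columns, function(cl) {
    data.frame(stratum = tbl$stratum, year = tbl$year, indicator = cl,
               value = tbl[[cl]])
  }))
  long$indicator <- factor(long$indicator, levels = columns)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value,
                                     colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "calendar year", y = "years of age", colour = NULL) +
    ggplot2::theme_minimal()
}
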