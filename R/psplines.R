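#' @importFrom Matrix crossprod Diagonal
NULL

# Penalized IRLS for a Poisson GLM with log link and offset.
# B: model matrix (dense or sparse Matrix), P: penalty matrix (lambda
# included), y: counts, offset: log exposure.  Returns coefficients,
# deviance, effective dimension (trace of the influence matrix) and
# convergence diagnostics.  Weights are clamped away from zero so cells
# whose fitted mean underflows do not zero out the working system.
pirls <- function(B, P, y, offset, theta0, tol = 1e-6, maxit = 200L) {
  theta <- theta0
  converged <- FALSE
  it <- 0L
  A <- NULL; BtWB <- NULL
  for (it in seq_len(maxit)) {
    eta <- as.vector(B %*% theta) + offset
    mu <- exp(pmin(eta, 30))
    w <- pmax(mu, 1e-10)
    z <- (eta - offset) + (y - mu) / w
    Bw <- if (inherits(B, "Matrix")) Matrix::Diagonal(x = w) %*% B else B * w
    BtWB <- as.matrix(Matrix::crossprod(B, Bw))
    rhs <- as.vector(Matrix::crossprod(B, w * z))
    A <- BtWB + P
    theta_new <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(theta_new)) break
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- as.vector(B %*% theta) + offset
  mu <- exp(eta)
  dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  ed <- if (!is.null(A)) {
    tryCatch(sum(diag(solve(A, BtWB))), error = function(e) NA_real_)
  } else NA_real_
  list(coef = theta, deviance = dev, ed = ed, converged = converged,
       iter = it, fitted = mu)
}

# Deterministic start: penalized least squares of the empirical log rate
# log((D + 0.5) / (E + 0.5)) on the basis.
pirls_start <- function(B, P, y, E) {
  ylog <- log((y + 0.5) / (E + 0.5))
  G <- as.matrix(Matrix::crossprod(B)) + P
  diag(G) <- diag(G) + 1e-8
  as.vector(solve(G, as.vector(Matrix::crossprod(B, ylog))))
}

#' Fit a one-dimensional P-spline Poisson hazard over age
#'
#' Maximizes the Poisson log-likelihood of death counts with a log-exposure
#' offset, minus `lambda/2` times an order-`order` difference penalty on the
#' B-spline coefficients of the log hazard, by iteratively reweighted
#' penalized least squares.  Cells with zero exposure carry no information
#' under the Poisson model and are excluded from the likelihood.
#'
#' @param deaths,exposures Numeric vectors over `ages` for one stratum-year.
#' @param ages Integer ages the data sit on.
#' @param lambda Nonnegative penalty weight.
#' @param spec Age [basis_spec()]; default cubic splines with 5-year knots
#'   on the data's age range.
#' @param order Difference-penalty order (default 2).
#' @param stratum,year Optional labels carried on the fit.
#' @param theta0 Optional starting coefficients.
#' @param tol,maxit IRLS convergence tolerance on the maximum absolute
#'   coefficient change, and iteration cap.
#' @return An object of class `pspline_fit` with coefficients on the
#'   log-hazard scale, Poisson deviance, effective dimension ED (trace of
#'   the influence matrix), and `BIC = deviance + log(n) * ED` where `n`
#'   counts cells with positive exposure.
#' @export
fit_1d <- function(deaths, exposures, ages, lambda,
                   spec = basis_spec(min(ages), max(ages)), order = 2,
                   stratum = NULL, year = NULL, theta0 = NULL,
                   tol = 1e-6, maxit = 200L) {
  stopifnot(length(deaths) == length(ages), length(exposures) == length(ages),
            lambda >= 0)
  keep <- exposures > 0
  if (!any(keep)) stop("no cells with positive exposure")
  if (sum(deaths[keep]) <= 0) {
    stop("all death counts are zero: the Poisson MLE lies at the -Inf ",
         "boundary and the log hazard is not estimable")
  }
  y <- deaths[keep]; E <- exposures[keep]
  B <- build_basis(spec, ages[keep])
  P <- lambda * build_penalty(spec$nbasis, order)
  if (is.null(theta0)) theta0 <- pirls_start(B, P, y, E)
  res <- pirls(B, P, y, log(E), theta0, tol = tol, maxit = maxit)
  if (!res$converged) {
    warning(sprintf("IRLS did not converge in %d iterations (lambda = %g)",
                    maxit, lambda))
  }
  n <- sum(keep)
  structure(
    list(type = "1d", stratum = stratum, year = year, spec_age = spec,
         spec_year = NULL, order = order, lambda = lambda,
         coef = res$coef, deviance = res$deviance, ed = res$ed,
         bic = res$deviance + log(n) * res$ed, n_obs = n,
         converged = res$converged, iter = res$iter,
         ages = ages, years = year),
    class = "pspline_fit")
}

#' Fit a two-dimensional P-spline Poisson hazard over age and year
#'
#' Tensor-product B-spline basis (Kronecker product of marginal bases) with
#' an additive anisotropic penalty
#' `lambda_age * (I x P_age) + lambda_year * (P_year x I)` on the
#' coefficient grid, fitted by the same penalized IRLS as [fit_1d()].
#'
#' @param deaths,exposures Age-by-year matrices for one stratum.
#' @param ages,years Integer grids labelling rows and columns.
#' @param lambda_age,lambda_year Nonnegative penalty weights per dimension.
#' @param spec_age,spec_year Marginal [basis_spec()]s; defaults use 5-year
#'   knot spacing and cubic splines in both dimensions.
#' @inheritParams fit_1d
#' @return A `pspline_fit` whose `coef` is an age-basis by year-basis matrix.
#' @export
fit_2d <- function(deaths, exposures, ages, years, lambda_age, lambda_year,
                   spec_age = basis_spec(min(ages), max(ages)),
                   spec_year = basis_spec(min(years), max(years)),
                   order = 2, stratum = NULL, theta0 = NULL,
                   tol = 1e-6, maxit = 200L) {
  stopifnot(is.matrix(deaths), all(dim(deaths) == c(length(ages), length(years))),
            all(dim(exposures) == dim(deaths)),
            lambda_age >= 0, lambda_year >= 0)
  y <- as.vector(deaths); E <- as.vector(exposures)
  keep <- E > 0
  if (!any(keep)) stop("no cells with positive exposure")
  if (sum(y[keep]) <= 0) {
    stop("all death counts are zero: the Poisson MLE lies at the -Inf ",
         "boundary and the log hazard is not estimable")
  }
  Bx <- build_basis(spec_age, ages, sparse = TRUE)
  By <- build_basis(spec_year, years, sparse = TRUE)
  ka <- spec_age$nbasis; ky <- spec_year$nbasis
  # cells vectorized age-fastest, coefficients vec(Theta) age-basis-fastest
  B <- Matrix::kronecker(By, Bx)[keep, , drop = FALSE]
  P <- as.matrix(lambda_age * Matrix::kronecker(Matrix::Diagonal(ky),
                                                build_penalty(ka, order)) +
                 lambda_year * Matrix::kronecker(build_penalty(ky, order),
                                                 Matrix::Diagonal(ka)))
  if (is.null(theta0)) theta0 <- pirls_start(B, P, y[keep], E[keep])
  res <- pirls(B, P, y[keep], log(E[keep]), theta0, tol = tol, maxit = maxit)
  if (!res$converged) {
    warning(sprintf(
      "IRLS did not converge in %d iterations (lambda_age = %g, lambda_year = %g)",
      maxit, lambda_age, lambda_year))
  }
  n <- sum(keep)
  structure(
    list(type = "2d", stratum = stratum, year = NULL, spec_age = spec_age,
         spec_year = spec_year, order = order,
         lambda = c(age = lambda_age, year = lambda_year),
         coef = matrix(res$coef, ka, ky), deviance = res$deviance,
         ed = res$ed, bic = res$deviance + log(n) * res$ed, n_obs = n,
         converged = res$converged, iter = res$iter,
         ages = ages, years = years),
    class = "pspline_fit")
}

#' @export
print.pspline_fit <- function(x, ...) {
  cat(sprintf("%s P-spline fit%s: lambda = %s, ED = %.2f, deviance = %.2f, BIC = %.2f%s\n",
              toupper(x$type),
              if (is.null(x$stratum)) "" else paste0(" [", x$stratum, "]"),
              paste(signif(x$lambda, 3), collapse = "/"),
              x$ed, x$deviance, x$bic,
              if (x$converged) "" else " (NOT CONVERGED)"))
  invisible(x)
}

#' Select the smoothing parameter(s) by BIC on a discrete grid
#'
#' Fits the stratum at every grid point (a scalar grid in 1D, the Cartesian
#' product per dimension in 2D), warm-starting each fit from its
#' predecessor, and returns the converged fit with minimal
#' `BIC = deviance + log(n) * ED`.  Ties are broken toward larger lambda
#' (the smoother fit).  The full BIC profile is recorded on the result as
#' `$profile`.
#'
#' @param deaths,exposures One stratum's data: vectors over `ages` (1D) or
#'   age-by-year matrices (2D).
#' @param ages,years Integer grids (`years = NULL` selects a 1D fit).
#' @param lambda_grid Candidate penalty weights per dimension; default
#'   `10^(-2:6)`.
#' @param year Optional calendar-year label for a 1D fit (labelling only;
#'   use `years` for the 2D data grid).
#' @param ... Passed to [fit_1d()] / [fit_2d()] (basis specs, penalty
#'   order, labels, tolerances).
#' @return The minimal-BIC `pspline_fit`, with the profile attached.
#' @export
select_lambda <- function(deaths, exposures, ages, years = NULL,
                          lambda_grid = 10^seq(-2, 6), year = NULL, ...) {
  lambda_grid <- sort(unique(lambda_grid))
  if (length(lambda_grid) == 0L) stop("empty lambda grid")
  two_d <- !is.null(years)
  if (two_d) {
    cand <- expand.grid(lambda_age = lambda_grid, lambda_year = lambda_grid)
    cand <- cand[order(cand$lambda_age * cand$lambda_year, cand$lambda_age), ]
  } else {
    cand <- data.frame(lambda = lambda_grid)
  }
  best <- NULL
  theta_prev <- NULL
  prof <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fit <- withCallingHandlers(
      tryCatch({
        if (two_d) {
          fit_2d(deaths, exposures, ages, years,
                 lambda_age = cand$lambda_age[i],
                 lambda_year = cand$lambda_year[i],
                 theta0 = theta_prev, ...)
        } else {
          fit_1d(deaths, exposures, ages, lambda = cand$lambda[i],
                 theta0 = theta_prev, ...)
        }
      }, error = function(e) e),
      warning = function(w) invokeRestart("muffleWarning"))
    if (inherits(fit, "error")) {
      stop(fit)  # structural errors (all-zero deaths etc.) are not per-lambda
    }
    theta_prev <- as.vector(fit$coef)
    prof[[i]] <- data.frame(
      lambda_age = if (two_d) cand$lambda_age[i] else cand$lambda[i],
      lambda_year = if (two_d) cand$lambda_year[i] else NA_real_,
      bic = fit$bic, deviance = fit$deviance, ed = fit$ed,
      converged = fit$converged, iter = fit$iter)
    if (fit$converged && is.finite(fit$bic) &&
        (is.null(best) || fit$bic <= best$bic)) {
      best <- fit  # <= with ascending smoothness: ties go to larger lambda
    }
  }
  profile <- do.call(rbind, prof)
  if (is.null(best)) {
    stop(paste0("no candidate converged; diagnostics:\n",
                paste(utils::capture.output(print(profile)), collapse = "\n")))
  }
  best$profile <- profile
  if (!two_d && !is.null(year)) {
    best$year <- year
    best$years <- year
  }
  best
}

#' Evaluate a fitted hazard on a fine age grid
#'
#' Computes `exp(basis(grid) %*% coefficients)` for one calendar year of the
#' fit, then completes the result into a [smooth_hazard] with survival and
#' age-at-death density via [survival_and_density()].  Evaluation is
#' restricted to the fitted age and year window — no extrapolation.
#'
#' @param fit A `pspline_fit`.
#' @param year Calendar year to evaluate (must be within the fitted years;
#'   ignored, and taken from the fit's label, for a 1D fit).
#' @param step Fine-grid step in years of age (default 0.01).
#' @return A `smooth_hazard` object.
#' @export
evaluate_hazard <- function(fit, year = NULL, step = 0.01) {
  stopifnot(inherits(fit, "pspline_fit"))
  grid <- seq(min(fit$ages), max(fit$ages), by = step)
  if (fit$type == "1d") {
    coef_age <- as.vector(fit$coef)
    if (is.null(year)) year <- fit$year
  } else {
    if (is.null(year) || !(year %in% fit$years)) {
      stop("`year` must be one of the fitted calendar years (no extrapolation)")
    }
    by <- as.vector(build_basis(fit$spec_year, year))
    coef_age <- as.vector(fit$coef %*% by)
  }
  mu <- exp(as.vector(build_basis(fit$spec_age, grid) %*% coef_age))
  survival_and_density(grid, mu, stratum = fit$stratum, year = year)
}

#' Serialize a P-spline fit to a plain-text archive
#'
#' Writes the full fit object (coefficients, basis and penalty specs,
#' lambda, BIC, diagnostics) as parseable R source text, readable back with
#' [read_fit()]; used for pipeline caching.
#' @param fit A `pspline_fit`.
#' @param path Output file.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pspline_fit"))
  dput(fit, file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  fit <- dget(path)
  stopifnot(inherits(fit, "pspline_fit"))
  fit
}
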