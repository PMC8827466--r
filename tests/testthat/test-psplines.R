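test_that("equally spaced B-spline basis has the stated layout", {
  sp <- basis_spec(31, 110, spacing = 5, degree = 3)
  expect_identical(sp$nbasis, 19L)   # ceil(79/5) + 3
  x <- seq(31, 110, length.out = 200)
  B <- build_basis(sp, x)
  expect_identical(dim(B), c(200L, 19L))
  expect_true(max(abs(rowSums(B) - 1)) < 1e-12)        # partition of unity
  # each cubic basis function is supported on 4 adjacent knot intervals
  expect_true(all(colSums(build_basis(sp, seq(31, 110, by = 0.1)) > 0) <=
                    ceiling(4 * 5 / 0.1)))
  # degree 0 with spacing equal to the domain width: a single indicator
  sp0 <- basis_spec(31, 110, spacing = 79, degree = 0)
  expect_identical(sp0$nbasis, 1L)
  expect_true(all(build_basis(sp0, c(31, 70.5, 110)) == 1))
  expect_error(build_basis(sp, 111), "outside")
  expect_error(build_basis(sp, 30.9), "outside")
})

test_that("difference penalty annihilates low-order sequences and has rank n - order", {
  P2 <- build_penalty(5, 2)
  expect_equal(drop(t(1:5) %*% P2 %*% (1:5)), 0, tolerance = 1e-12)
  expect_equal(drop(t(2 * (1:5) + 3) %*% P2 %*% (2 * (1:5) + 3)), 0,
               tolerance = 1e-12)
  expect_identical(qr(P2)$rank, 3L)
  P1 <- build_penalty(6, 1)
  expect_equal(drop(t(rep(4, 6)) %*% P1 %*% rep(4, 6)), 0, tolerance = 1e-12)
  expect_identical(qr(P1)$rank, 5L)
  ev <- eigen(P2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))      # positive semidefinite
  expect_error(build_penalty(3, 3), "order")
})

test_that("infinite-penalty limit of an order-2 fit is the Gompertz GLM", {
  ages <- 31:110
  E <- rep(1e5, 80)
  D <- GOMP_A * exp(GOMP_B * ages) * E   # noise-free expected counts
  fit <- fit_1d(D, E, ages, lambda = 1e8)
  hz <- evaluate_hazard(fit)
  # fitted log hazard is linear in age with slope b
  at <- sapply(ages, function(a) hz$hazard[which.min(abs(hz$ages - a))])
  co <- stats::coef(stats::lm(log(at) ~ ages))
  expect_equal(unname(co[2]), GOMP_B, tolerance = 1e-3)
  expect_lt(max(abs(stats::residuals(stats::lm(log(at) ~ ages)))), 1e-3)
  # fine-grid relative error against the true hazard on [40, 100]
  sel <- hz$ages >= 40 & hz$ages <= 100
  rel <- abs(hz$hazard[sel] / (GOMP_A * exp(GOMP_B * hz$ages[sel])) - 1)
  expect_lt(max(rel), 0.01)
})

test_that("unpenalized saturated fit reproduces observed counts", {
  ages <- 31:110
  set.seed(21)
  E <- rep(1e4, 80)
  D <- rpois(80, 2e-4 * exp(0.09 * ages) * E)
  # one indicator basis function per data point, lambda = 0
  sp <- basis_spec(31, 111, spacing = 1, degree = 0)
  fit <- fit_1d(D, E, ages, lambda = 0, spec = sp, order = 1)
  fitted_counts <- exp(as.vector(build_basis(sp, ages) %*% fit$coef)) * E
  pos <- D > 0
  expect_lt(max(abs(fitted_counts[pos] / D[pos] - 1)), 1e-6)
})

test_that("fitted rates are invariant to joint scaling of deaths and exposures", {
  ages <- 31:110
  set.seed(4)
  E <- rep(1e4, 80)
  D <- rpois(80, 1e-4 * exp(0.095 * ages) * E)
  # unpenalized: pure offset invariance of the Poisson likelihood
  f1 <- fit_1d(D, E, ages, lambda = 0,
               spec = basis_spec(31, 110, spacing = 10))
  f2 <- fit_1d(10 * D, 10 * E, ages, lambda = 0,
               spec = basis_spec(31, 110, spacing = 10))
  expect_lt(max(abs(f1$coef - f2$coef)), 1e-8)
  # penalized: the objective scales exactly when lambda scales with the data
  f3 <- fit_1d(D, E, ages, lambda = 50)
  f4 <- fit_1d(10 * D, 10 * E, ages, lambda = 500)
  expect_lt(max(abs(f3$coef - f4$coef)), 1e-8)
})

test_that("degenerate inputs are rejected with clear errors", {
  ages <- 31:110
  expect_error(fit_1d(rep(0, 80), rep(1e4, 80), ages, lambda = 1),
               "all death counts are zero")
  expect_error(fit_1d(rep(1, 80), rep(0, 80), ages, lambda = 1),
               "positive exposure")
  # non-convergence is flagged and warned about, never silent
  D <- rpois(80, 1e-4 * exp(0.1 * ages) * 1e4)
  expect_warning(f <- fit_1d(D, rep(1e4, 80), ages, lambda = 1, maxit = 1L),
                 "did not converge")
  expect_false(f$converged)
})

test_that("2D tensor fit recovers bilinear log-hazard structure", {
  ages <- 31:110; years <- 2000:2019
  E <- matrix(1e5, 80, 20)
  r <- 0.015
  mu <- outer(exp(0.1 * ages), 2e-5 * (1 - r)^(years - 2000))
  fit <- fit_2d(mu * E, E, ages, years, lambda_age = 1e8, lambda_year = 1e8)
  expect_true(fit$converged)
  # slope in age and improvement rate both recovered from the coefficients
  hz1 <- evaluate_hazard(fit, 2000, step = 0.5)
  hz2 <- evaluate_hazard(fit, 2010, step = 0.5)
  slope <- stats::coef(stats::lm(log(hz1$hazard) ~ hz1$ages))[2]
  expect_equal(unname(slope), 0.1, tolerance = 1e-3)
  imp <- 1 - exp(mean(log(hz2$hazard / hz1$hazard)) / 10)
  expect_equal(imp, r, tolerance = 1e-3)
  # ED bounded by the basis size and the penalty null-space dimension
  expect_lte(fit$ed, fit$spec_age$nbasis * fit$spec_year$nbasis)
  expect_gte(fit$ed, 4 - 1e-6)
})

test_that("a surface constant in calendar year stays constant when smoothed", {
  # noise-free expected counts: with no year signal in the data, a heavy
  # year penalty pins the fitted surface to a year-constant hazard
  ages <- 31:110; years <- 2001:2012
  E <- matrix(2e4, 80, 12)
  mu <- matrix(3e-5 * exp(0.1 * ages), 80, 12)
  fit <- fit_2d(mu * E, E, ages, years, lambda_age = 10, lambda_year = 1e8)
  h1 <- evaluate_hazard(fit, 2001, step = 0.25)$hazard
  h2 <- evaluate_hazard(fit, 2012, step = 0.25)$hazard
  expect_lt(max(abs(h2 / h1 - 1)), 1e-4)
})

test_that("BIC selection returns the profile minimum, ties toward smoother fits", {
  ages <- 31:110
  set.seed(12)
  E <- rep(1e5, 80)
  D <- rpois(80, GOMP_A * exp(GOMP_B * ages) * E)
  fit <- select_lambda(D, E, ages)
  expect_true(fit$converged)
  prof <- fit$profile
  conv <- prof[prof$converged & is.finite(prof$bic), ]
  expect_equal(fit$bic, min(conv$bic))
  # with duplicated lambda values the selection is unchanged
  fit2 <- select_lambda(D, E, ages, lambda_grid = rep(10^seq(-2, 6), 2))
  expect_identical(fit2$lambda, fit$lambda)
  expect_equal(fit2$coef, fit$coef, tolerance = 1e-10)
  # selected hazard within 5% of the generating truth at ages 60-95
  hz <- evaluate_hazard(fit)
  sel <- hz$ages >= 60 & hz$ages <= 95
  rel <- abs(hz$hazard[sel] / (GOMP_A * exp(GOMP_B * hz$ages[sel])) - 1)
  expect_lt(max(rel), 0.05)
  expect_error(select_lambda(D, E, ages, lambda_grid = numeric(0)),
               "empty lambda grid")
})

test_that("hazard evaluation is consistent with the fitted likelihood", {
  ages <- 31:110
  set.seed(17)
  E <- rep(5e4, 80)
  D <- rpois(80, 2e-5 * exp(0.1 * ages) * E)
  fit <- fit_1d(D, E, ages, lambda = 100)
  hz <- evaluate_hazard(fit)
  rate_at_data <- exp(as.vector(build_basis(fit$spec_age, ages) %*% fit$coef))
  idx <- vapply(ages, function(a) which.min(abs(hz$ages - a)), integer(1))
  expect_lt(max(abs(hz$hazard[idx] / rate_at_data - 1)), 1e-10)
  # grid-refinement stability of the downstream mode
  m1 <- modal_age(evaluate_hazard(fit, step = 0.01))$M
  m2 <- modal_age(evaluate_hazard(fit, step = 0.005))$M
  expect_lte(abs(m1 - m2), 0.01)
  # no evaluation outside the fitted year window in 2D
  fit2 <- fit_2d(matrix(D, 80, 2), matrix(E, 80, 2), ages, 2000:2001,
                 lambda_age = 10, lambda_year = 10)
  expect_error(evaluate_hazard(fit2, year = 2002), "no extrapolation")
})

test_that("IRLS matches direct numerical optimization of the penalized likelihood", {
  ages <- 31:110
  set.seed(8)
  E <- rep(1e4, 80)
  D <- rpois(80, 3e-5 * exp(0.095 * ages) * E)
  sp <- basis_spec(31, 110, spacing = 10)   # 11 coefficients
  expect_lte(sp$nbasis, 12L)
  lam <- 30
  fit <- fit_1d(D, E, ages, lambda = lam, spec = sp, tol = 1e-10)
  B <- build_basis(sp, ages); P <- build_penalty(sp$nbasis, 2)
  negobj <- function(th) {
    eta <- as.vector(B %*% th) + log(E)
    -(sum(D * eta - exp(eta)) - 0.5 * lam * drop(t(th) %*% P %*% th))
  }
  grad <- function(th) {
    eta <- as.vector(B %*% th) + log(E)
    -(as.vector(t(B) %*% (D - exp(eta))) - lam * as.vector(P %*% th))
  }
  opt <- stats::optim(rep(log(mean(D / E)), sp$nbasis), negobj, grad,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(fit$coef - opt$par)), 1e-5)
})

test_that("deviance and ED trade off monotonically in lambda", {
  ages <- 31:110
  set.seed(15)
  E <- rep(2e4, 80)
  D <- rpois(80, 2.5e-5 * exp(0.1 * ages) * E)
  lams <- 10^seq(-2, 6)
  fits <- lapply(lams, function(l) fit_1d(D, E, ages, lambda = l))
  dev <- vapply(fits, `[[`, numeric(1), "deviance")
  ed <- vapply(fits, `[[`, numeric(1), "ed")
  expect_true(all(diff(dev) >= -1e-6))   # deviance nondecreasing in lambda
  expect_true(all(diff(ed) <= 1e-6))     # ED nonincreasing in lambda
  expect_true(all(ed >= 2 - 1e-6))       # order-2 null space
  expect_true(all(ed <= 19 + 1e-6))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  expect_equal(bics, dev + log(80) * ed, tolerance = 1e-10)
})

test_that("fits are invariant to row order of the input", {
  ages <- 31:110
  set.seed(19)
  E <- rep(1e4, 80)
  D <- rpois(80, 2e-5 * exp(0.1 * ages) * E)
  f1 <- fit_1d(D, E, ages, lambda = 10)
  perm <- sample(80)
  f2 <- fit_1d(D[perm], E[perm], ages[perm], lambda = 10)
  expect_lt(max(abs(f1$coef - f2$coef)), 1e-10)
})

test_that("fit archives round-trip through plain text", {
  ages <- 31:110
  set.seed(23)
  E <- rep(1e4, 80)
  D <- rpois(80, 2e-5 * exp(0.1 * ages) * E)
  fit <- fit_1d(D, E, ages, lambda = 10, stratum = "s1", year = 2000L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_equal(back$coef, fit$coef, tolerance = 1e-12)
  expect_identical(back$stratum, "s1")
  expect_equal(back$bic, fit$bic, tolerance = 1e-12)
})
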