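# Build data whose ML sample moments equal the model-implied moments
# exactly, so the fitted discrepancy must vanish.
saturating_data <- function(n = 60, alpha = c(2, 1),
                            Psi = matrix(c(1, 0.3, 0.3, 1), 2),
                            theta = c(0.5, 0.5, 0.5), times = 0:2,
                            seed = 41) {
  set.seed(seed)
  p <- length(times)
  Lam <- cbind(1, times)
  Sigma <- Lam %*% Psi %*% t(Lam) + diag(theta)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  W <- chol(crossprod(Z) / n)
  Z <- Z %*% solve(W)                    # exact zero mean, identity ML cov
  sweep(Z %*% chol(Sigma), 2, as.numeric(Lam %*% alpha), "+")
}

test_that("information criteria reproduce the textbook arithmetic", {
  ic <- information_criteria(-20010.134, 9, 1322)
  expect_equal(unname(round(ic, 2)), c(40038.27, 40084.95, 40056.36))
})

test_that("saturating data drives the ML discrepancy to zero", {
  y <- saturating_data()
  fit <- fit_lgcm(y)
  expect_true(fit$converged)
  expect_lt(fit$F_ML, 1e-7)
  expect_lt(fit$chisq, 1e-4)
  expect_equal(unname(fit$alpha), c(2, 1), tolerance = 1e-3)
  expect_equal(unname(fit$psi), c(1, 0.3, 1), tolerance = 1e-2)
  fi <- fit_indices(fit)
  expect_equal(fi$CFI, 1)
  expect_equal(fi$TLI, 1)
  expect_lt(fi$RMSEA, 1e-3)
  expect_lt(fi$SRMR, 1e-4)
})

test_that("model-implied wave means follow the growth line on clean data", {
  y <- saturating_data(alpha = c(3, 2))
  fit <- fit_lgcm(y)
  mu <- fit$alpha[1] + fit$alpha[2] * (0:2)
  expect_equal(unname(colMeans(y)), unname(mu), tolerance = 1e-6)
})

test_that("two waves leave negative degrees of freedom and error out", {
  y <- saturating_data()[, 1:2]
  expect_error(fit_lgcm(y, times = 0:1), "not identified")
})

test_that("missing cells and tiny samples are rejected", {
  y <- saturating_data(n = 20)
  y_na <- y; y_na[1, 1] <- NA
  expect_error(fit_lgcm(y_na), "complete")
  expect_error(fit_lgcm(y[1:6, ]), "more users than")
})

test_that("parameters are recovered at scale with correct uncertainty", {
  spec <- growth_spec(intercept_mean = 838.13, slope_mean = 273.33,
                      intercept_sd = 300, slope_sd = 150,
                      intercept_slope_corr = 0.36,
                      residual_sd = c(100, 100, 100))
  sim <- simulate_trajectories(spec, 1322, seed = 42)
  fit <- fit_lgcm(sim$y)
  expect_true(fit$converged)
  # alpha_I SE ~ sqrt(psi_II/n) ~ 8.3; allow ~3 SEs
  expect_lt(abs(fit$alpha[["alpha_I"]] - 838.13), 25)
  expect_lt(abs(fit$alpha[["alpha_S"]] - 273.33), 15)
  expect_lt(abs(fit$r - 0.36), 0.1)
  expect_true(all(is.finite(fit$se)))
  expect_lt(abs(fit$alpha[["alpha_I"]] - 838.13) / fit$se[["alpha_I"]], 4)
})

test_that("fit indices follow their defining formulas", {
  ct <- swbgrowth:::cfi_tli(4, 1, 100, 3)
  expect_equal(unname(ct["CFI"]), 1 - 3 / 97, tolerance = 1e-12)
  expect_equal(unname(ct["TLI"]), (100 / 3 - 4) / (100 / 3 - 1),
               tolerance = 1e-12)
  # chisq == df -> RMSEA = 0 by the max(., 0) numerator
  y <- saturating_data(n = 80, seed = 43)
  fit <- fit_lgcm(y)
  fit$chisq <- fit$df
  fi <- fit_indices(fit)
  expect_equal(fi$RMSEA, 0)
})

test_that("equal-residual restriction frees two degrees of freedom", {
  y <- saturating_data(n = 100, seed = 44)
  f_free <- fit_lgcm(y, residuals = "free")
  f_eq <- fit_lgcm(y, residuals = "equal")
  expect_equal(f_free$q, 8)
  expect_equal(f_eq$q, 6)
  expect_equal(f_eq$df, f_free$df + 2)
  expect_lte(f_eq$logL, f_free$logL + 1e-6)
})

test_that("covariate recoding shifts means consistently, slopes unchanged", {
  spec <- growth_spec(intercept_mean = 5, slope_mean = 1,
                      intercept_sd = 1.5, slope_sd = 0.5,
                      intercept_slope_corr = 0.3, residual_sd = c(1, 1, 1))
  sim <- simulate_trajectories(spec, 400, seed = 45)
  x <- rep(c(0, 1), 200)
  y <- sim$y
  y[x == 1, ] <- y[x == 1, ] + 2   # gender effect on the intercept
  f01 <- fit_conditional_lgcm(y, x)
  f12 <- fit_conditional_lgcm(y, x + 1)
  expect_equal(f01$alpha[["gamma1_I"]], f12$alpha[["gamma1_I"]],
               tolerance = 1e-3)
  expect_equal(f01$alpha[["gamma1_S"]], f12$alpha[["gamma1_S"]],
               tolerance = 1e-3)
  expect_equal(f12$alpha[["gamma0_I"]],
               f01$alpha[["gamma0_I"]] - f01$alpha[["gamma1_I"]],
               tolerance = 1e-2)
  expect_gt(f01$alpha[["gamma1_I"]], 1)  # recovers the planted +2 shift
})

test_that("a null covariate stays within sampling noise of zero", {
  spec <- growth_spec(intercept_mean = 5, slope_mean = 1,
                      intercept_sd = 1.5, slope_sd = 0.5,
                      intercept_slope_corr = 0.3, residual_sd = c(1, 1, 1))
  for (s in 1:3) {
    sim <- simulate_trajectories(spec, 300, seed = 50 + s)
    set.seed(60 + s)
    x <- rbinom(300, 1, 0.5)
    fit <- fit_conditional_lgcm(sim$y, x)
    expect_lt(abs(fit$alpha[["gamma1_I"]] / fit$se[["gamma1_I"]]), 4)
    expect_lt(abs(fit$alpha[["gamma1_S"]] / fit$se[["gamma1_S"]]), 4)
  }
})

test_that("a constant covariate is refused", {
  y <- saturating_data(n = 30)
  expect_error(fit_conditional_lgcm(y, rep(1, 30)), "constant")
})
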