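test_that("a one-class mixture reproduces the LGCM maximum likelihood", {
  sim <- simulate_trajectories(one_class_spec(), 80, seed = 61)
  f_mix <- fit_lgmm(sim$y, K = 1, n_starts = 1, seed = 1)
  f_sem <- fit_lgcm(sim$y)
  expect_lt(abs(f_mix$logL - f_sem$logL), 1e-6)
  expect_equal(unname(f_mix$alpha[1, ]), unname(f_sem$alpha),
               tolerance = 1e-4)
})

test_that("EM log-likelihood traces are nondecreasing across seeds", {
  sim <- simulate_trajectories(two_class_spec(), 300, seed = 62)
  for (s in 1:4) {
    fit <- fit_lgmm(sim$y, K = 2, n_starts = 3, seed = s)
    expect_true(all(diff(fit$logL_trace) >= -1e-8))
  }
})

test_that("a well-separated two-class population is recovered", {
  sim <- simulate_trajectories(two_class_spec(), 800, seed = 63)
  fit <- fit_lgmm(sim$y, K = 2, n_starts = 10, seed = 64)
  # classes sorted by slope mean descending: class1 is the high-growth one
  expect_gt(fit$alpha["class1", "slope"], fit$alpha["class2", "slope"])
  expect_lt(abs(fit$pi[2] - 0.937), 0.04)
  expect_lt(abs(fit$alpha["class1", "slope"] - 2.88), 0.4)
  expect_lt(abs(fit$alpha["class2", "slope"] - 0.57), 0.15)
  expect_gt(fit$entropy, 0.9)
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-9))
})

test_that("duplicating every user doubles the log-likelihood", {
  sim <- simulate_trajectories(two_class_spec(), 200, seed = 65)
  y2 <- rbind(sim$y, sim$y)
  f1 <- fit_lgmm(sim$y, K = 2, n_starts = 5, seed = 66)
  f2 <- fit_lgmm(y2, K = 2, n_starts = 5, seed = 66)
  expect_equal(f2$logL, 2 * f1$logL, tolerance = 1e-5)
  ord <- order(f1$alpha[, 2])
  expect_equal(unname(f2$alpha[order(f2$alpha[, 2]), ]),
               unname(f1$alpha[ord, ]), tolerance = 1e-2)
})

test_that("EM's optimum dominates a coarse brute-force grid", {
  spec <- two_class_spec()
  sim <- simulate_trajectories(spec, 50, seed = 67)
  fit <- fit_lgmm(sim$y, K = 2, n_starts = 10, seed = 68)
  # oracle: likelihood over a coarse grid of class means with the remaining
  # parameters held at the generator truth
  Lam <- cbind(1, 0:2)
  Psi <- matrix(c(1.5^2, 0.3 * 1.5 * 0.3, 0.3 * 1.5 * 0.3, 0.3^2), 2)
  grid_logL <- -Inf
  for (i1 in c(10, 14.49, 18)) for (s1 in c(2, 2.88, 3.5)) {
    for (i2 in c(1, 2.6, 4)) for (s2 in c(0.2, 0.57, 1)) {
      ll <- swbgrowth:::lgmm_loglik(
        sim$y, Lam, rbind(c(i1, s1), c(i2, s2)),
        c(0.063, 0.937), Psi, c(1, 1, 1))
      grid_logL <- max(grid_logL, ll)
    }
  }
  expect_gte(fit$logL, grid_logL)
})

test_that("relative entropy hits its defining anchor points", {
  expect_equal(relative_entropy(matrix(0.5, 4, 2)), 0)
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(relative_entropy(onehot), 1)
  expect_equal(relative_entropy(rbind(c(0.9, 0.1), c(0.8, 0.2))),
               0.4045, tolerance = 1e-4)
  expect_true(is.na(relative_entropy(matrix(1, 5, 1))))
  expect_error(relative_entropy(matrix(c(0.5, 0.2), 1)), "sum to 1")
  # range property over random valid posteriors
  set.seed(69)
  for (i in 1:10) {
    P <- matrix(rexp(30), 10, 3)
    P <- P / rowSums(P)
    e <- relative_entropy(P)
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
})

test_that("average posterior matrix averages within modal classes", {
  P <- rbind(c(0.9, 0.1), c(0.7, 0.3), c(0.2, 0.8))
  M <- avg_posterior_matrix(P)
  expect_equal(M[1, ], c(0.8, 0.2), ignore_attr = TRUE)
  expect_equal(M[2, ], c(0.2, 0.8), ignore_attr = TRUE)
  expect_equal(rowSums(M), c(1, 1), ignore_attr = TRUE)
  # one-hot posteriors give the identity
  expect_equal(unname(avg_posterior_matrix(diag(3)[c(1, 2, 3), ])), diag(3))
  # an inconsistent assignment is rejected
  expect_error(avg_posterior_matrix(P, assignment = c(2, 1, 1)),
               "inconsistent")
  # empty modal class yields an NA row
  M2 <- avg_posterior_matrix(rbind(c(0.9, 0.1), c(0.8, 0.2)))
  expect_true(all(is.na(M2[2, ])))
  # rows sum to 1 for random posteriors
  set.seed(70)
  P3 <- matrix(rexp(60), 20, 3)
  P3 <- P3 / rowSums(P3)
  M3 <- avg_posterior_matrix(P3)
  ok <- !apply(is.na(M3), 1, any)
  expect_true(all(abs(rowSums(M3[ok, , drop = FALSE]) - 1) < 1e-9))
})

test_that("the bootstrap counting formula and guards are exact", {
  expect_equal(blrt_pvalue(5, c(1, 2, 3, 4, 5, 6, 0.5, 0.1, 0.2, 0.3)),
               3 / 11, tolerance = 1e-12)
  expect_error(blrt_pvalue(5, numeric(0)), "at least one")
  sim <- simulate_trajectories(one_class_spec(), 50, seed = 71)
  expect_error(blrt(sim$y, K = 1), ">= 2")
  expect_error(blrt(sim$y, K = 2, B = 0), ">= 1")
})

test_that("LMR is exact on its anchors and powerful when classes exist", {
  sim <- simulate_trajectories(two_class_spec(), 400, seed = 72)
  f1 <- fit_lgmm(sim$y, K = 1, n_starts = 2, seed = 73)
  f2 <- fit_lgmm(sim$y, K = 2, n_starts = 6, seed = 73)
  r <- lmr_test(f2, f1)
  expect_gte(r$p, 0)
  expect_lte(r$p, 1)
  expect_lt(r$p, 0.05)   # strong separation
  expect_error(lmr_test(f2, f2), "one more class")
  # mismatched data is detected
  other <- fit_lgmm(sim$y[1:100, ], K = 1, n_starts = 1, seed = 1)
  expect_error(lmr_test(f2, other), "identical data")
})

test_that("lmr_test p = 1 requires equal fits of adjacent K", {
  sim <- simulate_trajectories(one_class_spec(), 60, seed = 74)
  f1 <- fit_lgmm(sim$y, K = 1, n_starts = 1, seed = 1)
  f2 <- f1
  f2$K <- 2L
  f2$q <- f1$q + 3L
  expect_equal(lmr_test(f2, f1)$p, 1)
})

test_that("the small-class flag triggers strictly below 3 percent", {
  expect_true(is_small_class(c(0.971, 0.029)))
  expect_false(is_small_class(c(0.969, 0.031)))
  expect_false(is_small_class(c(0.97, 0.03)))   # boundary is not flagged
})

test_that("class enumeration selects the generating K", {
  sim2 <- simulate_trajectories(two_class_spec(), 500, seed = 75)
  enum2 <- enumerate_classes(sim2$y, K_range = 1:3, n_starts = 8, seed = 76)
  expect_equal(enum2$selected, 2)
  lls <- enum2$table$logL
  expect_true(all(diff(lls[!is.na(lls)]) >= -1e-6))

  sim1 <- simulate_trajectories(one_class_spec(), 300, seed = 77)
  enum1 <- enumerate_classes(sim1$y, K_range = 1:2, n_starts = 8, seed = 78)
  expect_equal(enum1$selected, 1)
  expect_error(enumerate_classes(sim1$y, K_range = 2:3), "start at 1")
})
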