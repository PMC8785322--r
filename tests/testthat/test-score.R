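test_that("the SWB count score adds highs and subtracts negatives", {
  expect_equal(swb_score(10, 5, 3), 12)
  expect_equal(swb_score(0, 0, 0), 0)
  expect_equal(swb_score(0, 0, 5), -5)
  expect_error(swb_score(-1, 0, 0), "nonnegative")
  # translation consistency: one more high-NA post lowers the score by 1
  expect_equal(swb_score(4, 4, 3) - swb_score(4, 4, 4), 1)
})

make_counts <- function(swb_by_user_phase) {
  # decompose a target SWB matrix (users x phases) into counts so that
  # swb == the given matrix while every count column still varies
  df <- expand.grid(user_id = rownames(swb_by_user_phase),
                    phase = seq_len(ncol(swb_by_user_phase)),
                    stringsAsFactors = FALSE)
  target <- swb_by_user_phase[cbind(match(df$user_id,
                                          rownames(swb_by_user_phase)),
                                    df$phase)]
  p <- seq_len(nrow(df)) %% 3
  df$n_high_LS <- target + 1
  df$n_high_PA <- p
  df$n_high_NA <- 1 + p
  df$n_posts <- abs(df$n_high_LS) + df$n_high_PA + df$n_high_NA + 2
  df$swb <- swb_score(df$n_high_LS, df$n_high_PA, df$n_high_NA)
  stopifnot(isTRUE(all.equal(df$swb, target)))
  df$gender <- "female"
  class(df) <- c("phase_counts", "data.frame")
  df
}

test_that("descriptives use the sample SD and honor degenerate cases", {
  m <- matrix(c(2, 4, 2, 4, 2, 4, 2, 4), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  d <- phase_descriptives(make_counts(m))
  swb1 <- d[d$variable == "SWB" & d$phase == 1, ]
  expect_equal(swb1$mean, 3)
  expect_equal(swb1$sd, sqrt(2))
  # identical users -> SD 0
  m0 <- matrix(3, 2, 4, dimnames = list(c("a", "b"), NULL))
  d0 <- phase_descriptives(make_counts(m0))
  expect_true(all(d0$sd[d0$variable == "SWB"] == 0))
  one_user <- make_counts(m)
  one_user <- one_user[one_user$user_id == "a", ]
  expect_error(phase_descriptives(one_user), "2 users")
})

test_that("descriptives are invariant to user ordering", {
  set.seed(31)
  m <- matrix(rpois(40, 5), 10, 4,
              dimnames = list(sprintf("u%02d", 1:10), NULL))
  counts <- make_counts(m)
  shuffled <- counts[sample(nrow(counts)), ]
  class(shuffled) <- class(counts)
  expect_equal(phase_descriptives(counts), phase_descriptives(shuffled))
})

test_that("repeated-measures F matches the sums-of-squares oracle", {
  m <- matrix(c(3, 5, 4,
                6, 7, 8,
                5, 6, 9,
                9, 12, 10), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  counts <- make_counts(m)
  res <- anova_phases(counts, type = "repeated")

  # brute-force one-way repeated-measures decomposition
  y <- m
  gm <- mean(y)
  ss_phase <- nrow(y) * sum((colMeans(y) - gm)^2)
  ss_subj <- ncol(y) * sum((rowMeans(y) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_phase - ss_subj
  df1 <- ncol(y) - 1
  df2 <- (nrow(y) - 1) * (ncol(y) - 1)
  F_oracle <- (ss_phase / df1) / (ss_err / df2)
  expect_equal(res$SWB$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$SWB$df1, df1)
  expect_equal(res$SWB$df2, df2)
  expect_equal(res$SWB$p, pf(F_oracle, df1, df2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(is.matrix(res$SWB$pairwise))
})

test_that("between-groups F matches aov and grows when a phase shifts", {
  set.seed(32)
  m <- matrix(rpois(48, 6) + rep(c(0, 0, 1, 3), each = 12), 12, 4,
              dimnames = list(sprintf("u%02d", 1:12), NULL))
  counts <- make_counts(m)
  res <- anova_phases(counts, type = "between")
  ref <- summary(aov(counts$swb ~ factor(counts$phase)))[[1]]
  expect_equal(res$SWB$F, ref[1, "F value"], tolerance = 1e-10)

  shifted <- m
  shifted[, 4] <- shifted[, 4] + 20
  res2 <- anova_phases(make_counts(shifted), type = "between")
  expect_gt(res2$SWB$F, res$SWB$F)
})

test_that("degenerate inputs are rejected", {
  m0 <- matrix(3, 4, 4, dimnames = list(letters[1:4], NULL))
  expect_error(anova_phases(make_counts(m0)), "zero total variance")
  expect_error(anova_phases(make_counts(m0)[0, ]), "phases|cases|variance")
})

test_that("repeated-measures ANOVA holds its nominal size", {
  # no phase effect in the generator: rejection rate ~ alpha
  set.seed(33)
  n_rej <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    m <- matrix(rnorm(20 * 4, mean = 5), 20, 4,
                dimnames = list(sprintf("u%02d", 1:20), NULL))
    res <- anova_phases(make_counts(m), type = "repeated")
    if (res$SWB$p < 0.05) n_rej <- n_rej + 1
  }
  rate <- n_rej / n_sim
  # binomial(200, 0.05): 4 Monte-Carlo SEs around 0.05
  expect_lt(rate, 0.05 + 4 * sqrt(0.05 * 0.95 / n_sim))
  expect_gt(rate, 0.05 - 4 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("phase_counts aggregates labels and the trajectory matrix", {
  labelled <- data.frame(
    user_id = rep(c("a", "b"), each = 8),
    phase = rep(rep(1:4, each = 2), 2),
    gender = rep(c("female", "male"), each = 8),
    label_LS = c(rep("high", 8), rep("low", 8)),
    label_PA = "low",
    label_NA = rep(c("low", "high"), 8),
    stringsAsFactors = FALSE)
  pc <- phase_counts(labelled)
  expect_equal(nrow(pc), 8)
  a1 <- pc[pc$user_id == "a" & pc$phase == 1, ]
  expect_equal(a1$n_high_LS, 2)
  expect_equal(a1$n_high_NA, 1)
  expect_equal(a1$swb, 2 + 0 - 1)
  expect_equal(a1$n_posts, 2)

  tm <- trajectory_matrix(pc, phases = 2:4)
  expect_equal(dim(tm$y), c(2, 3))
  expect_equal(tm$time_codes, 0:2)
  expect_equal(tm$gender, c("female", "male"))
  b3 <- pc$swb[pc$user_id == "b" & pc$phase == 3]
  expect_equal(unname(tm$y["b", 2]), b3)
})
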