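test_that("growth_spec validates its fields and names the offender", {
  expect_error(growth_spec(mixing = c(0.5, 0.6)), "mixing")
  expect_error(growth_spec(class_labels = c("a", "b"),
                           mixing = c(0.4, 0.6),
                           intercept_mean = 1, slope_mean = c(0, 0)),
               "intercept_mean")
  expect_error(growth_spec(intercept_sd = -1), "intercept_sd")
  expect_error(growth_spec(intercept_slope_corr = 1.5),
               "intercept_slope_corr")
  expect_error(growth_spec(residual_sd = c(1, 1), time_codes = 0:2),
               "residual_sd")
})

test_that("zero-variance degenerate spec gives exact deterministic rows", {
  spec <- growth_spec(intercept_mean = 1, slope_mean = 1,
                      intercept_sd = 0, slope_sd = 0,
                      residual_sd = c(0, 0, 0))
  sim <- simulate_trajectories(spec, 5, seed = 1)
  expect_equal(unname(sim$y), matrix(rep(c(1, 2, 3), each = 5), 5, 3))
})

test_that("degenerate mixing assigns every user to the sure class", {
  spec <- growth_spec(class_labels = c("a", "b"), mixing = c(1, 0),
                      intercept_mean = c(0, 10), slope_mean = c(0, 5),
                      residual_sd = c(1, 1, 1))
  sim <- simulate_trajectories(spec, 200, seed = 2)
  expect_true(all(sim$class == "a"))
})

test_that("empirical class share matches the binomial moment bound", {
  spec <- two_class_spec()
  sim <- simulate_trajectories(spec, 10000, seed = 3)
  share <- mean(sim$class == "normal_growth")
  tol <- 3 * sqrt(0.937 * 0.063 / 10000)
  expect_lt(abs(share - 0.937), tol)
})

test_that("fixed seed reproduces trajectories exactly", {
  spec <- two_class_spec()
  a <- simulate_trajectories(spec, 100, seed = 9)
  b <- simulate_trajectories(spec, 100, seed = 9)
  expect_identical(a$y, b$y)
  expect_identical(a$class, b$class)
})

test_that("sample moments converge to the model-implied moments", {
  spec <- one_class_spec()
  n <- 20000
  sim <- simulate_trajectories(spec, n, seed = 4)
  mom <- implied_moments(spec)
  # means within 4 Monte-Carlo SEs
  se_mean <- sqrt(diag(mom$cov) / n)
  expect_true(all(abs(colMeans(sim$y) - mom$marginal_mean) < 4 * se_mean))
  # covariances within 4 Monte-Carlo SEs (normal-theory variance of s_ij)
  S <- cov(sim$y)
  for (i in 1:3) for (j in 1:3) {
    se_ij <- sqrt((mom$cov[i, i] * mom$cov[j, j] + mom$cov[i, j]^2) / n)
    expect_lt(abs(S[i, j] - mom$cov[i, j]), 4 * se_ij)
  }
})

test_that("embedding vectors are unit norm and cluster by dimension", {
  emb <- simulate_embeddings(seed = 5)
  norms <- sqrt(rowSums(emb$vectors^2))
  expect_true(all(abs(norms - 1) < 1e-9))

  unit <- emb$vectors
  cos <- tcrossprod(unit)
  planted <- names(emb$dimension)[emb$dimension != "background"]
  # nearest non-self neighbour of every seed shares its dimension
  for (s in emb$seeds$word) {
    cs <- cos[s, ]
    cs[s] <- -Inf
    nn <- names(which.max(cs))
    expect_identical(unname(emb$dimension[nn]), unname(emb$dimension[s]))
  }
  # mean within-dimension cosine beats mean cross-dimension cosine
  within <- cross <- c()
  for (d in c("LS", "PA", "NA")) {
    in_d <- names(emb$dimension)[emb$dimension == d]
    out_d <- setdiff(planted, in_d)
    within <- c(within, mean(cos[in_d, in_d][upper.tri(cos[in_d, in_d])]))
    cross <- c(cross, mean(cos[in_d, out_d]))
  }
  expect_gt(mean(within), mean(cross))
})

test_that("embedding generator rejects empty dimensions", {
  expect_error(simulate_embeddings(vocab_sizes = c(LS = 0, PA = 5, `NA` = 5,
                                                   background = 5)),
               "at least one")
})

test_that("word2vec text format round-trips", {
  emb <- simulate_embeddings(vocab_sizes = c(LS = 3, PA = 3, `NA` = 3,
                                             background = 4),
                             n_seeds = 2, dim = 5, seed = 6)
  path <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(emb$vectors, path)
  back <- read_word2vec(path)
  expect_identical(rownames(back), rownames(emb$vectors))
  expect_equal(back, emb$vectors, tolerance = 1e-6)
})

test_that("corpus size is exactly users x phases x posts per phase", {
  lex <- toy_lexicon()
  spec4 <- growth_spec(intercept_mean = 0, slope_mean = 0.5,
                       residual_sd = rep(0.5, 4), time_codes = 0:3)
  corp <- simulate_corpus(20, spec = spec4, lex = lex, posts_per_phase = 7,
                          seed = 7)
  expect_equal(nrow(corp$posts), 20 * 4 * 7)
  expect_true(all(corp$posts$user_id %in% corp$users$user_id))
  expect_equal(nrow(corp$doc_labels), nrow(corp$posts))
})

test_that("suppressing a dimension's emission removes its planted words", {
  lex <- toy_lexicon()
  spec4 <- growth_spec(intercept_mean = 0, slope_mean = 0.5,
                       residual_sd = rep(0.5, 4), time_codes = 0:3)
  corp <- simulate_corpus(15, spec = spec4, lex = lex, posts_per_phase = 5,
                          emission_scale = c(`NA` = 0), low_plant_rate = 0,
                          junk_rate = 0, seed = 8)
  expect_true(all(corp$doc_labels$label_NA == "low"))
  na_words <- lex$word[lex$dimension == "NA"]
  toks <- unlist(strsplit(corp$posts$text, " "))
  expect_length(intersect(toks, na_words), 0)
})

test_that("higher latent levels yield more high-LS posts", {
  lex <- toy_lexicon()
  spec4 <- growth_spec(intercept_mean = 0, slope_mean = 0,
                       intercept_sd = 1.5, slope_sd = 0.1,
                       residual_sd = rep(0.3, 4), time_codes = 0:3)
  corp <- simulate_corpus(40, spec = spec4, lex = lex, posts_per_phase = 8,
                          steepness = 2, seed = 10)
  expect_gte(nrow(corp$posts), 1000)
  # users with higher average latent level emit more high-LS posts
  latent <- rowMeans(corp$trajectories$y)
  n_high <- tapply(corp$doc_labels$label_LS == "high",
                   corp$posts$user_id, sum)
  n_high <- n_high[corp$users$user_id]
  expect_gt(cor(latent, as.numeric(n_high)), 0.5)

  # raising the emission log-odds on matched seeds raises the counts
  hi <- simulate_corpus(40, spec = spec4, lex = lex, posts_per_phase = 8,
                        steepness = 2, base_logit = 1.5, seed = 10)
  expect_gt(sum(hi$doc_labels$label_LS == "high"),
            sum(corp$doc_labels$label_LS == "high"))
})

test_that("posts JSONL round-trips", {
  lex <- toy_lexicon()
  spec4 <- growth_spec(intercept_mean = 0, slope_mean = 0.5,
                       residual_sd = rep(0.5, 4), time_codes = 0:3)
  corp <- simulate_corpus(4, spec = spec4, lex = lex, posts_per_phase = 2,
                          seed = 11)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_posts_jsonl(corp$posts, path)
  back <- read_posts_jsonl(path)
  expect_equal(back$text, corp$posts$text)
  expect_equal(back$user_id, corp$posts$user_id)
  expect_equal(as.numeric(back$timestamp),
               round(as.numeric(corp$posts$timestamp)))
})
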