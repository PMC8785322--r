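test_that("cleaning applies the full rule chain on a mixed post", {
  expect_equal(clean_post("今天 http://t.cn/abc @friend #话题# ok123"),
               "今天")
})

test_that("non-original posts and empty results map to the drop marker", {
  expect_identical(clean_post("任何 内容", is_original = FALSE),
                   NA_character_)
  expect_identical(clean_post("http://t.cn/xyz"), NA_character_)
  expect_identical(clean_post("   "), NA_character_)
  expect_identical(clean_post("abc 123 DEF"), NA_character_)
})

test_that("each cleaning rule fires on its own construct", {
  expect_equal(clean_post("开心#超话名#结束"), "开心 结束")
  expect_equal(clean_post("喂 @某人 你好"), "喂 你好")
  expect_equal(clean_post("分享图片 美丽"), "美丽")
  expect_equal(clean_post("转发微博 好"), "好")
  expect_equal(clean_post("看 www.example.com/x 这里"), "看 这里")
  expect_equal(clean_post("笑死[笑cry]了"), "笑死 了")
  expect_equal(clean_post("好开心\U0001F600今天"), "好开心 今天")
  expect_equal(clean_post("价格 ５００ 元"), "价格 元")
})

test_that("cleaning is idempotent on its own output", {
  texts <- c("今天 http://t.cn/abc @friend #话题# ok123",
             "分享视频 [doge] 哈哈 2020",
             "纯文本 没有 杂质", "开心#超话#了")
  once <- clean_post(texts)
  kept <- once[!is.na(once)]
  expect_identical(clean_post(kept), kept)
})

test_that("tokenizer splits, drops stop words, and handles empties", {
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize(NA_character_), character(0))
  expect_identical(tokenize("a b a"), c("a", "b", "a"))
  expect_identical(tokenize("我 的 书 的", stopwords = "的"),
                   c("我", "书"))
})

test_that("active-user filter is strict on the count and account type", {
  posts <- make_posts(
    user_id = c(rep("u31", 31), rep("u30", 30), rep("inst", 500)),
    timestamp = "2020-01-01",
    account_type = c(rep("personal", 61), rep("institutional", 500)))
  kept <- filter_active_users(posts)
  expect_identical(kept, "u31")
})

test_that("phase assignment uses half-open windows, later side on boundary", {
  scheme <- default_phase_scheme()
  expect_equal(phase_of(as.POSIXct("2020-01-01", tz = "UTC"), scheme), 2L)
  # exact boundary between phases 2 and 3 belongs to phase 3
  expect_equal(phase_of(as.POSIXct("2020-01-23 00:00:00", tz = "UTC"),
                        scheme), 3L)
  expect_true(is.na(phase_of(as.POSIXct("2021-06-01", tz = "UTC"), scheme)))
})

test_that("overlapping or disordered phase windows are rejected", {
  expect_error(phase_scheme(c("2020-01-01", "2020-01-05"),
                            c("2020-01-10", "2020-02-01")), "overlap")
  expect_error(phase_scheme(c("2020-02-01", "2020-01-01"),
                            c("2020-02-10", "2020-01-10")), "ordered")
})

test_that("retention needs every phase covered and 30+ total posts", {
  scheme <- default_phase_scheme()
  mids <- c("2019-12-10", "2020-01-10", "2020-02-10", "2020-04-10")
  # complete user: 8 posts in each of 4 phases (32 >= 30)
  full <- make_posts(rep("full", 32), rep(mids, each = 8))
  # user missing phase 3 entirely
  gap <- make_posts(rep("gap", 32), rep(mids[c(1, 2, 4)], length.out = 32))
  # complete coverage but only 28 posts total
  few <- make_posts(rep("few", 28), rep(mids, each = 7))
  res <- assign_phases(rbind(full, gap, few), scheme)
  expect_identical(res$retained_users, "full")
  expect_true(all(res$posts$phase[res$posts$user_id == "full"] %in% 1:4))
})

test_that("retained-user set ignores post ordering", {
  scheme <- default_phase_scheme()
  mids <- c("2019-12-10", "2020-01-10", "2020-02-10", "2020-04-10")
  posts <- make_posts(rep(c("a", "b"), each = 32),
                      rep(rep(mids, each = 8), 2))
  shuffled <- posts[sample(nrow(posts)), ]
  expect_identical(assign_phases(posts, scheme)$retained_users,
                   assign_phases(shuffled, scheme)$retained_users)
})

test_that("preprocessed documents carry no URL, mention, digit or Latin", {
  lex <- toy_lexicon()
  spec4 <- growth_spec(intercept_mean = 0, slope_mean = 0.5,
                       residual_sd = rep(0.5, 4), time_codes = 0:3)
  corp <- simulate_corpus(25, spec = spec4, lex = lex, posts_per_phase = 12,
                          junk_rate = 0.3, prop_nonoriginal = 0.1, seed = 12)
  tok <- preprocess_posts(corp$posts, min_active = 30, min_total = 30)
  expect_gt(nrow(tok$docs), 0)
  txt <- unlist(tok$tokens)
  expect_gt(length(txt), 0)
  expect_false(any(grepl("https?://|@|[0-9A-Za-z]", txt)))
  counts <- tok$counts
  expect_lte(counts[["posts_retained"]], counts[["posts_cleaned"]])
  expect_true(all(tok$docs$phase %in% 1:4))
})
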