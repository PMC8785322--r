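# Shared generator configurations used across test files.

# Two-class population mirroring the published class solution: a small
# high-growth class and a large normal-growth class, well separated.
two_class_spec <- function() {
  growth_spec(
    class_labels = c("high_growth", "normal_growth"),
    mixing = c(0.063, 0.937),
    intercept_mean = c(14.49, 2.60),
    slope_mean = c(2.88, 0.57),
    intercept_sd = 1.5, slope_sd = 0.3, intercept_slope_corr = 0.3,
    residual_sd = c(1, 1, 1)
  )
}

one_class_spec <- function(intercept = 5, slope = 1) {
  growth_spec(intercept_mean = intercept, slope_mean = slope,
              intercept_sd = 1.2, slope_sd = 0.4,
              intercept_slope_corr = 0.2, residual_sd = c(1, 1, 1))
}

# A small planted lexicon for corpus tests (CJK-style synthetic words,
# which pass the cleaning rules unchanged).
toy_lexicon <- function(n = 6) {
  lexicon(
    word = c(synth_words(n, "LS"), synth_words(n, "PA"),
             synth_words(n, "NA")),
    dimension = rep(c("LS", "PA", "NA"), each = n)
  )
}

# Raw posts table builder for preprocessing tests.
make_posts <- function(user_id, timestamp, text = "今天 天气 很好",
                       is_original = TRUE, account_type = "personal",
                       gender = "female") {
  data.frame(post_id = sprintf("p%04d", seq_along(user_id)),
             user_id = user_id,
             timestamp = as.POSIXct(timestamp, tz = "UTC"),
             text = text, is_original = is_original,
             account_type = account_type, gender = gender,
             stringsAsFactors = FALSE)
}
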