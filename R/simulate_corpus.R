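#' Simulate a social-media corpus with planted well-being structure
#'
#' Generates per-user post streams across the phases of a [phase_scheme()].
#' Each user follows a latent linear growth trajectory drawn from `spec`
#' (one wave per phase); the probability that a given post is "high" on a
#' well-being dimension is a logistic function of the user's standardized
#' latent level in that phase — increasing for life satisfaction (LS) and
#' positive affect (PA), decreasing for negative affect (NA). High posts
#' embed words planted from the corresponding lexicon dimension; all posts
#' carry background words. True post labels, user classes and trajectories
#' are recorded so downstream stages can be validated against ground truth.
#'
#' The logistic emission link is this package's own construction: it is the
#' minimal monotone map from a continuous latent level to a post-level
#' Bernoulli probability, with configurable steepness.
#'
#' @param n_users number of users.
#' @param spec a [growth_spec()] with as many waves as `scheme` has phases.
#' @param lex a [lexicon()] with non-empty LS, PA and NA dimensions.
#' @param embeddings optional `sim_embeddings` supplying background words;
#'   if `NULL`, background tokens are synthesized with [synth_words()].
#' @param scheme a [phase_scheme()].
#' @param posts_per_phase fixed number of posts per user per phase.
#' @param tokens_per_post mean number of background tokens per post.
#' @param steepness slope of the logistic emission link on the standardized
#'   latent scale.
#' @param base_logit emission log-odds at the population-average latent
#'   level (0 gives probability 0.5).
#' @param emission_scale named multiplier in `[0, 1]` per dimension applied
#'   to the emission probability (0 suppresses a dimension entirely).
#' @param high_planted_mean mean count of planted words added to a high post
#'   (at least 1 is always added).
#' @param low_plant_rate Poisson rate of stray planted words in low posts.
#' @param prop_nonoriginal share of posts flagged as non-original (reposts).
#' @param junk_rate share of posts decorated with URL/@-mention/digit junk,
#'   to exercise the cleaning rules.
#' @param prop_institutional share of users given an institutional account.
#' @param seed optional integer for reproducibility.
#' @return list of class `sim_corpus`:
#'   \item{posts}{data.frame `post_id, user_id, timestamp, text,
#'     is_original, account_type, gender`}
#'   \item{doc_labels}{data.frame `post_id, label_LS, label_PA, label_NA`
#'     with values `"high"`/`"low"`}
#'   \item{users}{data.frame `user_id, gender, account_type, class`}
#'   \item{trajectories}{the underlying [simulate_trajectories()] draw}
#'   \item{lexicon}{the planted lexicon}
#' @export
simulate_corpus <- function(n_users,
                            spec = growth_spec(
                              intercept_mean = 0, slope_mean = 0.6,
                              intercept_sd = 1, slope_sd = 0.3,
                              intercept_slope_corr = 0.3,
                              residual_sd = rep(0.5, 4), time_codes = 0:3),
                            lex,
                            embeddings = NULL,
                            scheme = default_phase_scheme(),
                            posts_per_phase = 10,
                            tokens_per_post = 8,
                            steepness = 1.5,
                            base_logit = 0,
                            emission_scale = c(LS = 1, PA = 1, `NA` = 1),
                            high_planted_mean = 2,
                            low_plant_rate = 0.05,
                            prop_nonoriginal = 0.05,
                            junk_rate = 0.02,
                            prop_institutional = 0,
                            seed = NULL) {
  stopifnot(inherits(lex, "swb_lexicon"))
  dims <- c("LS", "PA", "NA")
  lex_words <- lapply(dims, function(d) lex$word[lex$dimension == d])
  names(lex_words) <- dims
  if (any(vapply(lex_words, length, 0L) == 0)) {
    stop("lexicon must be non-empty for LS, PA and NA", call. = FALSE)
  }
  n_phases <- nrow(scheme)
  if (length(spec$time_codes) != n_phases) {
    stop("`spec` must have one wave per phase of `scheme`", call. = FALSE)
  }
  if (posts_per_phase < 1) {
    stop("`posts_per_phase` must be >= 1", call. = FALSE)
  }
  scale <- c(LS = 1, PA = 1, `NA` = 1)
  scale[names(emission_scale)] <- emission_scale
  with_seed_set(seed)

  traj <- simulate_trajectories(spec, n_users)
  # standardize each wave by the model-implied marginal moments so the
  # emission link is scale-free in the growth parameters
  mom <- implied_moments(spec)
  marg_mu <- mom$marginal_mean
  between <- colSums(spec$mixing *
                       sweep(mom$mean, 2, marg_mu, "-")^2)
  marg_sd <- sqrt(pmax(diag(mom$cov) + between, 1e-12))
  zstd <- sweep(sweep(traj$y, 2, marg_mu, "-"), 2, marg_sd, "/")

  bg_words <- if (!is.null(embeddings)) {
    names(embeddings$dimension)[embeddings$dimension == "background"]
  } else synth_words(150, "background")
  if (!length(bg_words)) bg_words <- synth_words(150, "background")

  genders <- sample(c("male", "female"), n_users, replace = TRUE)
  acct <- ifelse(stats::runif(n_users) < prop_institutional,
                 "institutional", "personal")
  user_ids <- sprintf("u%05d", seq_len(n_users))

  n_posts <- n_users * n_phases * posts_per_phase
  post_user <- rep(seq_len(n_users), each = n_phases * posts_per_phase)
  post_phase <- rep(rep(seq_len(n_phases), each = posts_per_phase), n_users)

  # per-post emission probabilities from the user's phase latent level
  z <- zstd[cbind(post_user, post_phase)]
  p_high <- cbind(
    LS = scale[["LS"]] * stats::plogis(base_logit + steepness * z),
    PA = scale[["PA"]] * stats::plogis(base_logit + steepness * z),
    `NA` = scale[["NA"]] * stats::plogis(base_logit - steepness * z)
  )
  is_high <- matrix(stats::runif(3 * n_posts), n_posts, 3) < p_high
  colnames(is_high) <- dims

  start_s <- as.numeric(scheme$start)
  end_s <- as.numeric(scheme$end)
  ts <- as.POSIXct(start_s[post_phase] +
                     stats::runif(n_posts) *
                       (end_s[post_phase] - start_s[post_phase] - 1),
                   origin = "1970-01-01", tz = "UTC")

  texts <- character(n_posts)
  for (i in seq_len(n_posts)) {
    toks <- sample(bg_words, max(1, stats::rpois(1, tokens_per_post)),
                   replace = TRUE)
    for (d in dims) {
      n_plant <- if (is_high[i, d]) {
        1L + stats::rpois(1, max(high_planted_mean - 1, 0))
      } else {
        stats::rpois(1, low_plant_rate)
      }
      if (n_plant > 0) {
        toks <- c(toks, sample(lex_words[[d]], n_plant, replace = TRUE))
      }
    }
    toks <- sample(toks)
    txt <- paste(toks, collapse = " ")
    if (stats::runif(1) < junk_rate) {
      txt <- paste(txt, sample(c("http://t.cn/abc123", "@someone", "42"), 1))
    }
    texts[i] <- txt
  }

  posts <- data.frame(
    post_id = sprintf("p%07d", seq_len(n_posts)),
    user_id = user_ids[post_user],
    timestamp = ts,
    text = texts,
    is_original = stats::runif(n_posts) >= prop_nonoriginal,
    account_type = acct[post_user],
    gender = genders[post_user],
    stringsAsFactors = FALSE
  )
  doc_labels <- data.frame(
    post_id = posts$post_id,
    label_LS = ifelse(is_high[, "LS"], "high", "low"),
    label_PA = ifelse(is_high[, "PA"], "high", "low"),
    label_NA = ifelse(is_high[, "NA"], "high", "low"),
    stringsAsFactors = FALSE
  )
  users <- data.frame(user_id = user_ids, gender = genders,
                      account_type = acct, class = traj$class,
                      stringsAsFactors = FALSE)
  structure(list(posts = posts, doc_labels = doc_labels, users = users,
                 trajectories = traj, lexicon = lex, scheme = scheme),
            class = "sim_corpus")
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat(sprintf("Synthetic corpus: %d posts from %d users across %d phases\n",
              nrow(x$posts), nrow(x$users), nrow(x$scheme)))
  invisible(x)
}

#' Read and write post tables as JSON Lines
#'
#' One JSON record per line with fields `post_id`, `user_id`, `timestamp`
#' (ISO-8601), `text`, `is_original`, `account_type`, `gender`.
#'
#' @param posts a posts data.frame as produced by [simulate_corpus()].
#' @param path file path.
#' @return `read_posts_jsonl()` returns the posts data.frame with a POSIXct
#'   `timestamp` column.
#' @export
write_posts_jsonl <- function(posts, path) {
  out <- posts
  out$timestamp <- format(as.POSIXct(out$timestamp, tz = "UTC"),
                          "%Y-%m-%dT%H:%M:%SZ")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(out))) {
    writeLines(jsonlite::toJSON(as.list(out[i, , drop = FALSE]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_posts_jsonl
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- lapply(lines[nzchar(lines)], jsonlite::fromJSON)
  posts <- do.call(rbind, lapply(recs, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  posts$timestamp <- as.POSIXct(posts$timestamp,
                                format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  posts
}
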