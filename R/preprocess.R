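#' Clean raw post text
#'
#' Applies, in order, the cleaning rules used before segmentation:
#' (a) non-original posts are dropped; (b) topic hashtags (`#...#` spans)
#' are replaced with a blank; (c) `@username` mentions are removed;
#' (d) share placeholders (shared picture/video/article/web-page markers and
#' repost markers) are removed; (e) URLs are removed; (f) emoticons and
#' emoji are removed, including bracketed platform emoticon codes such as
#' `[笑]`; (g) Arabic digits and Latin characters are removed. A post
#' that is non-original, or whose text is empty or whitespace after
#' cleaning, maps to the drop marker `NA_character_`. The function is total
#' and idempotent.
#'
#' @param text character vector of raw post texts.
#' @param is_original logical vector (recycled); `FALSE` posts are dropped.
#' @return character vector: cleaned text, or `NA_character_` for dropped
#'   posts.
#' @examples
#' clean_post("今天 http://t.cn/abc @friend #话题# ok123")
#' @export
clean_post <- function(text, is_original = TRUE) {
  stopifnot(is.character(text))
  is_original <- rep_len(as.logical(is_original), length(text))
  out <- text
  # (b) topic hashtags  #....#  -> blank
  out <- gsub("#[^#]*#", " ", out, perl = TRUE)
  # (c) @-mentions (word characters, CJK, dash/dot)
  out <- gsub("@[A-Za-z0-9_.\\-一-鿿]+", " ", out, perl = TRUE)
  # (d) share placeholders
  share_pat <- paste0("(分享图片|分享视频|",
                      "分享文章|分享网页|",
                      "转发微博)")
  out <- gsub(share_pat, " ", out, perl = TRUE)
  # (e) URLs
  out <- gsub("(https?://|www\\.)[^\\s一-鿿]+", " ", out,
              perl = TRUE)
  # (f) bracketed emoticon codes and Unicode emoji / symbol blocks
  out <- gsub("\\[[^\\[\\]]{1,12}\\]", " ", out, perl = TRUE)
  emoji_class <- paste0(
    "[", intToUtf8(0x1F000), "-", intToUtf8(0x1FAFF),
    intToUtf8(0x2600), "-", intToUtf8(0x27BF),
    intToUtf8(0x2190), "-", intToUtf8(0x21FF),
    intToUtf8(0x2B00), "-", intToUtf8(0x2BFF), intToUtf8(0xFE0F), "]")
  out <- gsub(emoji_class, " ", out, perl = TRUE)
  # (g) Arabic digits (ASCII and fullwidth) and Latin letters
  out <- gsub("[0-9A-Za-z０-９Ａ-Ｚａ-ｚ]", "", out,
              perl = TRUE)
  out <- gsub("\\s+", " ", out, perl = TRUE)
  out <- trimws(out)
  out[!is_original | is.na(out) | out == ""] <- NA_character_
  out
}

#' Tokenize cleaned text
#'
#' Splits text into tokens with a pluggable segmentation engine and removes
#' stop words. The default engine splits on whitespace, which is exact for
#' the synthetic corpora this package generates; for real Chinese text,
#' supply a word-segmentation function (e.g. a jieba binding) with the same
#' contract: character scalar in, character vector of tokens out.
#'
#' @param text character scalar (or vector) of cleaned text.
#' @param stopwords character vector of stop words to remove.
#' @param engine function mapping one string to a character vector of
#'   tokens.
#' @return for a single string, a character vector of tokens; for a vector,
#'   a list of such vectors. Empty or `NA` text yields `character(0)`.
#' @export
tokenize <- function(text, stopwords = character(0),
                     engine = whitespace_tokenizer) {
  one <- function(tx) {
    if (is.na(tx) || !nzchar(tx)) return(character(0))
    toks <- engine(tx)
    toks[!toks %in% stopwords & nzchar(toks)]
  }
  if (length(text) == 1) one(text) else lapply(text, one)
}

#' @rdname tokenize
#' @export
whitespace_tokenizer <- function(text) {
  strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
}

#' Read a stop-word list (one word per line, UTF-8)
#' @param path file path.
#' @return character vector.
#' @export
read_stopwords <- function(path) {
  w <- readLines(path, encoding = "UTF-8")
  w <- trimws(w)
  w[nzchar(w)]
}

#' Select active users
#'
#' Keeps users whose total post count is strictly greater than
#' `min_posts` (the "more than 30 posts" rule) and whose account type is
#' personal (non-institutional).
#'
#' @param posts posts data.frame with columns `user_id` and `account_type`.
#' @param min_posts strict lower bound on the post count (default 30).
#' @return character vector of retained user ids.
#' @export
filter_active_users <- function(posts, min_posts = 30) {
  counts <- table(posts$user_id)
  acct <- tapply(posts$account_type, posts$user_id,
                 function(a) a[1])
  keep <- names(counts)[counts > min_posts &
                          acct[names(counts)] == "personal"]
  sort(unname(keep))
}

#' Assign posts to pandemic phases and apply the completeness filter
#'
#' Posts falling outside every phase window are discarded. A user is
#' retained when they have at least one original post in every phase and at
#' least `min_total` posts in total across the phases ("at least 30", a
#' non-strict bound — deliberately different from the strict active-user
#' rule).
#'
#' @param posts posts data.frame with `user_id`, `timestamp`, `is_original`.
#' @param scheme a [phase_scheme()].
#' @param min_total non-strict lower bound on a retained user's total
#'   in-window post count (default 30).
#' @return list with `posts` (in-window posts with a `phase` column) and
#'   `retained_users` (character vector).
#' @export
assign_phases <- function(posts, scheme, min_total = 30) {
  stopifnot(inherits(scheme, "phase_scheme"))
  ph <- phase_of(posts$timestamp, scheme)
  inw <- posts[!is.na(ph), , drop = FALSE]
  inw$phase <- ph[!is.na(ph)]
  n_phases <- nrow(scheme)
  orig <- inw[inw$is_original, , drop = FALSE]
  per_user_phases <- tapply(orig$phase, orig$user_id,
                            function(p) length(unique(p)))
  totals <- table(inw$user_id)
  users <- names(totals)
  covered <- users %in% names(per_user_phases) &
    per_user_phases[users] == n_phases
  retained <- users[covered & totals >= min_total]
  list(posts = inw, retained_users = sort(unname(retained)))
}

#' Preprocess a post table into tokenized documents
#'
#' Runs the full preprocessing chain: cleaning ([clean_post()]), phase
#' assignment and the active-user and completeness filters, then
#' tokenization with stop-word removal. Filter counts are recorded so runs
#' can be audited.
#'
#' @param posts raw posts data.frame (`post_id`, `user_id`, `timestamp`,
#'   `text`, `is_original`, `account_type`, `gender`).
#' @param scheme a [phase_scheme()].
#' @param stopwords character vector of stop words.
#' @param engine tokenizer engine, see [tokenize()].
#' @param min_active strict active-user threshold (post count > this).
#' @param min_total non-strict four-phase total threshold.
#' @return list of class `token_corpus`:
#'   \item{docs}{data.frame `post_id, user_id, phase, gender,
#'     n_raw_chars`}
#'   \item{tokens}{list of token vectors parallel to `docs`}
#'   \item{retained_users}{user ids passing all filters}
#'   \item{counts}{named vector of document/user counts after each step}
#' @export
preprocess_posts <- function(posts, scheme = default_phase_scheme(),
                             stopwords = character(0),
                             engine = whitespace_tokenizer,
                             min_active = 30, min_total = 30) {
  counts <- c(posts_in = nrow(posts))
  active <- filter_active_users(posts, min_posts = min_active)
  posts <- posts[posts$user_id %in% active, , drop = FALSE]
  counts["users_active"] <- length(active)
  counts["posts_active_users"] <- nrow(posts)

  cleaned <- clean_post(posts$text, posts$is_original)
  keep <- !is.na(cleaned)
  posts <- posts[keep, , drop = FALSE]
  posts$clean_text <- cleaned[keep]
  counts["posts_cleaned"] <- nrow(posts)

  ass <- assign_phases(posts, scheme, min_total = min_total)
  posts <- ass$posts
  posts <- posts[posts$user_id %in% ass$retained_users, , drop = FALSE]
  counts["users_retained"] <- length(ass$retained_users)
  counts["posts_retained"] <- nrow(posts)

  toks <- lapply(posts$clean_text, function(tx) {
    tokenize(tx, stopwords = stopwords, engine = engine)
  })
  docs <- data.frame(post_id = posts$post_id, user_id = posts$user_id,
                     phase = posts$phase,
                     gender = if ("gender" %in% names(posts)) posts$gender
                              else NA_character_,
                     n_raw_chars = nchar(posts$text),
                     stringsAsFactors = FALSE)
  structure(list(docs = docs, tokens = toks,
                 retained_users = ass$retained_users, counts = counts),
            class = "token_corpus")
}

#' @export
print.token_corpus <- function(x, ...) {
  cat("Tokenized corpus:", nrow(x$docs), "documents,",
      length(x$retained_users), "retained users\n")
  print(x$counts)
  invisible(x)
}
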