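#' Three-dimension subjective well-being lexicon
#'
#' A lexicon is a data.frame with columns `word`, `dimension` (one of
#' `"LS"`, `"PA"`, `"NA"`) and `provenance` (`"seed"`, `"expanded"` or
#' `"screened_in"`). Words are unique across dimensions: a word can belong
#' to at most one dimension.
#'
#' @param word character vector of words.
#' @param dimension character vector (recycled) of dimensions.
#' @param provenance character vector (recycled) of provenance tags.
#' @return object of class `swb_lexicon`.
#' @export
lexicon <- function(word, dimension, provenance = "seed") {
  df <- data.frame(word = as.character(word),
                   dimension = as.character(dimension),
                   provenance = as.character(provenance),
                   stringsAsFactors = FALSE)
  as_lexicon(df)
}

#' @rdname lexicon
#' @param x data.frame with columns `word`, `dimension`, `provenance`.
#' @export
as_lexicon <- function(x) {
  stopifnot(all(c("word", "dimension", "provenance") %in% names(x)))
  bad <- setdiff(unique(x$dimension), c("LS", "PA", "NA"))
  if (length(bad)) {
    stop("unknown lexicon dimension(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$word)) {
    stop("lexicon words must be unique across dimensions", call. = FALSE)
  }
  rownames(x) <- NULL
  structure(x, class = c("swb_lexicon", "data.frame"))
}

#' @export
print.swb_lexicon <- function(x, ...) {
  cat("SWB lexicon:",
      paste(sprintf("%s=%d", c("LS", "PA", "NA"),
                    vapply(c("LS", "PA", "NA"),
                           function(d) sum(x$dimension == d), 0L)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a lexicon as TSV
#'
#' Format: `word<TAB>dimension<TAB>provenance`, one word per line, UTF-8,
#' with a header row. The literal string `"NA"` is a valid dimension label
#' and is never parsed as missing.
#'
#' @param lex a [lexicon()].
#' @param path file path.
#' @export
write_lexicon <- function(lex, path) {
  utils::write.table(as.data.frame(lex), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character", fileEncoding = "UTF-8")
  as_lexicon(df)
}

#' Expand a seed lexicon through embedding neighbourhoods
#'
#' For every seed word present in the embedding table, the `top_k` nearest
#' words by cosine similarity with similarity at least `min_cos` are added
#' as expansion candidates (tag `"expanded"`). Seeds absent from the table
#' are kept with a warning but contribute no candidates. Cosine ties are
#' broken lexicographically; a word's similarity to itself is ignored. A
#' word nominated by several dimensions is assigned to the dimension where
#' its best seed-cosine is highest; words that are already seeds are never
#' re-added.
#'
#' @param seeds a [lexicon()] of seed words.
#' @param emb embedding matrix (rownames are words), e.g. from
#'   [read_word2vec()] or [simulate_embeddings()].
#' @param top_k neighbours per seed (>= 0).
#' @param min_cos minimum cosine similarity, in `[-1, 1]`.
#' @return a [lexicon()] containing seeds plus expansion candidates.
#' @export
expand_lexicon <- function(seeds, emb, top_k = 10, min_cos = 0.5) {
  stopifnot(inherits(seeds, "swb_lexicon"), is.matrix(emb))
  if (top_k < 0) stop("`top_k` must be >= 0", call. = FALSE)
  if (min_cos < -1 || min_cos > 1) {
    stop("`min_cos` must lie in [-1, 1]", call. = FALSE)
  }
  if (top_k == 0) return(seeds)
  unit <- emb / sqrt(rowSums(emb^2))
  vocab <- rownames(unit)
  missing <- setdiff(seeds$word, vocab)
  if (length(missing)) {
    warning("seed word(s) absent from embedding table: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  # collect (word, dimension, best seed cosine) nominations
  nom <- list()
  for (i in seq_len(nrow(seeds))) {
    s <- seeds$word[i]
    if (!s %in% vocab) next
    cos <- as.numeric(unit %*% unit[s, ])
    names(cos) <- vocab
    cos <- cos[names(cos) != s]
    cos <- cos[cos >= min_cos]
    if (!length(cos)) next
    ord <- order(-cos, names(cos))
    take <- ord[seq_len(min(top_k, length(ord)))]
    nom[[length(nom) + 1L]] <- data.frame(
      word = names(cos)[take], dimension = seeds$dimension[i],
      cos = cos[take], stringsAsFactors = FALSE)
  }
  if (!length(nom)) return(seeds)
  nom <- do.call(rbind, nom)
  nom <- nom[!nom$word %in% seeds$word, , drop = FALSE]
  if (!nrow(nom)) return(seeds)
  # per word, keep the dimension with the highest best-seed cosine
  best <- stats::aggregate(cos ~ word + dimension, nom, max)
  best <- best[order(best$word, -best$cos, best$dimension), ]
  best <- best[!duplicated(best$word), ]
  out <- rbind(as.data.frame(seeds),
               data.frame(word = best$word, dimension = best$dimension,
                          provenance = "expanded", stringsAsFactors = FALSE))
  as_lexicon(out[order(out$dimension, out$word), ])
}

#' Apply accept/reject screening lists to a candidate lexicon
#'
#' Mirrors a manual screening step: every word on the reject list is
#' removed (seeds included), and accepted extra words are added with tag
#' `"screened_in"`.
#'
#' @param candidates a [lexicon()].
#' @param accept data.frame with columns `word` and `dimension`, or `NULL`.
#' @param reject character vector of words to drop, or `NULL`.
#' @return the screened [lexicon()].
#' @export
apply_screening <- function(candidates, accept = NULL, reject = NULL) {
  stopifnot(inherits(candidates, "swb_lexicon"))
  acc_words <- if (is.null(accept)) character(0) else accept$word
  rej_words <- if (is.null(reject)) character(0) else as.character(reject)
  if (length(intersect(acc_words, rej_words))) {
    stop("accept and reject lists overlap: ",
         paste(intersect(acc_words, rej_words), collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(candidates)
  out <- out[!out$word %in% rej_words, , drop = FALSE]
  if (length(acc_words)) {
    add <- accept[!accept$word %in% out$word, , drop = FALSE]
    if (nrow(add)) {
      out <- rbind(out, data.frame(word = add$word,
                                   dimension = add$dimension,
                                   provenance = "screened_in",
                                   stringsAsFactors = FALSE))
    }
  }
  as_lexicon(out)
}

#' Remove lexicon words that never occur in a corpus
#'
#' Drops every word whose document frequency in `docs` is zero, so that the
#' final lexicon only carries words that can produce a nonzero TF-IDF
#' feature.
#'
#' @param lex a [lexicon()].
#' @param docs list of token character vectors (one element per document).
#' @return the pruned [lexicon()].
#' @export
prune_zero_features <- function(lex, docs) {
  stopifnot(inherits(lex, "swb_lexicon"))
  if (!length(docs)) stop("`docs` must be a non-empty corpus", call. = FALSE)
  present <- unique(unlist(lapply(docs, unique), use.names = FALSE))
  as_lexicon(as.data.frame(lex)[lex$word %in% present, , drop = FALSE])
}
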