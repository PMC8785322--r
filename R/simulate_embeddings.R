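#' Simulate a word-embedding table with planted SWB dimensions
#'
#' Generates unit-norm word vectors in which the words of each well-being
#' dimension (life satisfaction `LS`, positive affect `PA`, negative affect
#' `NA`) cluster around a dimension centroid, while background words are
#' drawn isotropically. The centroids are mutually orthogonal, so
#' within-dimension cosines exceed cross-dimension cosines by construction.
#' The first `n_seeds` words of each dimension are returned as a seed
#' lexicon, mimicking the hand-curated seed lists that bootstrap lexicon
#' expansion.
#'
#' @param vocab_sizes named integer vector with entries `LS`, `PA`, `NA`
#'   (planted words per dimension, each >= 1) and `background`.
#' @param n_seeds number of seed words per dimension (<= each planted size).
#' @param dim embedding dimensionality.
#' @param noise_sd spread of planted words around their centroid; smaller
#'   values give tighter clusters.
#' @param seed optional integer for reproducibility.
#' @return list of class `sim_embeddings` with `vectors` (matrix, one row
#'   per word, unit L2 norm), `dimension` (named character vector giving the
#'   true dimension of every planted word), and `seeds` (a [lexicon()] of
#'   the planted seed words).
#' @examples
#' emb <- simulate_embeddings(seed = 1)
#' range(sqrt(rowSums(emb$vectors^2)))  # all 1
#' @export
simulate_embeddings <- function(vocab_sizes = c(LS = 40, PA = 40, `NA` = 40,
                                                background = 120),
                                n_seeds = 8,
                                dim = 25,
                                noise_sd = 0.25,
                                seed = NULL) {
  dims <- c("LS", "PA", "NA")
  if (!all(dims %in% names(vocab_sizes))) {
    stop("`vocab_sizes` must name LS, PA and NA entries", call. = FALSE)
  }
  if (any(vocab_sizes[dims] < 1)) {
    stop("each SWB dimension needs at least one planted word", call. = FALSE)
  }
  if (n_seeds < 1 || any(n_seeds > vocab_sizes[dims])) {
    stop("`n_seeds` must be >= 1 and <= each dimension's vocabulary size",
         call. = FALSE)
  }
  if (dim < length(dims)) {
    stop("`dim` must be at least the number of dimensions", call. = FALSE)
  }
  with_seed_set(seed)
  n_bg <- if ("background" %in% names(vocab_sizes)) {
    as.integer(vocab_sizes[["background"]])
  } else 0L

  # orthonormal centroids via QR of a random Gaussian matrix
  centroids <- qr.Q(qr(matrix(stats::rnorm(dim * length(dims)), dim)))

  word_names <- c(
    unlist(lapply(seq_along(dims), function(d) {
      synth_words(vocab_sizes[[dims[d]]], dims[d])
    })),
    if (n_bg > 0) synth_words(n_bg, "background")
  )
  true_dim <- c(rep(dims, times = vocab_sizes[dims]),
                rep("background", n_bg))
  names(true_dim) <- word_names

  vecs <- matrix(NA_real_, length(word_names), dim,
                 dimnames = list(word_names, NULL))
  row <- 0L
  for (d in seq_along(dims)) {
    nd <- vocab_sizes[[dims[d]]]
    noise <- matrix(stats::rnorm(nd * dim, sd = noise_sd), nd, dim)
    vecs[row + seq_len(nd), ] <- sweep(noise, 2, centroids[, d], "+")
    row <- row + nd
  }
  if (n_bg > 0) {
    vecs[row + seq_len(n_bg), ] <- matrix(stats::rnorm(n_bg * dim), n_bg, dim)
  }
  vecs <- vecs / sqrt(rowSums(vecs^2))

  seeds <- do.call(rbind, lapply(dims, function(d) {
    w <- word_names[true_dim == d][seq_len(n_seeds)]
    data.frame(word = w, dimension = d, provenance = "seed",
               stringsAsFactors = FALSE)
  }))
  structure(list(vectors = vecs, dimension = true_dim,
                 seeds = as_lexicon(seeds)),
            class = "sim_embeddings")
}

#' @export
print.sim_embeddings <- function(x, ...) {
  cat(sprintf("Synthetic embedding table: %d words x %d dims (%s)\n",
              nrow(x$vectors), ncol(x$vectors),
              paste(sprintf("%s=%d", names(table(x$dimension)),
                            table(x$dimension)), collapse = ", ")))
  invisible(x)
}

#' Write / read embeddings in word2vec text format
#'
#' The text format starts with a header line `"<n> <dim>"` followed by one
#' line per word: the word and its coordinates, space-separated.
#'
#' @param vectors matrix with rownames as words.
#' @param path file path.
#' @return `read_word2vec()` returns the matrix; `write_word2vec()` the path,
#'   invisibly.
#' @export
write_word2vec <- function(vectors, path) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(vectors), ncol(vectors)), con)
  body <- vapply(seq_len(nrow(vectors)), function(i) {
    paste(rownames(vectors)[i],
          paste(formatC(vectors[i, ], format = "g", digits = 9),
                collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr))) {
    stop("malformed word2vec header line", call. = FALSE)
  }
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  if (nrow(vecs) != hdr[1]) {
    stop("word2vec body does not match header count", call. = FALSE)
  }
  if (any(!is.finite(vecs))) {
    stop("non-finite embedding entries", call. = FALSE)
  }
  rownames(vecs) <- words
  vecs
}


#' Synthesize CJK-style words for a dimension
#'
#' Each word is a dimension marker character followed by a two-character
#' suffix drawn from a fixed syllabary, so words are unique, deterministic,
#' and contain no Latin characters or digits (they pass the cleaning
#' rules unchanged).
#'
#' @param n number of words.
#' @param dimension `"LS"`, `"PA"`, `"NA"` or `"background"`.
#' @return character vector of length `n`.
#' @export
synth_words <- function(n, dimension = c("background", "LS", "PA", "NA")) {
  dimension <- match.arg(dimension)
  marker <- c(LS = "\u4e50", PA = "\u559c", `NA` = "\u54c0",
              background = "\u5e38")[[dimension]]
  pool <- 0x4E00 + 0:39
  vapply(seq_len(n) - 1L, function(i) {
    paste0(marker, intToUtf8(pool[i %/% 40 + 1]), intToUtf8(pool[i %% 40 + 1]))
  }, character(1))
}
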