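#' Inverse document frequencies over a training corpus
#'
#' Uses the smoothed variant \eqn{\mathrm{idf}(t) = \ln((1+N)/(1+df_t)) + 1},
#' where \eqn{N} is the number of documents and \eqn{df_t} the number of
#' documents containing term \eqn{t}.
#'
#' @param docs list of token vectors.
#' @param vocab ordered character vector of feature words.
#' @return numeric vector of idf weights, one per vocabulary word.
#' @export
compute_idf <- function(docs, vocab) {
  stopifnot(length(vocab) > 0)
  N <- length(docs)
  df <- vapply(vocab, function(w) {
    sum(vapply(docs, function(tk) w %in% tk, logical(1)))
  }, numeric(1))
  log((1 + N) / (1 + df)) + 1
}

#' TF-IDF featurization of tokenized documents
#'
#' Term frequency is the raw in-document count restricted to `vocab`; each
#' weight is `tf * idf`, and the resulting vector is L2-normalized unless it
#' is all zero (an empty document stays the zero vector).
#'
#' @param docs list of token vectors (or a single vector).
#' @param vocab ordered feature words.
#' @param idf idf weights from [compute_idf()] (same length as `vocab`).
#' @return numeric matrix, one row per document, one column per vocabulary
#'   word.
#' @examples
#' docs <- list(c("a", "a", "b"), "b")
#' idf <- compute_idf(docs, c("a", "b"))
#' featurize(docs, c("a", "b"), idf)
#' @export
featurize <- function(docs, vocab, idf) {
  stopifnot(length(vocab) > 0, length(idf) == length(vocab))
  if (is.character(docs)) docs <- list(docs)
  X <- t(vapply(docs, function(tk) {
    tf <- tabulate(match(tk, vocab), nbins = length(vocab))
    w <- tf * idf
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w / nrm else w
  }, numeric(length(vocab))))
  colnames(X) <- vocab
  X
}

#' Precision, recall and F1 for binary high/low labels
#'
#' `"high"` is the positive class. A metric with zero denominator is
#' reported as 0 with a warning.
#'
#' @param truth,pred character vectors of `"high"`/`"low"` labels.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(truth, pred) {
  tp <- sum(pred == "high" & truth == "high")
  fp <- sum(pred == "high" & truth == "low")
  fn <- sum(pred == "low" & truth == "high")
  zero_warn <- function(what) {
    warning(sprintf("%s has zero denominator; reported as 0", what),
            call. = FALSE)
    0
  }
  pre <- if (tp + fp > 0) tp / (tp + fp) else zero_warn("precision")
  re <- if (tp + fn > 0) tp / (tp + fn) else zero_warn("recall")
  f1 <- if (pre + re > 0) 2 * pre * re / (pre + re) else 0
  c(precision = pre, recall = re, f1 = f1)
}

#' Stratified cross-validation folds
#' @keywords internal
#' @noRd
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Train a high/low classifier for one well-being dimension
#'
#' TF-IDF features over the lexicon vocabulary feed a radial-kernel support
#' vector machine. Hyper-parameters are selected by exhaustive grid search
#' maximizing mean cross-validated F1 (stratified folds); ties prefer the
#' smaller `C`, then the smaller `gamma`. The winning pair is refit on all
#' data.
#'
#' @param docs list of token vectors.
#' @param labels character vector of `"high"`/`"low"` training labels.
#' @param vocab feature vocabulary (ordered lexicon words).
#' @param dimension dimension id stored with the model (`"LS"`, `"PA"`,
#'   `"NA"`).
#' @param C_grid,gamma_grid candidate values; defaults
#'   `C in {0.1, 1, 10, 100}`, `gamma in {0.01, 0.1, 1}`.
#' @param folds number of stratified CV folds (>= 2).
#' @param seed optional integer controlling fold assignment.
#' @return object of class `swb_classifier` with elements `dimension`,
#'   `vocab`, `idf`, `C`, `gamma`, `svm` (the fitted [e1071::svm()] model),
#'   `cv_table` (mean CV F1 per grid point) and `cv_report` (pooled
#'   precision/recall/F1 of the winning grid point's out-of-fold
#'   predictions).
#' @export
train_swb_classifier <- function(docs, labels, vocab,
                                 dimension = "LS",
                                 C_grid = c(0.1, 1, 10, 100),
                                 gamma_grid = c(0.01, 0.1, 1),
                                 folds = 5, seed = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("training labels must contain both classes", call. = FALSE)
  }
  if (folds < 2) stop("`folds` must be >= 2", call. = FALSE)
  with_seed_set(seed)
  idf <- compute_idf(docs, vocab)
  X <- featurize(docs, vocab, idf)
  y <- factor(labels, levels = c("low", "high"))
  fold <- stratified_folds(labels, folds)

  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  grid <- grid[order(grid$C, grid$gamma), ]
  cv_f1 <- numeric(nrow(grid))
  oof_best <- NULL
  for (g in seq_len(nrow(grid))) {
    oof <- rep(NA_character_, length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = grid$C[g], gamma = grid$gamma[g],
                      scale = FALSE)
      oof[!tr] <- as.character(stats::predict(m, X[!tr, , drop = FALSE]))
    }
    ok <- !is.na(oof)
    per_fold <- vapply(seq_len(folds), function(f) {
      sel <- fold == f & ok
      if (!any(sel)) return(NA_real_)
      suppressWarnings(
        classification_metrics(labels[sel], oof[sel])[["f1"]])
    }, numeric(1))
    cv_f1[g] <- mean(per_fold, na.rm = TRUE)
    if (g == which.max(replace(cv_f1, seq_len(nrow(grid)) > g, -Inf))) {
      oof_best <- oof
    }
  }
  best <- which.max(cv_f1)  # grid sorted by (C, gamma): ties -> smaller
  fit <- e1071::svm(X, y, kernel = "radial", cost = grid$C[best],
                    gamma = grid$gamma[best], scale = FALSE)
  ok <- !is.na(oof_best)
  report <- suppressWarnings(
    classification_metrics(labels[ok], oof_best[ok]))
  structure(list(dimension = dimension, vocab = vocab, idf = idf,
                 C = grid$C[best], gamma = grid$gamma[best], svm = fit,
                 folds = folds,
                 cv_table = cbind(grid, mean_f1 = cv_f1),
                 cv_report = report),
            class = "swb_classifier")
}

#' @export
print.swb_classifier <- function(x, ...) {
  cat(sprintf("SWB classifier [%s]: RBF-SVM, C = %g, gamma = %g, %d features\n",
              x$dimension, x$C, x$gamma, length(x$vocab)))
  cat(sprintf("  CV (pooled, %d folds): precision %.3f, recall %.3f, F1 %.3f\n",
              x$folds, x$cv_report["precision"], x$cv_report["recall"],
              x$cv_report["f1"]))
  invisible(x)
}

#' Predict high/low labels for tokenized documents
#'
#' Documents are featurized with the model's vocabulary and idf weights. A
#' document with an all-zero feature vector (e.g. an empty document) is
#' labelled `"low"` by convention.
#'
#' @param object a `swb_classifier`.
#' @param docs list of token vectors.
#' @param ... unused.
#' @return character vector of `"high"`/`"low"` labels.
#' @export
predict.swb_classifier <- function(object, docs, ...) {
  X <- featurize(docs, object$vocab, object$idf)
  pred <- as.character(stats::predict(object$svm, X))
  pred[rowSums(abs(X)) == 0] <- "low"
  pred
}

#' Evaluate a classifier on labelled documents
#'
#' @param model a `swb_classifier`.
#' @param docs list of token vectors.
#' @param labels true `"high"`/`"low"` labels.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
evaluate_classifier <- function(model, docs, labels) {
  classification_metrics(as.character(labels), predict(model, docs))
}

#' Predict all three dimensions for a tokenized corpus
#'
#' @param models named list of `swb_classifier` objects (`LS`, `PA`, `NA`).
#' @param corpus a `token_corpus` from [preprocess_posts()], or a list of
#'   token vectors.
#' @return data.frame with one row per document and columns `label_LS`,
#'   `label_PA`, `label_NA` (plus the corpus doc columns when available).
#' @export
predict_dimensions <- function(models, corpus) {
  stopifnot(all(c("LS", "PA", "NA") %in% names(models)))
  toks <- if (inherits(corpus, "token_corpus")) corpus$tokens else corpus
  out <- data.frame(
    label_LS = predict(models[["LS"]], toks),
    label_PA = predict(models[["PA"]], toks),
    label_NA = predict(models[["NA"]], toks),
    stringsAsFactors = FALSE
  )
  if (inherits(corpus, "token_corpus")) {
    out <- cbind(corpus$docs, out)
  }
  out
}
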