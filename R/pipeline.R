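#' Default pipeline configuration
#'
#' All knobs of [run_pipeline()] with their defaults, as a nested list that
#' can be dumped to YAML, edited, and read back with
#' [read_pipeline_config()]. Stage toggles allow partial runs; every random
#' draw in the pipeline flows from the single `seed` through named
#' per-stage substreams.
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "swb_run",
    stages = list(simulate = TRUE, preprocess = TRUE, lexicon = TRUE,
                  classify = TRUE, score = TRUE, lgcm = TRUE, lgmm = TRUE),
    simulate = list(
      n_users = 150L, posts_per_phase = 12L,
      intercept_mean = 0, slope_mean = 0.6,
      intercept_sd = 1, slope_sd = 0.3, intercept_slope_corr = 0.3,
      residual_sd = 0.5, steepness = 1.5,
      vocab = list(LS = 40L, PA = 40L, `NA` = 40L, background = 120L),
      n_seeds = 8L
    ),
    paths = list(posts = NULL, seeds = NULL, embeddings = NULL,
                 stoplist = NULL, accept = NULL, reject = NULL),
    filters = list(min_active = 30L, min_total = 30L),
    lexicon = list(top_k = 10L, min_cos = 0.5),
    classifier = list(C_grid = c(0.1, 1, 10, 100),
                      gamma_grid = c(0.01, 0.1, 1),
                      folds = 5L, train_n = 600L),
    growth = list(phases = 2:4, K_range = 1:3, n_starts = 20L, blrt_B = 0L)
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' Values absent from the file fall back to [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_pipeline_config(), user)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Executes, per the stage toggles: corpus simulation (or reading posts
#' from `paths$posts`), preprocessing and filtering, lexicon construction,
#' classifier training (on the synthetic ground-truth labels), per-phase
#' SWB scoring with descriptives and ANOVA, LGCM fitting with fit indices
#' and the gender-covariate extension, and LGMM class enumeration. All
#' artifacts are written to `config$out_dir` together with a manifest
#' recording the package version, seed, per-stage counts and MD5 hashes of
#' every output file; identical config and seed give identical hashes. A
#' stage failure aborts with a stage-named error, leaving earlier artifacts
#' in place.
#'
#' @param config list as produced by [default_pipeline_config()] (or a path
#'   to a YAML file).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- modifyList(default_pipeline_config(), config)
  for (pth in Filter(Negate(is.null), cfg$paths)) {
    if (!file.exists(pth)) {
      stop("configured path does not exist: ", pth, call. = FALSE)
    }
  }
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  substream <- function(k) seed * 131L + k  # named per-stage substreams
  manifest <- list(package = "swbgrowth",
                   version = as.character(utils::packageVersion("swbgrowth")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC"),
                   seed = seed, config = cfg, stages = list(),
                   counts = list(), files = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(obj, file, writer = utils::write.csv) {
    path <- file.path(out, file)
    if (identical(writer, utils::write.csv)) {
      utils::write.csv(obj, path, row.names = FALSE)
    } else {
      writer(obj, path)
    }
    manifest$files <<- c(manifest$files, file)
    path
  }

  scheme <- default_phase_scheme()
  corpus <- NULL
  lex_seeds <- NULL
  emb <- NULL

  if (isTRUE(cfg$stages$simulate)) {
    stage("simulate", {
      sim <- cfg$simulate
      embs <- simulate_embeddings(
        vocab_sizes = unlist(sim$vocab), n_seeds = sim$n_seeds,
        seed = substream(1L))
      emb <- embs$vectors
      lex_seeds <- embs$seeds
      planted <- lexicon(names(embs$dimension)[embs$dimension != "background"],
                         embs$dimension[embs$dimension != "background"])
      spec <- growth_spec(
        intercept_mean = sim$intercept_mean, slope_mean = sim$slope_mean,
        intercept_sd = sim$intercept_sd, slope_sd = sim$slope_sd,
        intercept_slope_corr = sim$intercept_slope_corr,
        residual_sd = rep(sim$residual_sd, nrow(scheme)),
        time_codes = seq_len(nrow(scheme)) - 1)
      corpus <- simulate_corpus(
        n_users = sim$n_users, spec = spec, lex = planted,
        embeddings = embs, scheme = scheme,
        posts_per_phase = sim$posts_per_phase,
        steepness = sim$steepness, seed = substream(2L))
      emit(corpus$posts, "posts.jsonl", write_posts_jsonl)
      emit(emb, "embeddings.w2v.txt", write_word2vec)
      emit(corpus$doc_labels, "truth_doc_labels.csv")
      emit(corpus$users, "truth_users.csv")
      manifest$counts$simulated_posts <- nrow(corpus$posts)
    })
  }

  posts <- if (!is.null(cfg$paths$posts)) {
    read_posts_jsonl(cfg$paths$posts)
  } else if (!is.null(corpus)) corpus$posts else {
    stop("stage 'preprocess' failed: no posts available ",
         "(enable the simulate stage or set paths$posts)", call. = FALSE)
  }
  if (!is.null(cfg$paths$embeddings)) emb <- read_word2vec(cfg$paths$embeddings)
  if (!is.null(cfg$paths$seeds)) lex_seeds <- read_lexicon(cfg$paths$seeds)

  tok <- NULL
  if (isTRUE(cfg$stages$preprocess)) {
    stage("preprocess", {
      stops <- if (!is.null(cfg$paths$stoplist)) {
        read_stopwords(cfg$paths$stoplist)
      } else character(0)
      tok <- preprocess_posts(posts, scheme = scheme, stopwords = stops,
                              min_active = cfg$filters$min_active,
                              min_total = cfg$filters$min_total)
      emit(tok$docs, "token_docs.csv")
      manifest$counts <- c(manifest$counts, as.list(tok$counts))
    })
  }

  lex <- NULL
  if (isTRUE(cfg$stages$lexicon)) {
    stage("lexicon", {
      if (is.null(lex_seeds) || is.null(emb)) {
        stop("lexicon stage needs seed words and embeddings")
      }
      cand <- expand_lexicon(lex_seeds, emb, top_k = cfg$lexicon$top_k,
                             min_cos = cfg$lexicon$min_cos)
      accept <- if (!is.null(cfg$paths$accept)) {
        utils::read.delim(cfg$paths$accept, na.strings = NULL,
                          colClasses = "character")
      } else NULL
      reject <- if (!is.null(cfg$paths$reject)) {
        read_stopwords(cfg$paths$reject)
      } else NULL
      cand <- apply_screening(cand, accept = accept, reject = reject)
      lex <- prune_zero_features(cand, tok$tokens)
      emit(as.data.frame(lex), "lexicon.tsv", function(o, p) {
        write_lexicon(as_lexicon(o), p)
      })
      manifest$counts$lexicon_words <- nrow(lex)
    })
  }

  models <- NULL
  if (isTRUE(cfg$stages$classify)) {
    stage("classify", {
      if (is.null(corpus)) stop("classifier training labels require the ",
                                "synthetic corpus truth")
      truth <- corpus$doc_labels[match(tok$docs$post_id,
                                       corpus$doc_labels$post_id), ]
      n_train <- min(cfg$classifier$train_n, nrow(tok$docs))
      with_seed_set(substream(3L))
      tr_idx <- sample.int(nrow(tok$docs), n_train)
      models <- list()
      for (d in c("LS", "PA", "NA")) {
        models[[d]] <- train_swb_classifier(
          tok$tokens[tr_idx], truth[[paste0("label_", d)]][tr_idx],
          vocab = lex$word, dimension = d,
          C_grid = cfg$classifier$C_grid,
          gamma_grid = cfg$classifier$gamma_grid,
          folds = cfg$classifier$folds, seed = substream(4L))
      }
      cvrep <- do.call(rbind, lapply(models, function(m) {
        data.frame(dimension = m$dimension, C = m$C, gamma = m$gamma,
                   t(m$cv_report))
      }))
      emit(cvrep, "classifier_cv.csv")
    })
  }

  counts <- NULL
  if (isTRUE(cfg$stages$score)) {
    stage("score", {
      labelled <- predict_dimensions(models, tok)
      counts <- phase_counts(labelled)
      emit(as.data.frame(counts), "phase_counts.csv")
      emit(phase_descriptives(counts), "phase_descriptives.csv")
      av <- anova_phases(counts)
      emit(data.frame(variable = names(av),
                      F = vapply(av, `[[`, 0, "F"),
                      df1 = vapply(av, `[[`, 0, "df1"),
                      df2 = vapply(av, `[[`, 0, "df2"),
                      p = vapply(av, `[[`, 0, "p")),
           "phase_anova.csv")
    })
  }

  traj <- NULL
  if (isTRUE(cfg$stages$lgcm)) {
    stage("lgcm", {
      traj <- trajectory_matrix(counts, phases = cfg$growth$phases)
      fit <- fit_lgcm(traj$y, times = traj$time_codes)
      fi <- fit_indices(fit)
      gender01 <- as.integer(traj$gender == "female")
      cond <- if (stats::var(gender01) > 0) {
        fit_conditional_lgcm(traj$y, gender01, times = traj$time_codes)
      } else NULL
      res <- list(unconditional = c(
        list(alpha = as.list(fit$alpha), psi = as.list(fit$psi),
             r = fit$r, logL = fit$logL, q = fit$q, n = fit$n),
        unclass(fi)))
      if (!is.null(cond)) {
        res$conditional <- list(alpha = as.list(cond$alpha),
                                r = cond$r, logL = cond$logL, q = cond$q)
      }
      emit(res, "lgcm_fit.json", function(o, p) {
        jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
      })
    })
  }

  if (isTRUE(cfg$stages$lgmm)) {
    stage("lgmm", {
      if (is.null(traj)) traj <- trajectory_matrix(counts,
                                                   phases = cfg$growth$phases)
      enum <- enumerate_classes(traj$y, K_range = cfg$growth$K_range,
                                times = traj$time_codes,
                                n_starts = cfg$growth$n_starts,
                                B = cfg$growth$blrt_B,
                                seed = substream(5L))
      emit(enum$table, "class_enumeration.csv")
      bestfit <- enum$fits[[enum$selected]]
      emit(cbind(user_id = traj$user_id,
                 as.data.frame(bestfit$posterior),
                 modal = bestfit$assignment), "posteriors.csv")
      emit(list(K = bestfit$K, pi = bestfit$pi,
                alpha = as.data.frame(bestfit$alpha),
                Psi = bestfit$Psi, theta = bestfit$theta,
                logL = bestfit$logL, entropy = bestfit$entropy,
                avg_posterior = avg_posterior_matrix(bestfit$posterior,
                                                     bestfit$assignment)),
           "lgmm_fit.json", function(o, p) {
        jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
      })
      grDevices::png(file.path(out, "class_trajectories.png"),
                     width = 720, height = 480)
      plot_class_trajectories(bestfit, traj$y)
      grDevices::dev.off()
      manifest$files <- c(manifest$files, "class_trajectories.png")
      manifest$counts$selected_K <- enum$selected
    })
  }

  hash_files <- setdiff(manifest$files, "class_trajectories.png")
  manifest$hashes <- as.list(tools::md5sum(file.path(out, hash_files)))
  names(manifest$hashes) <- hash_files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Render a human-readable report for a pipeline run
#'
#' Summarizes the manifest and the tabular artifacts of a completed (or
#' partial) run: filter counts, per-phase descriptives with ANOVA, the LGCM
#' fit, the class-enumeration table and the selected mixture. Missing
#' stages are marked as skipped rather than failing.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param file optional output file (default `report.txt` inside
#'   `run_dir`).
#' @return character vector of report lines, invisibly.
#' @export
make_report <- function(run_dir, file = file.path(run_dir, "report.txt")) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop("no manifest.json in ", run_dir, call. = FALSE)
  }
  man <- jsonlite::fromJSON(man_path)
  lines <- c(sprintf("swbgrowth run report (%s, seed %s)", man$created,
                     man$seed),
             sprintf("executed stages: %s",
                     paste(names(Filter(isTRUE, man$config$stages)),
                           collapse = ", ")),
             "")
  show_csv <- function(fname, title) {
    path <- file.path(run_dir, fname)
    if (file.exists(path)) {
      tab <- utils::read.csv(path, check.names = FALSE)
      c(title, utils::capture.output(print(tab, row.names = FALSE)), "")
    } else {
      c(title, "  [stage skipped]", "")
    }
  }
  lines <- c(lines,
             "Filter counts:",
             vapply(names(man$counts), function(k) {
               sprintf("  %-22s %s", k, man$counts[[k]])
             }, character(1)),
             "",
             show_csv("phase_descriptives.csv",
                      "Per-phase descriptives (mean, SD):"),
             show_csv("phase_anova.csv", "One-way ANOVA across phases:"),
             show_csv("classifier_cv.csv", "Classifier CV performance:"),
             show_csv("class_enumeration.csv",
                      "Class enumeration (K, logL, AIC, BIC, aBIC, entropy, LMR, BLRT):"))
  lgcm_path <- file.path(run_dir, "lgcm_fit.json")
  if (file.exists(lgcm_path)) {
    f <- jsonlite::fromJSON(lgcm_path)
    lines <- c(lines, "LGCM (unconditional):",
               sprintf("  alpha_I = %.4g, alpha_S = %.4g, r = %.3f",
                       f$unconditional$alpha$alpha_I,
                       f$unconditional$alpha$alpha_S, f$unconditional$r),
               sprintf(paste0("  chisq(%s) = %.3f, CFI = %.3f, TLI = %.3f, ",
                              "RMSEA = %.3f, SRMR = %.3f"),
                       f$unconditional$df, f$unconditional$chisq,
                       f$unconditional$CFI, f$unconditional$TLI,
                       f$unconditional$RMSEA, f$unconditional$SRMR), "")
  } else {
    lines <- c(lines, "LGCM: [stage skipped]", "")
  }
  lgmm_path <- file.path(run_dir, "lgmm_fit.json")
  if (file.exists(lgmm_path)) {
    f <- jsonlite::fromJSON(lgmm_path)
    lines <- c(lines, sprintf("Selected LGMM: K = %s", f$K),
               utils::capture.output(print(f$alpha, row.names = FALSE)),
               "Average posterior probability matrix:",
               utils::capture.output(print(round(as.matrix(f$avg_posterior),
                                                 4))))
  } else {
    lines <- c(lines, "LGMM: [stage skipped]")
  }
  writeLines(lines, file)
  invisible(lines)
}
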