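#' Subjective well-being count score
#'
#' The per-user per-phase SWB score is the number of high life-satisfaction
#' posts plus the number of high positive-affect posts minus the number of
#' high negative-affect posts. It may be negative.
#'
#' @param n_ls,n_pa,n_na nonnegative counts (vectorized).
#' @return integer-valued numeric vector `n_ls + n_pa - n_na`.
#' @examples
#' swb_score(10, 5, 3)  # 12
#' @export
swb_score <- function(n_ls, n_pa, n_na) {
  if (any(c(n_ls, n_pa, n_na) < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  n_ls + n_pa - n_na
}

#' Aggregate predicted labels into per-user per-phase counts
#'
#' @param labelled data.frame with columns `user_id`, `phase`, `label_LS`,
#'   `label_PA`, `label_NA` (and optionally `gender`), as produced by
#'   [predict_dimensions()].
#' @return data.frame of class `phase_counts` with columns `user_id`,
#'   `gender`, `phase`, `n_high_LS`, `n_high_PA`, `n_high_NA`, `n_posts`,
#'   `swb`.
#' @export
phase_counts <- function(labelled) {
  req <- c("user_id", "phase", "label_LS", "label_PA", "label_NA")
  stopifnot(all(req %in% names(labelled)))
  key <- interaction(labelled$user_id, labelled$phase, drop = TRUE)
  agg <- function(v) as.numeric(tapply(v, key, sum))
  first <- function(v) as.vector(tapply(v, key, function(x) x[1]))
  out <- data.frame(
    user_id = first(labelled$user_id),
    gender = if ("gender" %in% names(labelled)) first(labelled$gender)
             else NA_character_,
    phase = as.integer(first(labelled$phase)),
    n_high_LS = agg(labelled$label_LS == "high"),
    n_high_PA = agg(labelled$label_PA == "high"),
    n_high_NA = agg(labelled$label_NA == "high"),
    n_posts = as.numeric(tapply(rep(1, nrow(labelled)), key, sum)),
    stringsAsFactors = FALSE
  )
  out$swb <- swb_score(out$n_high_LS, out$n_high_PA, out$n_high_NA)
  out <- out[order(out$user_id, out$phase), ]
  rownames(out) <- NULL
  class(out) <- c("phase_counts", "data.frame")
  out
}

#' Per-phase descriptive statistics
#'
#' Mean and sample standard deviation (n-1 denominator) of the high-LS,
#' high-PA, high-NA counts and the SWB score, per phase.
#'
#' @param counts a [phase_counts()] data.frame.
#' @return data.frame with columns `variable`, `phase`, `mean`, `sd`, `n`.
#' @export
phase_descriptives <- function(counts) {
  if (length(unique(counts$user_id)) < 2) {
    stop("descriptives need at least 2 users", call. = FALSE)
  }
  vars <- c(LS = "n_high_LS", PA = "n_high_PA", `NA` = "n_high_NA",
            SWB = "swb")
  out <- do.call(rbind, lapply(names(vars), function(v) {
    col <- counts[[vars[[v]]]]
    data.frame(
      variable = v,
      phase = sort(unique(counts$phase)),
      mean = as.numeric(tapply(col, counts$phase, mean)),
      sd = as.numeric(tapply(col, counts$phase, stats::sd)),
      n = as.numeric(tapply(col, counts$phase, length)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of the well-being variables across phases
#'
#' By default a one-way repeated-measures ANOVA (phase as the within-user
#' factor, complete cases only) with Bonferroni-corrected paired pairwise
#' comparisons; `type = "between"` treats phases as independent groups.
#'
#' @param counts a [phase_counts()] data.frame.
#' @param type `"repeated"` (default) or `"between"`.
#' @return list of class `phase_anova`: per variable, a list with `F`,
#'   `df1`, `df2`, `p`, and `pairwise` (matrix of Bonferroni-adjusted
#'   p-values).
#' @export
anova_phases <- function(counts, type = c("repeated", "between")) {
  type <- match.arg(type)
  phases <- sort(unique(counts$phase))
  if (length(phases) < 2) stop("need >= 2 phases", call. = FALSE)
  vars <- c(LS = "n_high_LS", PA = "n_high_PA", `NA` = "n_high_NA",
            SWB = "swb")
  if (type == "repeated") {
    keep <- names(which(table(counts$user_id) == length(phases)))
    counts <- counts[counts$user_id %in% keep, , drop = FALSE]
    if (length(keep) < 2) {
      stop("repeated-measures ANOVA needs >= 2 complete cases",
           call. = FALSE)
    }
  }
  res <- lapply(names(vars), function(v) {
    y <- counts[[vars[[v]]]]
    if (stats::var(y) == 0) {
      stop(sprintf("variable %s has zero total variance", v), call. = FALSE)
    }
    ph <- factor(counts$phase)
    if (type == "repeated") {
      uid <- factor(counts$user_id)
      fit <- stats::aov(y ~ ph + Error(uid))
      tab <- summary(fit)[["Error: Within"]][[1]]
      rn <- trimws(rownames(tab))
      Fv <- tab[rn == "ph", "F value"]
      df1 <- tab[rn == "ph", "Df"]
      df2 <- tab[rn == "Residuals", "Df"]
      p <- tab[rn == "ph", "Pr(>F)"]
      pw <- stats::pairwise.t.test(y, ph, paired = TRUE,
                                   p.adjust.method = "bonferroni")$p.value
    } else {
      fit <- stats::aov(y ~ ph)
      tab <- summary(fit)[[1]]
      rn <- trimws(rownames(tab))
      Fv <- tab[rn == "ph", "F value"]
      df1 <- tab[rn == "ph", "Df"]
      df2 <- tab[rn == "Residuals", "Df"]
      p <- tab[rn == "ph", "Pr(>F)"]
      pw <- stats::pairwise.t.test(y, ph,
                                   p.adjust.method = "bonferroni")$p.value
    }
    list(F = unname(Fv), df1 = unname(df1), df2 = unname(df2),
         p = unname(p), pairwise = pw)
  })
  names(res) <- names(vars)
  structure(res, class = "phase_anova", type = type)
}

#' @export
print.phase_anova <- function(x, ...) {
  cat(sprintf("One-way %s ANOVA across phases\n", attr(x, "type")))
  for (v in names(x)) {
    cat(sprintf("  %-4s F(%d, %d) = %.2f, p = %.3g\n", v,
                x[[v]]$df1, x[[v]]$df2, x[[v]]$F, x[[v]]$p))
  }
  invisible(x)
}

#' Reshape phase counts to a user x wave trajectory matrix
#'
#' Extracts complete cases for the requested phases and returns the outcome
#' matrix used by the growth models, with the per-user covariate.
#'
#' @param counts a [phase_counts()] data.frame.
#' @param phases phases to use as waves, in order (default phases 2 to 4,
#'   the post-outbreak waves).
#' @param outcome column to model (default `"swb"`).
#' @return list with `y` (n x T matrix), `user_id`, `gender` and
#'   `time_codes` (`0..T-1`).
#' @export
trajectory_matrix <- function(counts, phases = 2:4, outcome = "swb") {
  sub <- counts[counts$phase %in% phases, , drop = FALSE]
  complete <- names(which(table(sub$user_id) == length(phases)))
  sub <- sub[sub$user_id %in% complete, , drop = FALSE]
  sub <- sub[order(sub$user_id, sub$phase), ]
  n <- length(complete)
  y <- matrix(sub[[outcome]], nrow = n, ncol = length(phases), byrow = TRUE,
              dimnames = list(sort(complete), paste0("w", seq_along(phases))))
  gender <- sub$gender[!duplicated(sub$user_id)]
  list(y = y, user_id = sort(complete), gender = gender,
       time_codes = seq_along(phases) - 1)
}
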