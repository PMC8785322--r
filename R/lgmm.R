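#' Fit a latent growth mixture model by EM
#'
#' Maximizes \eqn{\sum_i \ln \sum_k \pi_k\,\phi(y_i; \Lambda\alpha_k,
#' \Lambda\Psi\Lambda' + \Theta)} over K latent trajectory classes with
#' class-specific growth-factor means \eqn{\alpha_k} and a growth-factor
#' covariance \eqn{\Psi} and diagonal residual covariance \eqn{\Theta}
#' shared across classes. The E-step computes class posteriors and the
#' conditional moments of the growth factors; the M-step updates
#' \eqn{\pi_k} and \eqn{\alpha_k} in closed form and \eqn{\Psi},
#' \eqn{\Theta} from the expected complete-data moments, so the observed
#' log-likelihood is nondecreasing across iterations (asserted each
#' iteration). The best of `n_starts` starts is kept: the first start is
#' initialized from k-means on per-user OLS intercepts/slopes, the rest from
#' random perturbations. Classes are reported sorted by slope mean,
#' descending. Variances that collapse are floored at 1e-8 with a warning;
#' a start whose smallest mixing proportion falls below 1/n is abandoned as
#' degenerate.
#'
#' @param y n x T outcome matrix.
#' @param K number of latent classes (>= 1).
#' @param times time codes, one per wave.
#' @param n_starts number of EM starts (default 50).
#' @param seed optional integer controlling the starts.
#' @param max_iter maximum EM iterations for the winning start.
#' @param start_iter EM iterations granted to every start in the screening
#'   stage before the best start is pursued to convergence.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param polish refine the best EM solution with a quasi-Newton pass on
#'   the marginal log-likelihood (default `TRUE`); EM's linear convergence
#'   can crawl on the shared factor/residual variance split, and the polish
#'   step closes the last fraction of a log-likelihood unit.
#' @param polish_control control list for the quasi-Newton polish
#'   ([stats::nlminb()]).
#' @param se compute standard errors (numerical Hessian of the mixture
#'   log-likelihood at the optimum); skipped when `FALSE` for speed.
#' @return object of class `lgmm_fit`: `K`, `pi` (mixing proportions),
#'   `alpha` (K x 2 matrix of class intercept/slope means), `Psi`, `theta`,
#'   `logL`, `q`, `n`, `posterior` (n x K), `assignment` (modal classes),
#'   `entropy`, `ic` (AIC/BIC/aBIC), `logL_trace` of the winning start,
#'   `se`/`p_values` for the class means, `converged`, `n_degenerate`.
#' @export
fit_lgmm <- function(y, K, times = seq_len(ncol(y)) - 1,
                     n_starts = 50, seed = NULL, max_iter = 500,
                     start_iter = 60, tol = 1e-6, polish = TRUE,
                     polish_control = list(iter.max = 300, eval.max = 900,
                                           rel.tol = 1e-11),
                     se = FALSE) {
  y <- as.matrix(y)
  n <- nrow(y)
  p <- ncol(y)
  if (K < 1) stop("`K` must be >= 1", call. = FALSE)
  if (n_starts < 1) stop("`n_starts` must be >= 1", call. = FALSE)
  if (anyNA(y)) stop("`y` must be complete", call. = FALSE)
  with_seed_set(seed)
  Lam <- growth_loadings(times)
  XtXi <- solve(crossprod(Lam))
  b <- y %*% Lam %*% XtXi                      # per-user OLS factors
  e <- y - b %*% t(Lam)
  Psi_init <- stats::cov(b)
  Psi_init <- Psi_init + diag(2) * (0.05 * mean(diag(Psi_init)) + 1e-6)
  theta_init <- pmax(colSums(e^2) / n, 1e-4)

  starts <- vector("list", n_starts)
  km <- tryCatch(stats::kmeans(b, centers = K, nstart = 5),
                 error = function(e) NULL)
  starts[[1]] <- if (!is.null(km)) {
    list(alpha = matrix(km$centers, K, 2),
         pi = pmax(as.numeric(table(factor(km$cluster, levels = 1:K))) / n,
                   1e-3))
  } else {
    list(alpha = matrix(colMeans(b), K, 2, byrow = TRUE), pi = rep(1 / K, K))
  }
  starts[[1]]$pi <- starts[[1]]$pi / sum(starts[[1]]$pi)
  if (n_starts > 1) {
    sds <- apply(b, 2, stats::sd)
    for (s in 2:n_starts) {
      base <- b[sample.int(n, K), , drop = FALSE]
      starts[[s]] <- list(
        alpha = base + matrix(stats::rnorm(2 * K, sd = 0.25 * sds),
                              K, 2, byrow = TRUE),
        pi = {
          w <- stats::runif(K, 0.2, 1)
          w / sum(w)
        })
    }
  }

  best <- NULL
  n_degenerate <- 0L
  for (s in seq_len(n_starts)) {
    run <- em_lgmm_run(y, Lam, K, starts[[s]]$alpha, starts[[s]]$pi,
                       Psi_init, theta_init, min(start_iter, max_iter), tol)
    if (is.null(run)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    if (is.null(best) || run$logL > best$logL) best <- run
  }
  if (is.null(best)) {
    stop("all EM starts degenerated (empty class); model flagged as failed",
         call. = FALSE)
  }
  # pursue the winning start to convergence
  if (!best$converged && max_iter > start_iter) {
    cont <- em_lgmm_run(y, Lam, K, best$alpha, best$pi, best$Psi,
                        best$theta, max_iter - start_iter, tol)
    if (!is.null(cont)) {
      cont$trace <- c(best$trace, cont$trace)
      best <- cont
    }
  }
  if (polish) {
    pol <- polish_lgmm(y, Lam, K, best, polish_control)
    if (!is.null(pol) && pol$logL >= best$logL) {
      pol$trace <- c(best$trace, pol$logL)
      pol$floored <- best$floored
      best <- pol
    }
  }

  # label switching: sort classes by slope mean, descending
  ord <- order(best$alpha[, 2], decreasing = TRUE)
  alpha <- best$alpha[ord, , drop = FALSE]
  dimnames(alpha) <- list(paste0("class", seq_len(K)),
                          c("intercept", "slope"))
  pi_k <- best$pi[ord]
  post <- best$post[, ord, drop = FALSE]
  colnames(post) <- rownames(alpha)
  assignment <- max.col(post, ties.method = "first")

  q <- 2 * K + (K - 1) + 3 + p
  ic <- information_criteria(best$logL, q, n)
  ent <- if (K > 1) relative_entropy(post) else NA_real_

  se_vec <- p_vec <- NULL
  if (se) {
    nat0 <- c(t(alpha))
    nll_nat <- function(parn) {
      a <- matrix(parn, K, 2, byrow = TRUE)
      -lgmm_loglik(y, Lam, a, pi_k, best$Psi, best$theta)
    }
    H <- num_hessian(nll_nat, nat0)
    se_vec <- se_from_information(H)
    nm <- as.vector(t(outer(rownames(alpha), c("intercept", "slope"),
                            paste, sep = ".")))
    names(se_vec) <- nm
    p_vec <- 2 * stats::pnorm(-abs(nat0 / se_vec))
    names(p_vec) <- nm
  }

  structure(list(K = K, pi = pi_k, alpha = alpha, Psi = best$Psi,
                 theta = best$theta, logL = best$logL, q = q, n = n,
                 times = times, posterior = post, assignment = assignment,
                 entropy = ent, ic = ic, logL_trace = best$trace,
                 se = se_vec, p_values = p_vec,
                 converged = best$converged,
                 n_degenerate = n_degenerate,
                 variance_floored = best$floored),
            class = "lgmm_fit")
}

#' E-step: mixture log-likelihood and class posteriors
#' @keywords internal
#' @noRd
lgmm_estep <- function(y, Lam, alpha, pi_k, Psi, theta, yt = t(y)) {
  n <- nrow(y)
  p <- ncol(y)
  K <- nrow(alpha)
  Sigma <- Lam %*% Psi %*% t(Lam) + diag(theta, p)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  cst <- -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))))
  tch <- t(ch)
  lw <- matrix(0, n, K)
  for (k in seq_len(K)) {
    z <- forwardsolve(tch, yt - as.numeric(Lam %*% alpha[k, ]))
    lw[, k] <- cst - 0.5 * colSums(z * z) + log(pi_k[k])
  }
  m <- lw[, 1]
  if (K > 1) for (k in 2:K) m <- pmax(m, lw[, k])
  e <- exp(lw - m)
  rs <- rowSums(e)
  list(logL = sum(m + log(rs)), post = e / rs)
}

#' Quasi-Newton refinement of the marginal mixture likelihood
#' @keywords internal
#' @noRd
polish_lgmm <- function(y, Lam, K, state, control) {
  p <- ncol(y)
  ch <- tryCatch(chol(state$Psi), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  par0 <- c(if (K > 1) log(state$pi[-K] / state$pi[K]),
            as.numeric(t(state$alpha)),
            log(ch[1, 1]), ch[1, 2], log(ch[2, 2]),
            0.5 * log(pmax(state$theta, 1e-10)))
  unpack <- function(par) {
    i <- 0
    pi_k <- if (K > 1) {
      e <- exp(c(par[seq_len(K - 1)], 0))
      i <- K - 1
      e / sum(e)
    } else 1
    alpha <- matrix(par[i + seq_len(2 * K)], K, 2, byrow = TRUE)
    i <- i + 2 * K
    Psi <- chol_to_psi(par[i + 1:3])
    theta <- exp(2 * par[i + 3 + seq_len(p)])
    list(pi = pi_k, alpha = alpha, Psi = Psi, theta = theta)
  }
  yt <- t(y)
  nll <- function(par) {
    u <- unpack(par)
    v <- -lgmm_loglik(y, Lam, u$alpha, u$pi, u$Psi, u$theta, yt = yt)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- tryCatch(stats::nlminb(par0, nll, control = control),
                  error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  u <- unpack(opt$par)
  es <- lgmm_estep(y, Lam, u$alpha, u$pi, u$Psi, u$theta)
  if (is.null(es)) return(NULL)
  nk <- colSums(es$post)
  if (any(nk < 1)) return(NULL)
  list(logL = es$logL, alpha = u$alpha, pi = u$pi, Psi = u$Psi,
       theta = u$theta, post = es$post, trace = numeric(0),
       converged = opt$convergence == 0, floored = FALSE)
}

#' Mixture log-likelihood at given parameters
#' @keywords internal
#' @noRd
lgmm_loglik <- function(y, Lam, alpha, pi_k, Psi, theta, yt = t(y)) {
  es <- lgmm_estep(y, Lam, alpha, pi_k, Psi, theta, yt = yt)
  if (is.null(es)) return(-Inf)
  es$logL
}

#' One EM run; returns NULL on a degenerate (empty-class) trajectory
#' @keywords internal
#' @noRd
em_lgmm_run <- function(y, Lam, K, alpha, pi_k, Psi, theta, max_iter, tol) {
  n <- nrow(y)
  p <- ncol(y)
  yt <- t(y)
  logL_old <- -Inf
  trace <- numeric(0)
  floored <- FALSE
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    es <- lgmm_estep(y, Lam, alpha, pi_k, Psi, theta, yt = yt)
    if (is.null(es)) return(NULL)
    logL <- es$logL
    if (logL < logL_old - 1e-8) {
      stop("internal error: EM log-likelihood decreased", call. = FALSE)
    }
    trace <- c(trace, logL)
    post <- es$post
    nk <- colSums(post)
    if (any(nk < 1)) return(NULL)  # empty class: degenerate start

    if (is.finite(logL_old) && abs(logL - logL_old) < tol) {
      converged <- TRUE
      break
    }
    logL_old <- logL

    # E-step: growth-factor conditional moments (shared across classes)
    Psi_inv <- solve(Psi)
    LtTi <- t(Lam) / rep(theta, each = 2)         # Lam' Theta^-1
    V <- solve(Psi_inv + LtTi %*% Lam)            # 2 x 2
    # M-step
    pi_k <- nk / n
    Psi_new <- matrix(0, 2, 2)
    theta_new <- numeric(p)
    alpha_new <- alpha
    proj <- y %*% t(LtTi)                          # n x 2 : Lam'Th^-1 y
    for (k in seq_len(K)) {
      mk <- (proj + matrix(Psi_inv %*% alpha[k, ], n, 2,
                           byrow = TRUE)) %*% V    # E[eta | y, k]
      alpha_new[k, ] <- colSums(post[, k] * mk) / nk[k]
      d <- sweep(mk, 2, alpha_new[k, ])
      Psi_new <- Psi_new + nk[k] * V + crossprod(d * post[, k], d)
      ey <- y - mk %*% t(Lam)
      theta_new <- theta_new +
        colSums(post[, k] * ey^2) + nk[k] * diag(Lam %*% V %*% t(Lam))
    }
    alpha <- alpha_new
    Psi <- Psi_new / n
    theta <- theta_new / n
    if (any(theta < 1e-8) || any(diag(Psi) < 1e-8)) {
      floored <- TRUE
      theta <- pmax(theta, 1e-8)
      diag(Psi) <- pmax(diag(Psi), 1e-8)
    }
  }
  if (floored) {
    warning("variance floored at 1e-8 during EM (Heywood)", call. = FALSE)
  }
  list(logL = trace[length(trace)], alpha = alpha, pi = pi_k, Psi = Psi,
       theta = theta, post = post, trace = trace, converged = converged,
       floored = floored)
}

#' @export
print.lgmm_fit <- function(x, ...) {
  cat(sprintf("LGMM: K = %d, n = %d, q = %d, logL = %.3f%s\n", x$K, x$n,
              x$q, x$logL, if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- data.frame(class = rownames(x$alpha),
                    mixing = round(x$pi, 4),
                    intercept = round(x$alpha[, 1], 4),
                    slope = round(x$alpha[, 2], 4),
                    modal_share = round(as.numeric(
                      table(factor(x$assignment, levels = seq_len(x$K)))) /
                        x$n, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("entropy = %s; AIC = %.2f, BIC = %.2f, aBIC = %.2f\n",
              format(x$entropy, digits = 4), x$ic["AIC"], x$ic["BIC"],
              x$ic["aBIC"]))
  invisible(x)
}

#' Relative entropy of a posterior classification
#'
#' \eqn{E = 1 - \sum_i\sum_k (-p_{ik}\ln p_{ik}) / (n \ln K)}: 1 for
#' perfectly crisp (one-hot) posteriors, 0 for uniform posteriors. Not
#' defined for K = 1 (returns `NA`).
#'
#' @param posterior n x K matrix with rows summing to 1.
#' @return scalar in `[0, 1]`, or `NA` for K = 1.
#' @export
relative_entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  if (any(posterior < 0) ||
      any(abs(rowSums(posterior) - 1) > 1e-9)) {
    stop("posterior rows must be nonnegative and sum to 1", call. = FALSE)
  }
  K <- ncol(posterior)
  if (K == 1) return(NA_real_)
  plogp <- posterior * log(posterior)
  plogp[posterior == 0] <- 0
  1 - sum(-plogp) / (nrow(posterior) * log(K))
}

#' Average posterior probabilities by modal class
#'
#' Entry (j, k) is the mean posterior probability of class k among users
#' modally assigned to class j; rows sum to 1. Diagonal dominance indicates
#' a clean classification. A modal class with no members yields a row of
#' `NA`.
#'
#' @param posterior n x K posterior matrix.
#' @param assignment integer modal assignments (defaults to row-wise
#'   argmax).
#' @return K x K matrix.
#' @export
avg_posterior_matrix <- function(posterior,
                                 assignment = max.col(posterior,
                                                      ties.method = "first")) {
  posterior <- as.matrix(posterior)
  K <- ncol(posterior)
  if (any(assignment != pmin(pmax(assignment, 1), K))) {
    stop("`assignment` must index posterior columns", call. = FALSE)
  }
  chk <- max.col(posterior, ties.method = "first")
  if (any(posterior[cbind(seq_len(nrow(posterior)), assignment)] <
          posterior[cbind(seq_len(nrow(posterior)), chk)] - 1e-12)) {
    stop("`assignment` inconsistent with posteriors", call. = FALSE)
  }
  out <- matrix(NA_real_, K, K,
                dimnames = list(colnames(posterior), colnames(posterior)))
  for (j in seq_len(K)) {
    sel <- assignment == j
    if (any(sel)) out[j, ] <- colMeans(posterior[sel, , drop = FALSE])
  }
  out
}

#' Simulate trajectories from a fitted mixture (parametric bootstrap draw)
#' @keywords internal
#' @noRd
simulate_from_lgmm <- function(fit, n) {
  K <- fit$K
  cls <- if (K == 1) rep(1L, n) else {
    sample.int(K, n, replace = TRUE, prob = fit$pi)
  }
  Lam <- growth_loadings(fit$times)
  eta <- matrix(NA_real_, n, 2)
  for (k in seq_len(K)) {
    idx <- which(cls == k)
    if (length(idx)) eta[idx, ] <- rmvn(length(idx), fit$alpha[k, ], fit$Psi)
  }
  eta %*% t(Lam) +
    matrix(stats::rnorm(n * length(fit$times)), n) %*%
      diag(sqrt(fit$theta), length(fit$times))
}

#' Bootstrap p-value from an observed LR and bootstrap replicates
#'
#' `p = (1 + #\{LR_b >= LR_obs\}) / (B + 1)`.
#'
#' @param lr_obs observed likelihood-ratio statistic.
#' @param lr_boot numeric vector of bootstrap statistics.
#' @return scalar p-value.
#' @export
blrt_pvalue <- function(lr_obs, lr_boot) {
  if (!length(lr_boot)) stop("need at least one bootstrap LR", call. = FALSE)
  (1 + sum(lr_boot >= lr_obs)) / (length(lr_boot) + 1)
}

#' Bootstrap likelihood ratio test for K vs K-1 classes
#'
#' Computes `LR_obs = 2(logL_K - logL_{K-1})` on the data, then simulates
#' `B` parametric bootstrap datasets from the fitted (K-1)-class model,
#' refits both models on each, and returns the bootstrap p-value
#' `(1 + #\{LR_b >= LR_obs\}) / (B + 1)`. Bootstrap replicates whose refits
#' degenerate are dropped; if more than 20% fail the p-value is flagged.
#'
#' @param y n x T outcome matrix.
#' @param K alternative number of classes (>= 2).
#' @param B number of bootstrap replicates (>= 1).
#' @param times time codes.
#' @param seed optional integer.
#' @param n_starts starts for the observed-data fits.
#' @param n_starts_boot starts for each bootstrap refit (smaller for speed).
#' @param boot_max_iter EM iteration cap per bootstrap refit; the
#'   quasi-Newton polish still runs each refit to its optimum.
#' @param fit_K,fit_Km1 optional precomputed fits on `y` (skips refitting).
#' @param ... further arguments passed to [fit_lgmm()] (e.g.
#'   `polish_control`), applied to the observed and bootstrap fits alike.
#' @return list of class `blrt_result`: `p`, `lr_obs`, `lr_boot`,
#'   `n_failed`, `flagged`.
#' @export
blrt <- function(y, K, B = 99, times = seq_len(ncol(y)) - 1, seed = NULL,
                 n_starts = 20, n_starts_boot = 4, boot_max_iter = 120,
                 fit_K = NULL, fit_Km1 = NULL, ...) {
  if (K < 2) stop("`K` must be >= 2", call. = FALSE)
  if (B < 1) stop("`B` must be >= 1", call. = FALSE)
  with_seed_set(seed)
  if (is.null(fit_Km1)) {
    fit_Km1 <- fit_lgmm(y, K - 1, times = times, n_starts = n_starts, ...)
  }
  if (is.null(fit_K)) {
    fit_K <- fit_lgmm(y, K, times = times, n_starts = n_starts, ...)
  }
  lr_obs <- 2 * (fit_K$logL - fit_Km1$logL)
  lr_boot <- rep(NA_real_, B)
  for (bi in seq_len(B)) {
    yb <- simulate_from_lgmm(fit_Km1, nrow(y))
    f0 <- tryCatch(fit_lgmm(yb, K - 1, times = times,
                            n_starts = n_starts_boot,
                            max_iter = boot_max_iter, ...),
                   error = function(e) NULL)
    f1 <- tryCatch(fit_lgmm(yb, K, times = times,
                            n_starts = n_starts_boot,
                            max_iter = boot_max_iter, ...),
                   error = function(e) NULL)
    if (!is.null(f0) && !is.null(f1)) {
      lr_boot[bi] <- max(2 * (f1$logL - f0$logL), 0)
    }
  }
  ok <- !is.na(lr_boot)
  n_failed <- sum(!ok)
  flagged <- n_failed > 0.2 * B
  if (flagged) {
    warning(sprintf("%d of %d bootstrap refits failed; p-value flagged",
                    n_failed, B), call. = FALSE)
  }
  structure(list(p = blrt_pvalue(lr_obs, lr_boot[ok]), lr_obs = lr_obs,
                 lr_boot = lr_boot[ok], n_failed = n_failed,
                 flagged = flagged, B = B),
            class = "blrt_result")
}

#' @export
print.blrt_result <- function(x, ...) {
  cat(sprintf("BLRT: LR = %.3f, B = %d (%d failed), p = %.4f%s\n",
              x$lr_obs, x$B, x$n_failed, x$p,
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Lo-Mendell-Rubin approximate likelihood ratio test
#'
#' Scales the likelihood-ratio statistic for K vs K-1 classes by the
#' Lo-Mendell-Rubin-style correction `c = 1 + 1/(d ln n)` (d the difference
#' in free parameters) and refers it to a chi-square with d degrees of
#' freedom. This is an analytic approximation to the nonstandard mixture
#' LRT distribution; the bootstrap test ([blrt()]) is the authoritative
#' one.
#'
#' @param fit_K,fit_Km1 `lgmm_fit` objects fitted to the same data with K
#'   and K-1 classes.
#' @param n sample size (defaults to the fits' n).
#' @return list of class `lmr_result`: `statistic`, `df`, `p`.
#' @export
lmr_test <- function(fit_K, fit_Km1, n = fit_K$n) {
  stopifnot(inherits(fit_K, "lgmm_fit"), inherits(fit_Km1, "lgmm_fit"))
  if (fit_K$n != fit_Km1$n ||
      !isTRUE(all.equal(fit_K$times, fit_Km1$times))) {
    stop("fits must come from identical data", call. = FALSE)
  }
  if (fit_K$K != fit_Km1$K + 1) {
    stop("`fit_K` must have exactly one more class than `fit_Km1`",
         call. = FALSE)
  }
  d <- fit_K$q - fit_Km1$q
  lr <- max(2 * (fit_K$logL - fit_Km1$logL), 0)
  cc <- 1 + 1 / (d * log(n))
  stat <- lr / cc
  structure(list(statistic = stat, df = d,
                 p = stats::pchisq(stat, d, lower.tail = FALSE),
                 approximate = TRUE),
            class = "lmr_result")
}

#' @export
print.lmr_result <- function(x, ...) {
  cat(sprintf("LMR (approximate): statistic = %.3f, df = %d, p = %.4f\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Enumerate latent trajectory classes
#'
#' Fits the mixture for each K in `K_range`, collecting log-likelihood,
#' information criteria, relative entropy, LMR and (optionally) BLRT
#' p-values and class proportions, and flags solutions whose smallest class
#' holds less than `small_class` of the sample. The selected K is the
#' largest K whose BLRT (or, without BLRT, LMR) p-value is below `alpha`,
#' that carries no small-class flag, and whose BIC does not exceed the
#' preceding solution's; the full table is always returned for review.
#'
#' @param y n x T outcome matrix.
#' @param K_range contiguous class counts starting at 1.
#' @param times time codes.
#' @param n_starts EM starts per fit.
#' @param B bootstrap replicates for the BLRT; `0` skips the BLRT.
#' @param seed optional integer.
#' @param small_class small-class share threshold (default 0.03).
#' @param alpha test level used by the selection rule.
#' @return list of class `class_enumeration` with `table` (one row per K),
#'   `fits` (the `lgmm_fit` objects) and `selected` (the chosen K).
#' @export
enumerate_classes <- function(y, K_range = 1:4,
                              times = seq_len(ncol(y)) - 1,
                              n_starts = 20, B = 0, seed = NULL,
                              small_class = 0.03, alpha = 0.05) {
  if (K_range[1] != 1 || any(diff(K_range) != 1)) {
    stop("`K_range` must be contiguous and start at 1", call. = FALSE)
  }
  with_seed_set(seed)
  fits <- vector("list", length(K_range))
  rows <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- tryCatch(fit_lgmm(y, K, times = times, n_starts = n_starts),
                    error = function(e) NULL)
    fits[[i]] <- fit
    if (is.null(fit)) {
      rows[[i]] <- data.frame(K = K, q = NA, logL = NA, AIC = NA, BIC = NA,
                              aBIC = NA, entropy = NA, LMR_p = NA,
                              BLRT_p = NA, proportions = NA,
                              smallest_share = NA, small_class_flag = NA,
                              failed = TRUE)
      next
    }
    lmr_p <- blrt_p <- NA_real_
    if (K > 1 && !is.null(fits[[i - 1]])) {
      lmr_p <- lmr_test(fit, fits[[i - 1]])$p
      if (B > 0) {
        blrt_p <- blrt(y, K, B = B, times = times,
                       fit_K = fit, fit_Km1 = fits[[i - 1]])$p
      }
    }
    shares <- as.numeric(table(factor(fit$assignment,
                                      levels = seq_len(K)))) / fit$n
    rows[[i]] <- data.frame(
      K = K, q = fit$q, logL = fit$logL,
      AIC = unname(fit$ic["AIC"]), BIC = unname(fit$ic["BIC"]),
      aBIC = unname(fit$ic["aBIC"]), entropy = fit$entropy,
      LMR_p = lmr_p, BLRT_p = blrt_p,
      proportions = paste(sprintf("%.3f", fit$pi), collapse = "/"),
      smallest_share = min(shares),
      small_class_flag = is_small_class(shares, small_class),
      failed = FALSE)
  }
  tab <- do.call(rbind, rows)
  selected <- 1L
  for (i in seq_along(K_range)[-1]) {
    row <- tab[i, ]
    if (isTRUE(row$failed)) break
    test_p <- if (!is.na(row$BLRT_p)) row$BLRT_p else row$LMR_p
    supported <- !is.na(test_p) && test_p < alpha &&
      !isTRUE(row$small_class_flag) &&
      (is.na(tab$BIC[i - 1]) || row$BIC <= tab$BIC[i - 1])
    if (supported) selected <- K_range[i] else break
  }
  structure(list(table = tab, fits = fits, selected = selected),
            class = "class_enumeration")
}

#' Small-class flag used during class enumeration
#'
#' @param shares class shares (proportions).
#' @param threshold flag when any share is strictly below this (default
#'   0.03).
#' @return logical.
#' @export
is_small_class <- function(shares, threshold = 0.03) {
  any(shares < threshold)
}

#' @export
print.class_enumeration <- function(x, ...) {
  cat("Class enumeration (selected K =", x$selected, ")\n")
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}
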