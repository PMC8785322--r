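#' Information criteria from a log-likelihood
#'
#' AIC = -2logL + 2q; BIC = -2logL + q ln(n); the sample-size-adjusted BIC
#' replaces n by (n+2)/24 in the penalty.
#'
#' @param logL maximized log-likelihood.
#' @param q number of free parameters.
#' @param n sample size.
#' @return named numeric vector `AIC`, `BIC`, `aBIC`.
#' @examples
#' information_criteria(-20010.134, 9, 1322)
#' @export
information_criteria <- function(logL, q, n) {
  c(AIC = -2 * logL + 2 * q,
    BIC = -2 * logL + q * log(n),
    aBIC = -2 * logL + q * log((n + 2) / 24))
}

#' @keywords internal
#' @noRd
chol_to_psi <- function(p) {
  L <- matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2, 2)
  L %*% t(L)
}

#' Marginal log-likelihood of the linear growth model
#' @keywords internal
#' @noRd
lgcm_loglik <- function(y, Lam, alpha_mat, Psi, theta) {
  Sigma <- Lam %*% Psi %*% t(Lam) + diag(theta, nrow(Lam))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  mu <- alpha_mat %*% t(Lam)                       # n x T
  z <- forwardsolve(t(ch), t(y - mu))
  p <- ncol(y)
  -0.5 * (nrow(y) * (p * log(2 * pi) + 2 * sum(log(diag(ch)))) +
            sum(z^2))
}

#' Fit a linear latent growth curve model by maximum likelihood
#'
#' Models repeated measures \eqn{y_{it}} with latent intercept and slope
#' factors: \eqn{y_i = \Lambda\eta_i + \epsilon_i},
#' \eqn{\eta_i \sim N(\alpha, \Psi)},
#' \eqn{\epsilon_i \sim N(0, \Theta)} with diagonal \eqn{\Theta}. The
#' loadings are fixed: a unit column for the intercept and the time codes
#' for the slope. Estimation maximizes the normal log-likelihood with a
#' quasi-Newton optimizer on a Cholesky/log parameterization that keeps
#' \eqn{\Psi} and \eqn{\Theta} positive (semi-)definite; variances pushed to
#' the boundary (Heywood cases) are clamped near zero with a warning.
#' With a time-invariant covariate `x`, the growth factors are regressed on
#' it: \eqn{\eta_i = \gamma_0 + \gamma_1 x_i + \zeta_i}, and \eqn{\Psi}
#' becomes the residual factor covariance.
#'
#' @param y n x T outcome matrix, complete cases.
#' @param times numeric time codes, one per column of `y` (default
#'   `0..T-1`).
#' @param covariate optional numeric vector of length n (e.g. gender coded
#'   0/1); must have positive variance.
#' @param residuals `"free"` (one residual variance per wave, default) or
#'   `"equal"` (a single shared residual variance).
#' @param se compute standard errors from the information matrix
#'   (numerical Hessian of the negative log-likelihood at the optimum).
#' @param control list passed to [stats::nlminb()].
#' @return object of class `lgcm_fit` with elements `alpha` (growth-factor
#'   means; in the conditional model the intercepts `gamma0` and covariate
#'   slopes `gamma1`), `Psi`, `psi` (named `psi_II`, `psi_IS`, `psi_SS`),
#'   `theta` (residual variances), `r` (intercept-slope correlation), `logL`,
#'   `logL_sat`, `F_ML`, `chisq`, `df`, `q`, `n`, `se`, `p_values`,
#'   `converged`.
#' @references The fit-statistic conventions follow standard SEM practice:
#'   the minimum of the ML discrepancy scaled by (n-1) is the model
#'   chi-square.
#' @export
fit_lgcm <- function(y, times = seq_len(ncol(y)) - 1, covariate = NULL,
                     residuals = c("free", "equal"), se = TRUE,
                     control = list(iter.max = 1000, eval.max = 2000,
                                    rel.tol = 1e-10)) {
  residuals <- match.arg(residuals)
  y <- as.matrix(y)
  n <- nrow(y)
  p <- ncol(y)
  if (length(times) != p) stop("`times` must match ncol(y)", call. = FALSE)
  if (anyNA(y)) stop("`y` must be complete (no missing cells)",
                     call. = FALSE)
  conditional <- !is.null(covariate)
  if (conditional) {
    covariate <- as.numeric(covariate)
    if (length(covariate) != n) {
      stop("`covariate` must have one value per row of `y`", call. = FALSE)
    }
    if (stats::var(covariate) == 0) {
      stop("`covariate` is constant (no variance)", call. = FALSE)
    }
  }
  n_theta <- if (residuals == "free") p else 1L
  n_mean <- if (conditional) 4L else 2L
  q <- n_mean + 3L + n_theta
  moments <- p + p * (p + 1) / 2 + if (conditional) p else 0
  df <- moments - q
  if (df < 0) {
    stop(sprintf(paste("model not identified: %d free parameters exceed %d",
                       "observed moments (negative degrees of freedom)"),
                 q, moments), call. = FALSE)
  }
  if (n <= q) stop("need more users than free parameters", call. = FALSE)

  Lam <- growth_loadings(times)
  X <- if (conditional) cbind(1, covariate) else matrix(1, n, 1)

  # start values from per-user OLS growth estimates
  XtXi <- solve(crossprod(Lam))
  b <- y %*% Lam %*% XtXi                      # n x 2 OLS intercept/slope
  B0 <- solve(crossprod(X), crossprod(X, b))   # regression of factors on X
  resid_b <- b - X %*% B0
  Psi0 <- crossprod(resid_b) / n
  Psi0 <- Psi0 + diag(1e-4 + 0.01 * diag(Psi0))
  e <- y - b %*% t(Lam)
  theta0 <- pmax(colSums(e^2) / n, 1e-3)
  if (residuals == "equal") theta0 <- mean(theta0)
  ch0 <- chol(Psi0)
  par0 <- c(as.numeric(B0), log(ch0[1, 1]), ch0[1, 2], log(ch0[2, 2]),
            0.5 * log(theta0))

  unpack <- function(par) {
    beta <- matrix(par[seq_len(n_mean)], ncol = 2)
    psi_par <- par[n_mean + 1:3]
    th <- exp(2 * par[n_mean + 3 + seq_len(n_theta)])
    if (residuals == "equal") th <- rep(th, p)
    list(beta = beta, Psi = chol_to_psi(psi_par), theta = th)
  }
  nll <- function(par) {
    u <- unpack(par)
    -lgcm_loglik(y, Lam, X %*% u$beta, u$Psi, u$theta)
  }
  lb <- rep(-Inf, length(par0))
  lb[c(n_mean + 1, n_mean + 3, n_mean + 3 + seq_len(n_theta))] <- -12
  opt <- stats::nlminb(par0, nll, lower = lb, control = control)
  u <- unpack(opt$par)
  logL <- -opt$objective
  converged <- opt$convergence == 0

  at_boundary <- any(opt$par[c(n_mean + 1, n_mean + 3,
                               n_mean + 3 + seq_len(n_theta))] <= -11.5)
  if (at_boundary) {
    warning("variance estimate at the zero boundary (Heywood case); ",
            "clamped near 0", call. = FALSE)
  }

  # saturated model: unconstrained means (regression on X) and covariance
  Bsat <- solve(crossprod(X), crossprod(X, y))
  esat <- y - X %*% Bsat
  S_ml <- crossprod(esat) / n
  logL_sat <- -0.5 * n * (p * log(2 * pi) +
                            determinant(S_ml)$modulus[1] + p)
  F_ML <- max(2 * (logL_sat - logL) / n, 0)
  chisq <- (n - 1) * F_ML

  psi <- c(psi_II = u$Psi[1, 1], psi_IS = u$Psi[1, 2], psi_SS = u$Psi[2, 2])
  r <- if (psi[1] > 0 && psi[3] > 0) {
    unname(psi[2] / sqrt(psi[1] * psi[3]))
  } else NA_real_

  se_vec <- p_vec <- NULL
  r_se <- NA_real_
  if (se) {
    # natural parameter vector is column-major in the beta matrix:
    # (gamma0_I, gamma1_I, gamma0_S, gamma1_S)
    nat_names <- c(
      if (conditional) c("gamma0_I", "gamma1_I", "gamma0_S", "gamma1_S")
      else c("alpha_I", "alpha_S"),
      "psi_II", "psi_IS", "psi_SS",
      paste0("theta_", seq_len(n_theta)))
    nat0 <- c(as.numeric(u$beta), psi,
              if (residuals == "equal") u$theta[1] else u$theta)
    nll_nat <- function(parn) {
      beta <- matrix(parn[seq_len(n_mean)], ncol = 2)
      Psi <- matrix(parn[n_mean + c(1, 2, 2, 3)], 2, 2)
      th <- parn[n_mean + 3 + seq_len(n_theta)]
      if (residuals == "equal") th <- rep(th, p)
      if (any(th <= 0)) return(Inf)
      -lgcm_loglik(y, Lam, X %*% beta, Psi, th)
    }
    H <- num_hessian(nll_nat, nat0)
    se_vec <- se_from_information(H)
    names(se_vec) <- nat_names
    z <- (nat0 / se_vec)
    p_vec <- 2 * stats::pnorm(-abs(z))
    names(p_vec) <- nat_names
    # delta method for the intercept-slope correlation
    if (!is.na(r) && all(!is.na(se_vec[c("psi_II", "psi_IS", "psi_SS")]))) {
      g <- rep(0, length(nat0))
      i0 <- n_mean
      g[i0 + 1] <- -r / (2 * psi[1])
      g[i0 + 2] <- 1 / sqrt(psi[1] * psi[3])
      g[i0 + 3] <- -r / (2 * psi[3])
      Vfull <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vfull)) {
        vr <- drop(t(g) %*% Vfull %*% g)
        if (is.finite(vr) && vr > 0) r_se <- sqrt(vr)
      }
    }
  }

  beta <- u$beta
  alpha <- if (conditional) {
    c(gamma0_I = beta[1, 1], gamma0_S = beta[1, 2],
      gamma1_I = beta[2, 1], gamma1_S = beta[2, 2])
  } else {
    c(alpha_I = beta[1, 1], alpha_S = beta[1, 2])
  }
  structure(list(alpha = alpha, Psi = u$Psi, psi = psi, theta = u$theta,
                 r = r, r_se = r_se,
                 r_p = if (!is.na(r_se)) 2 * stats::pnorm(-abs(r / r_se))
                       else NA_real_,
                 logL = logL, logL_sat = logL_sat, F_ML = F_ML,
                 chisq = chisq, df = df, q = q, n = n, p = p,
                 times = times, residuals = residuals,
                 conditional = conditional,
                 se = se_vec, p_values = p_vec,
                 converged = converged, heywood = at_boundary,
                 y_mean = colMeans(y),
                 S = stats::cov(y)),
            class = "lgcm_fit")
}

#' @rdname fit_lgcm
#' @export
fit_conditional_lgcm <- function(y, covariate, times = seq_len(ncol(y)) - 1,
                                 residuals = c("free", "equal"), ...) {
  if (is.null(covariate)) stop("`covariate` is required", call. = FALSE)
  fit_lgcm(y, times = times, covariate = covariate,
           residuals = match.arg(residuals), ...)
}

#' @export
print.lgcm_fit <- function(x, ...) {
  cat(sprintf("Linear LGCM (%s): n = %d, %d waves, q = %d, logL = %.3f\n",
              if (x$conditional) "conditional" else "unconditional",
              x$n, x$p, x$q, x$logL))
  est <- format(x$alpha, digits = 5)
  cat("  growth-factor means:",
      paste(sprintf("%s = %s", names(x$alpha), est), collapse = ", "), "\n")
  cat(sprintf("  psi_II = %.4g, psi_IS = %.4g, psi_SS = %.4g (r = %.3f)\n",
              x$psi[1], x$psi[2], x$psi[3], x$r))
  cat(sprintf("  residual variances: %s\n",
              paste(format(x$theta, digits = 4), collapse = ", ")))
  cat(sprintf("  chisq(%d) = %.3f%s\n", x$df, x$chisq,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @keywords internal
#' @noRd
cfi_tli <- function(chisq_m, df_m, chisq_b, df_b) {
  num <- max(chisq_m - df_m, 0)
  den <- max(chisq_b - df_b, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  rb <- chisq_b / df_b
  rm <- if (df_m > 0) chisq_m / df_m else NA_real_
  # truncated at 1: a model fitting better than its df (chisq < df) is
  # reported as a perfect 1, the usual reporting convention
  tli <- if (!is.na(rm) && rb > 1) min((rb - rm) / (rb - 1), 1) else NA_real_
  c(CFI = cfi, TLI = tli)
}

#' SEM fit indices for a fitted growth model
#'
#' Computes chi-square-based fit indices against the independence baseline
#' (free means and variances, zero covariances):
#' `CFI = 1 - max(chisq_M - df_M, 0) / max(chisq_B - df_B, 0)`,
#' `TLI = ((chisq_B/df_B) - (chisq_M/df_M)) / ((chisq_B/df_B) - 1)`,
#' `RMSEA = sqrt(max(chisq - df, 0) / (df (n-1)))`, SRMR as the root mean
#' square of standardized residual moments (covariances and means), and the
#' information criteria of [information_criteria()]. With `df = 0`, RMSEA
#' and chi-square/df are reported as `NA`.
#'
#' @param fit an `lgcm_fit` from [fit_lgcm()].
#' @return list of class `fit_indices`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "lgcm_fit"))
  if (!fit$converged) {
    warning("fit indices computed from a non-converged fit", call. = FALSE)
  }
  n <- fit$n
  p <- fit$p
  S_ml <- fit$S * (n - 1) / n
  # independence baseline on the outcome moments
  F_B <- sum(log(diag(S_ml))) - determinant(S_ml)$modulus[1]
  chisq_B <- (n - 1) * F_B
  df_B <- p * (p - 1) / 2
  ct <- cfi_tli(fit$chisq, fit$df, chisq_B, df_B)
  rmsea <- if (fit$df > 0) {
    sqrt(max(fit$chisq - fit$df, 0) / (fit$df * (n - 1)))
  } else NA_real_
  # standardized residuals over unique moments (means + covariances)
  Lam <- growth_loadings(fit$times)
  Sigma <- Lam %*% fit$Psi %*% t(Lam) + diag(fit$theta, p)
  mu <- if (fit$conditional) fit$y_mean else {
    as.numeric(Lam %*% fit$alpha)
  }
  sds <- sqrt(diag(S_ml))
  res_cov <- (S_ml - Sigma) / tcrossprod(sds)
  res_mean <- (fit$y_mean - mu) / sds
  srmr <- sqrt((sum(res_cov[lower.tri(res_cov, diag = TRUE)]^2) +
                  sum(res_mean^2)) / (p * (p + 1) / 2 + p))
  ic <- information_criteria(fit$logL, fit$q, n)
  structure(list(
    chisq = fit$chisq, df = fit$df,
    chisq_df = if (fit$df > 0) fit$chisq / fit$df else NA_real_,
    p_value = if (fit$df > 0) {
      stats::pchisq(fit$chisq, fit$df, lower.tail = FALSE)
    } else NA_real_,
    CFI = unname(ct["CFI"]), TLI = unname(ct["TLI"]),
    RMSEA = rmsea, SRMR = srmr,
    AIC = unname(ic["AIC"]), BIC = unname(ic["BIC"]),
    aBIC = unname(ic["aBIC"]),
    baseline_chisq = chisq_B, baseline_df = df_B
  ), class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chisq(%d) = %.3f (chisq/df = %s, p = %s)\n", x$df, x$chisq,
              format(x$chisq_df, digits = 4),
              format(x$p_value, digits = 3)))
  cat(sprintf("CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$CFI, x$TLI, x$RMSEA, x$SRMR))
  cat(sprintf("AIC = %.2f, BIC = %.2f, aBIC = %.2f\n",
              x$AIC, x$BIC, x$aBIC))
  invisible(x)
}
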