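# Internal numerical helpers shared across the growth-model code.

#' Draw from a multivariate normal via the Cholesky factor
#'
#' @param n number of draws
#' @param mu mean vector
#' @param Sigma covariance matrix (symmetric, positive semi-definite)
#' @return an `n x length(mu)` matrix
#' @keywords internal
#' @noRd
rmvn <- function(n, mu, Sigma) {
  p <- length(mu)
  ev <- eigen(Sigma, symmetric = TRUE)
  # tolerate semi-definite Sigma (zero-variance degenerate configurations)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% A, 2, mu, "+")
}

#' Log-density of N(mu, Sigma) evaluated at the rows of y
#'
#' @param y `n x p` matrix
#' @return numeric vector of length `n`
#' @keywords internal
#' @noRd
dmvn_log <- function(y, mu, Sigma) {
  p <- ncol(y)
  ch <- chol(Sigma)
  z <- forwardsolve(t(ch), t(y) - mu)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
}

#' Numerically symmetric central-difference Hessian
#' @keywords internal
#' @noRd
num_hessian <- function(fn, x, eps = 1e-4) {
  q <- length(x)
  h <- pmax(abs(x), 1) * eps
  H <- matrix(NA_real_, q, q)
  f0 <- fn(x)
  for (i in seq_len(q)) {
    for (j in i:q) {
      xpp <- x; xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
      xpm <- x; xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
      xmp <- x; xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
      xmm <- x; xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
      H[i, j] <- H[j, i] <-
        (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Standard errors from an information matrix, tolerant of near-singularity
#' @keywords internal
#' @noRd
se_from_information <- function(H) {
  se <- rep(NA_real_, nrow(H))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V)) {
    d <- diag(V)
    se[d > 0] <- sqrt(d[d > 0])
  }
  se
}

#' Numeric gradient (central differences)
#' @keywords internal
#' @noRd
num_gradient <- function(fn, x, eps = 1e-6) {
  h <- pmax(abs(x), 1) * eps
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h[i]
    xm <- x; xm[i] <- xm[i] - h[i]
    (fn(xp) - fn(xm)) / (2 * h[i])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the RNG state for a reproducible block
#' @keywords internal
#' @noRd
with_seed_set <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
        seed != round(seed)) {
      stop("`seed` must be a single integer", call. = FALSE)
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
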