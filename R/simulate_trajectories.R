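#' Simulate user trajectories from a growth specification
#'
#' Draws `n` users: a class label from the mixing proportions, latent growth
#' factors \eqn{(\eta_0, \eta_1)} from the class's bivariate normal, and
#' observed scores \eqn{y_{it} = \eta_{0i} + \eta_{1i} t_t + \epsilon_{it}}
#' with wave-specific normal residuals.
#'
#' @param spec a [growth_spec()].
#' @param n number of users (>= 1).
#' @param seed optional integer; fixing it makes the output reproducible.
#' @return list of class `sim_trajectories` with elements
#'   \item{y}{`n x T` outcome matrix (columns `w1..wT`)}
#'   \item{class}{character vector of true class labels}
#'   \item{eta}{`n x 2` matrix of true intercepts and slopes}
#'   \item{spec}{the generating spec}
#' @examples
#' spec <- growth_spec(intercept_mean = 1, slope_mean = 1,
#'                     intercept_sd = 0, slope_sd = 0,
#'                     residual_sd = c(0, 0, 0))
#' simulate_trajectories(spec, n = 2, seed = 1)$y  # rows are exactly 1 2 3
#' @export
simulate_trajectories <- function(spec, n, seed = NULL) {
  validate_growth_spec(spec)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  with_seed_set(seed)
  n <- as.integer(n)
  K <- length(spec$class_labels)
  Tn <- length(spec$time_codes)
  cls_idx <- if (K == 1) rep(1L, n) else {
    sample.int(K, n, replace = TRUE, prob = spec$mixing)
  }
  Psi <- spec_psi(spec)
  L <- growth_loadings(spec$time_codes)
  eta <- matrix(NA_real_, n, 2,
                dimnames = list(NULL, c("intercept", "slope")))
  for (k in seq_len(K)) {
    idx <- which(cls_idx == k)
    if (length(idx)) {
      eta[idx, ] <- rmvn(length(idx),
                         c(spec$intercept_mean[k], spec$slope_mean[k]), Psi)
    }
  }
  eps <- matrix(stats::rnorm(n * Tn), n, Tn) %*%
    diag(spec$residual_sd, Tn)
  y <- eta %*% t(L) + eps
  colnames(y) <- paste0("w", seq_len(Tn))
  structure(list(y = y, class = spec$class_labels[cls_idx], eta = eta,
                 spec = spec),
            class = "sim_trajectories")
}

#' @export
print.sim_trajectories <- function(x, ...) {
  cat(sprintf("Simulated trajectories: %d users x %d waves, %d class(es)\n",
              nrow(x$y), ncol(x$y), length(x$spec$class_labels)))
  print(table(class = x$class))
  invisible(x)
}
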