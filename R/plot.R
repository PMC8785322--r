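#' Plot mean trajectories of the latent classes
#'
#' Draws the model-implied mean trajectory of each latent class
#' (\eqn{\alpha_{0k} + \alpha_{1k} t}) over the observed waves, with the
#' observed per-class mean profiles (by modal assignment) overlaid as
#' points.
#'
#' @param fit an `lgmm_fit` from [fit_lgmm()].
#' @param y optional outcome matrix used for the observed class means.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the K x T matrix of implied class means.
#' @export
plot_class_trajectories <- function(fit, y = NULL, ...) {
  stopifnot(inherits(fit, "lgmm_fit"))
  Lam <- growth_loadings(fit$times)
  mu <- fit$alpha %*% t(Lam)
  graphics::matplot(fit$times, t(mu), type = "l", lty = 1, lwd = 2,
                    col = seq_len(fit$K), xlab = "wave (time code)",
                    ylab = "SWB score",
                    main = "Latent class mean trajectories", ...)
  if (!is.null(y)) {
    for (k in seq_len(fit$K)) {
      sel <- fit$assignment == k
      if (any(sel)) {
        graphics::points(fit$times, colMeans(y[sel, , drop = FALSE]),
                         col = k, pch = 19)
      }
    }
  }
  graphics::legend("topleft",
                   legend = sprintf("%s (pi = %.3f)", rownames(fit$alpha),
                                    fit$pi),
                   col = seq_len(fit$K), lty = 1, lwd = 2, bty = "n")
  invisible(mu)
}
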