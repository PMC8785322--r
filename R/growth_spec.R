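#' Specification of a (mixture of) linear latent growth model(s)
#'
#' A `growth_spec` describes the population from which user trajectories are
#' drawn: one or more latent classes, each with its own mean intercept and
#' mean slope, a growth-factor covariance matrix shared across classes, and
#' wave-specific residual standard deviations. The data-generating model for
#' user \eqn{i} observed at wave \eqn{t} is
#' \deqn{y_{it} = \eta_{0i} + \eta_{1i} t_t + \epsilon_{it},}
#' where \eqn{(\eta_{0i}, \eta_{1i})} is bivariate normal with the mean of the
#' user's class and shared covariance \eqn{\Psi}, and
#' \eqn{\epsilon_{it} \sim N(0, \theta_t)}.
#'
#' @param class_labels character vector of class identifiers.
#' @param mixing numeric vector of class proportions; nonnegative, summing
#'   to 1 (within 1e-12).
#' @param intercept_mean,slope_mean numeric vectors, one value per class, in
#'   score units (slope per unit of `time_codes`).
#' @param intercept_sd,slope_sd nonnegative scalars, shared across classes.
#' @param intercept_slope_corr scalar in `[-1, 1]`, shared across classes.
#' @param residual_sd nonnegative vector of wave residual standard
#'   deviations, one per wave.
#' @param time_codes numeric vector of loadings for the slope factor
#'   (default `0:2`, coding three waves).
#'
#' @return An object of class `growth_spec`.
#' @seealso [simulate_trajectories()]
#' @examples
#' spec <- growth_spec(
#'   class_labels = c("high_growth", "normal_growth"),
#'   mixing = c(0.063, 0.937),
#'   intercept_mean = c(14.49, 2.60), slope_mean = c(2.88, 0.57),
#'   intercept_sd = 1.5, slope_sd = 0.3, intercept_slope_corr = 0.3,
#'   residual_sd = c(1, 1, 1)
#' )
#' @export
growth_spec <- function(class_labels = "class1",
                        mixing = 1,
                        intercept_mean = 0,
                        slope_mean = 0,
                        intercept_sd = 1,
                        slope_sd = 1,
                        intercept_slope_corr = 0,
                        residual_sd = c(1, 1, 1),
                        time_codes = seq_along(residual_sd) - 1) {
  spec <- structure(
    list(class_labels = as.character(class_labels),
         mixing = as.numeric(mixing),
         intercept_mean = as.numeric(intercept_mean),
         slope_mean = as.numeric(slope_mean),
         intercept_sd = as.numeric(intercept_sd),
         slope_sd = as.numeric(slope_sd),
         intercept_slope_corr = as.numeric(intercept_slope_corr),
         residual_sd = as.numeric(residual_sd),
         time_codes = as.numeric(time_codes)),
    class = "growth_spec"
  )
  validate_growth_spec(spec)
  spec
}

#' @keywords internal
#' @noRd
validate_growth_spec <- function(spec) {
  k <- length(spec$class_labels)
  if (length(spec$mixing) != k) {
    stop("`mixing` must have one proportion per class", call. = FALSE)
  }
  if (any(spec$mixing < 0)) {
    stop("`mixing` proportions must be nonnegative", call. = FALSE)
  }
  if (abs(sum(spec$mixing) - 1) > 1e-12) {
    stop("`mixing` proportions must sum to 1", call. = FALSE)
  }
  if (length(spec$intercept_mean) != k) {
    stop("`intercept_mean` must have one value per class", call. = FALSE)
  }
  if (length(spec$slope_mean) != k) {
    stop("`slope_mean` must have one value per class", call. = FALSE)
  }
  for (fld in c("intercept_sd", "slope_sd")) {
    v <- spec[[fld]]
    if (length(v) != 1 || is.na(v) || v < 0) {
      stop(sprintf("`%s` must be a single nonnegative number", fld),
           call. = FALSE)
    }
  }
  if (abs(spec$intercept_slope_corr) > 1) {
    stop("`intercept_slope_corr` must lie in [-1, 1]", call. = FALSE)
  }
  if (any(spec$residual_sd < 0)) {
    stop("`residual_sd` must be nonnegative", call. = FALSE)
  }
  if (length(spec$residual_sd) != length(spec$time_codes)) {
    stop("`residual_sd` must have one value per entry of `time_codes`",
         call. = FALSE)
  }
  invisible(spec)
}

#' Growth-factor covariance matrix implied by a growth_spec
#' @keywords internal
#' @noRd
spec_psi <- function(spec) {
  cov_is <- spec$intercept_slope_corr * spec$intercept_sd * spec$slope_sd
  matrix(c(spec$intercept_sd^2, cov_is, cov_is, spec$slope_sd^2), 2, 2)
}

#' Factor-loading matrix for linear growth at given time codes
#' @keywords internal
#' @noRd
growth_loadings <- function(time_codes) {
  cbind(intercept = 1, slope = as.numeric(time_codes))
}

#' Model-implied mean vector and covariance matrix of a growth_spec
#'
#' Returns the per-class mean vectors \eqn{\Lambda\alpha_k} and the shared
#' covariance \eqn{\Lambda\Psi\Lambda' + \Theta} implied by the spec, i.e.
#' the moments the sample moments of simulated trajectories converge to.
#'
#' @param spec a [growth_spec()].
#' @return list with `mean` (K x T matrix, one row per class), `cov`
#'   (T x T), and `marginal_mean` (mixture-weighted mean vector).
#' @export
implied_moments <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  L <- growth_loadings(spec$time_codes)
  alpha <- cbind(spec$intercept_mean, spec$slope_mean)
  mu <- alpha %*% t(L)
  rownames(mu) <- spec$class_labels
  Sigma <- L %*% spec_psi(spec) %*% t(L) + diag(spec$residual_sd^2,
                                                length(spec$time_codes))
  list(mean = mu, cov = Sigma,
       marginal_mean = as.numeric(crossprod(spec$mixing, mu)))
}

#' @export
print.growth_spec <- function(x, ...) {
  cat("Linear growth specification\n")
  cat(sprintf("  classes: %s\n", paste(x$class_labels, collapse = ", ")))
  cat(sprintf("  mixing:  %s\n",
              paste(format(x$mixing, digits = 3), collapse = ", ")))
  cat(sprintf("  intercept means: %s\n",
              paste(format(x$intercept_mean, digits = 4), collapse = ", ")))
  cat(sprintf("  slope means:     %s\n",
              paste(format(x$slope_mean, digits = 4), collapse = ", ")))
  cat(sprintf("  intercept sd %.3g, slope sd %.3g, corr %.3g\n",
              x$intercept_sd, x$slope_sd, x$intercept_slope_corr))
  cat(sprintf("  time codes: %s; residual sd: %s\n",
              paste(x$time_codes, collapse = ", "),
              paste(format(x$residual_sd, digits = 3), collapse = ", ")))
  invisible(x)
}
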