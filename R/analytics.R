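#' Theta (breather) frequency at the onset of instability
#'
#' For a localized pattern governed by recurrent excitation with
#' firing-rate adaptation, linear stability of the two-variable
#' rate/adaptation system predicts an amplitude (breather) oscillation at
#' the Hopf onset with frequency
#' `f_c = sqrt((k - tau / tau_A) / (tau * tau_A)) / (2 pi)`,
#' where `k` is the adaptation strength, `tau` the rate decay constant,
#' and `tau_A` the adaptation decay constant. With `tau`, `tau_A` in ms
#' the result is in kHz; multiply by 1000 for Hz. The oscillation exists
#' only for `k >= tau / tau_A`; below onset the function signals this by
#' returning `NA` with a warning.
#'
#' @param k Adaptation strength (dimensionless).
#' @param tau Firing-rate decay constant, ms.
#' @param tau_A Adaptation decay constant, ms.
#' @return Frequency in cycles per ms (kHz); 0 exactly at onset.
#' @export
breather_frequency <- function(k, tau, tau_A) {
  stopifnot(tau > 0, tau_A > 0)
  below <- k < tau / tau_A
  if (any(below)) {
    warning("k below tau/tau_A: below the instability onset, no oscillation")
  }
  out <- rep(NA_real_, length(k))
  ok <- !below
  out[ok] <- sqrt((k[ok] - tau / tau_A) / (tau * tau_A)) / (2 * pi)
  out
}

# Hill estimator of the tail index from the largest `frac` of |x|, capped at
# the stable-law maximum of 2 (light-tailed steps estimate above 2 and are
# reported as the Gaussian boundary case)
hill_tail_index <- function(x, frac = 0.01) {
  ax <- sort(abs(x[x != 0]), decreasing = TRUE)
  k <- max(2L, floor(frac * length(ax)))
  min(1 / mean(log(ax[seq_len(k)] / ax[k + 1])), 2)
}

#' Superdiffusion diagnostics of a trajectory
#'
#' Unwraps the periodic trajectory with the minimal-image convention, then
#' fits the mean-squared-displacement exponent (`MSD ~ lag^exponent`,
#' log-log least squares) and the Hill tail index of the step sizes.
#' Ballistic motion gives exponent 2, Brownian 1; a tail index below 2
#' indicates heavy-tailed (Levy) steps.
#'
#' @param traj A `walker_trajectory` or data frame with `x`, `y` columns
#'   (or a [center_of_mass()] trajectory; gaps are dropped).
#' @param L Domain period for unwrapping.
#' @param lags Lag range (samples) for the MSD fit.
#' @param tail_frac Fraction of largest steps used by the Hill estimator.
#' @return A `diffusion_summary`: `msd_exponent`, `tail_index`.
#' @export
diffusion_summary <- function(traj, L = 64, lags = NULL, tail_frac = 0.01) {
  xy <- cbind(traj$x, traj$y)
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  n <- nrow(xy)
  if (n < 1e4) stop("need at least 10^4 trajectory samples")
  steps <- apply(xy, 2, function(v) (diff(v) + L / 2) %% L - L / 2)
  unwrapped <- apply(steps, 2, cumsum)
  if (is.null(lags)) lags <- unique(round(10^seq(0, log10(n / 20),
                                                 length.out = 15)))
  msd <- vapply(lags, function(lg) {
    d <- unwrapped[seq(1 + lg, n - 1), , drop = FALSE] -
      unwrapped[seq_len(n - 1 - lg), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  fit <- stats::lm(log10(msd) ~ log10(lags))
  structure(list(msd_exponent = unname(stats::coef(fit)[2]),
                 tail_index = hill_tail_index(rowSums(steps^2)^0.5,
                                              tail_frac),
                 lags = lags, msd = msd),
            class = "diffusion_summary")
}

#' @export
print.diffusion_summary <- function(x, ...) {
  cat(sprintf("diffusion_summary: MSD exponent %.2f, step tail index %.2f\n",
              x$msd_exponent, x$tail_index))
  invisible(x)
}
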