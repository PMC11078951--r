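#' On/Off state segmentation of MUA
#'
#' Classifies every millisecond of a 10 ms-binned MUA trace as On (vigorous
#' local firing) or Off (faint firing) in four steps: (1) Savitzky-Golay
#' smoothing of the MUA gives `eta1`; (2) mean-shift changepoints of `eta1`
#' are detected with PELT under an L2 cost, the penalty set by a slope
#' heuristic on the cost-versus-number-of-changepoints curve; (3) each
#' segment is replaced by its mean, giving the piecewise-constant `eta2`;
#' (4) a threshold `theta` is scanned over a grid between the 5th and 95th
#' percentile of `eta2`; for each candidate the binarized signal's merged
#' runs are re-averaged over `eta1` (giving `eta3`) and the threshold
#' minimizing `sum((eta3 - eta1)^2)` is kept. A sample is On when
#' `eta2 >= theta`. The threshold is determined separately per realization.
#'
#' @param signal MUA as a [continuous_signal()] at 1 kHz (10 ms bins) or a
#'   numeric vector. Concatenation of trials (with early transients already
#'   excluded) is permitted.
#' @param sg_window Savitzky-Golay window, samples (odd; ~90 ms at 1 kHz).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param n_thresholds Size of the threshold scan grid.
#' @param min_seg Minimum changepoint segment length, samples.
#' @param penalty Optional fixed PELT penalty; by default chosen by the
#'   slope heuristic.
#' @return A `state_labels` object: logical `on` per sample, the threshold
#'   `theta`, the changepoints, and the intermediate signals.
#' @export
detect_on_off <- function(signal, sg_window = 91, sg_order = 3,
                          n_thresholds = 100, min_seg = 10, penalty = NULL) {
  x <- sig_values(signal)
  n <- length(x)
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    warning("constant signal: a single state spans the whole recording")
    return(structure(list(on = rep(TRUE, n), theta = x[1], changepoints = integer(0),
                          eta1 = x, eta2 = x, degenerate = TRUE),
                     class = "state_labels"))
  }
  eta1 <- signal::sgolayfilt(x, p = sg_order, n = sg_window)

  if (is.null(penalty)) penalty <- pelt_slope_penalty(eta1, min_seg)
  cps <- .pelt_meanshift(eta1, penalty, min_seg)$changepoints

  bounds <- c(0L, cps, n)
  seg_id <- rep(seq_len(length(bounds) - 1L), diff(bounds))
  seg_mean <- tapply(eta1, seg_id, mean)
  eta2 <- as.numeric(seg_mean[seg_id])

  qs <- stats::quantile(eta2, c(0.05, 0.95), names = FALSE)
  thetas <- seq(qs[1], qs[2], length.out = n_thresholds)
  cs1 <- c(0, cumsum(eta1))
  sse <- vapply(thetas, function(th) {
    on <- eta2 >= th
    r <- rle(on)
    hi <- cumsum(r$lengths)
    lo <- c(1L, hi[-length(hi)] + 1L)
    means <- (cs1[hi + 1] - cs1[lo]) / r$lengths
    eta3 <- rep(means, r$lengths)
    sum((eta3 - eta1)^2)
  }, numeric(1))
  theta <- thetas[which.min(sse)]

  structure(list(on = eta2 >= theta, theta = theta, changepoints = cps,
                 eta1 = eta1, eta2 = eta2, thetas = thetas, sse = sse,
                 degenerate = FALSE),
            class = "state_labels")
}

# slope-heuristic penalty: run PELT over a log-spaced penalty ladder, fit the
# slope of total cost vs number of changepoints over the steeper (many-
# changepoint) half, and use twice its magnitude as the final penalty
pelt_slope_penalty <- function(y, min_seg) {
  n <- length(y)
  base <- stats::var(y) * log(n)
  pens <- base * 10^seq(-2, 1.5, length.out = 12)
  fits <- lapply(pens, function(p) .pelt_meanshift(y, p, min_seg))
  ncp <- vapply(fits, function(f) f$n_cp, integer(1))
  # total unpenalized cost
  cost <- vapply(seq_along(fits), function(i)
    fits[[i]]$cost - pens[i] * ncp[i], numeric(1))
  keep <- !duplicated(ncp) & ncp > 0
  if (sum(keep) < 2) return(base)
  ncp_k <- ncp[keep]
  cost_k <- cost[keep]
  hi <- ncp_k >= stats::median(ncp_k)
  if (sum(hi) < 2) hi <- rep(TRUE, length(ncp_k))
  slope <- stats::coef(stats::lm(cost_k[hi] ~ ncp_k[hi]))[2]
  2 * abs(unname(slope))
}

#' @export
print.state_labels <- function(x, ...) {
  cat(sprintf("state_labels: %d ms, %.1f%% On, theta = %.3g, %d changepoints\n",
              length(x$on), 100 * mean(x$on), x$theta, length(x$changepoints)))
  invisible(x)
}

#' Joint two-area state labels
#'
#' Pointwise cross-product of two binary On/Off labelings on a common time
#' base: S-On (both On), S-Off (both Off), 1-On (only area 1), 2-On (only
#' area 2). The four labels partition the timeline.
#'
#' @param labels1,labels2 `state_labels` for the two sites.
#' @return Factor with levels `S-Off`, `1-On`, `2-On`, `S-On`.
#' @export
joint_states <- function(labels1, labels2) {
  if (length(labels1$on) != length(labels2$on))
    stop("state labelings cover different spans")
  f <- ifelse(labels1$on,
              ifelse(labels2$on, "S-On", "1-On"),
              ifelse(labels2$on, "2-On", "S-Off"))
  factor(f, levels = c("S-Off", "1-On", "2-On", "S-On"))
}

#' Duration and rate statistics of On/Off episodes
#'
#' @param labels A `state_labels` (or logical vector at 1 kHz).
#' @param mua_signal Optional MUA [continuous_signal()] used to condition
#'   firing rates on state.
#' @return A `state_stats` list: On/Off run durations (ms), their means,
#'   mean MUA rate per state (Hz), and On-episode midpoints (ms).
#' @export
state_stats <- function(labels, mua_signal = NULL) {
  on <- if (inherits(labels, "state_labels")) labels$on else as.logical(labels)
  r <- rle(on)
  hi <- cumsum(r$lengths)
  lo <- c(1L, hi[-length(hi)] + 1L)
  t_on <- r$lengths[r$values]
  t_off <- r$lengths[!r$values]
  mid <- (lo[r$values] + hi[r$values]) / 2
  out <- list(t_on = t_on, t_off = t_off,
              mean_on = mean(t_on), mean_off = mean(t_off),
              on_midpoints = mid)
  if (!is.null(mua_signal)) {
    x <- sig_values(mua_signal)
    out$r_on <- mean(x[on])
    out$r_off <- mean(x[!on])
  }
  class(out) <- "state_stats"
  out
}

#' @export
print.state_stats <- function(x, ...) {
  cat(sprintf("state_stats: mean t_on %.2f ms (n=%d), mean t_off %.2f ms (n=%d)\n",
              x$mean_on, length(x$t_on), x$mean_off, length(x$t_off)))
  if (!is.null(x$r_on))
    cat(sprintf("  mean rate On %.2f Hz, Off %.2f Hz\n", x$r_on, x$r_off))
  invisible(x)
}

#' Theta phase of state events
#'
#' Band-passes the MUA into the theta band (3-6 Hz by default), extracts
#' the Hilbert phase, and samples it at event midpoints (e.g. the middle of
#' each simultaneous-On episode).
#'
#' @param mua_signal MUA [continuous_signal()] at 1 kHz.
#' @param midpoints Event midpoints in ms (samples).
#' @param band Theta band, Hz.
#' @return List with `phases_deg` per event and the circular mean
#'   `mean_deg` in degrees in `[0, 360)`.
#' @export
event_theta_phase <- function(mua_signal, midpoints, band = c(3, 6)) {
  midpoints <- midpoints[is.finite(midpoints)]
  if (!length(midpoints))
    return(list(phases_deg = numeric(0), mean_deg = NA_real_))
  ph <- narrowband_phase(mua_signal, band)$phase
  idx <- pmin(pmax(round(midpoints), 1), length(ph))
  phases <- ph[idx]
  mean_rad <- Arg(mean(exp(1i * phases)))
  list(phases_deg = (phases * 180 / pi) %% 360,
       mean_deg = (mean_rad * 180 / pi) %% 360)
}
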