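#' Uniformly sampled population signal
#'
#' @param x Numeric samples.
#' @param fs Sampling rate, Hz (signals in this package live at 1 kHz).
#' @param kind `"MUA"`, `"LFP"` or `"filtered"`.
#' @param site Optional site metadata (center, radius, area).
#' @return A `continuous_signal`.
#' @export
continuous_signal <- function(x, fs = 1000, kind = "MUA", site = NULL) {
  s <- list(x = as.numeric(x), fs = fs, kind = kind, site = site)
  class(s) <- "continuous_signal"
  s
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("continuous_signal (%s): %d samples at %g Hz\n",
              x$kind, length(x$x), x$fs))
  invisible(x)
}

#' @export
as.numeric.continuous_signal <- function(x, ...) x$x

sig_values <- function(s) if (inherits(s, "continuous_signal")) s$x else as.numeric(s)

#' Center of mass of spiking activity on the periodic plane
#'
#' Tracks the wave packet as the circular (resultant-vector) mean of
#' spike-count-weighted excitatory neuron coordinates, per axis:
#' `y_c = Arg( sum_j n_j exp(i y_j pi / hw) ) * hw / pi`, evaluated in a
#' sliding window. Samples with no spikes, or with a vanishing resultant,
#' are undefined and returned as `NA` (carried as gaps, not interpolated).
#'
#' @param raster A `spike_raster`.
#' @param area Which area's excitatory population to track.
#' @param times Evaluation times, ms (default every ms of the span).
#' @param window Window length, ms.
#' @return A `pattern_trajectory`: data frame with `t`, `x`, `y`.
#' @export
center_of_mass <- function(raster, area = 1, times = NULL, window = 10) {
  g <- raster$geometry
  hw <- g$half_width
  if (is.null(times))
    times <- seq(ceiling(raster$span[1]), floor(raster$span[2]), by = 1)
  keep <- raster$labels$type[raster$id] == "e" & raster$labels$area[raster$id] == area
  t <- raster$t[keep]
  xy <- raster$coords[raster$id[keep], , drop = FALSE]
  phx <- exp(1i * xy[, 1] * pi / hw)
  phy <- exp(1i * xy[, 2] * pi / hw)
  # per-ms complex sums, then sliding window sums centered on each time
  lo <- times - window / 2
  hi <- times + window / 2
  ordt <- order(t)
  t <- t[ordt]; phx <- phx[ordt]; phy <- phy[ordt]
  csx <- c(0, cumsum(phx))
  csy <- c(0, cumsum(phy))
  cnt <- c(0, cumsum(rep(1, length(t))))
  i_lo <- findInterval(lo, t, left.open = TRUE)   # spikes with t > lo start at i_lo+1
  i_hi <- findInterval(hi, t)                     # spikes with t <= hi
  sx <- csx[i_hi + 1] - csx[i_lo + 1]
  sy <- csy[i_hi + 1] - csy[i_lo + 1]
  n <- cnt[i_hi + 1] - cnt[i_lo + 1]
  eps <- 1e-9 * pmax(n, 1)
  x <- ifelse(n == 0 | Mod(sx) < eps, NA_real_, Arg(sx) * hw / pi)
  y <- ifelse(n == 0 | Mod(sy) < eps, NA_real_, Arg(sy) * hw / pi)
  # map the seam value +hw to -hw so coordinates live in [-hw, hw)
  x <- ifelse(!is.na(x) & x >= hw, -hw, x)
  y <- ifelse(!is.na(y) & y >= hw, -hw, y)
  structure(data.frame(t = times, x = x, y = y, n = n),
            window = window, half_width = hw, class = c("pattern_trajectory",
                                                        "data.frame"))
}

#' Multi-unit activity of a local neuron group
#'
#' Mean firing rate of the excitatory neurons within `radius` grid points of
#' a site center (80 neurons for the standard radius 5 on the full lattice),
#' computed in a sliding window of `bin` ms and sampled at 1 kHz. Use
#' `bin = 10` for On/Off state detection and `bin = 1` for spectral, phase
#' locking, and transfer entropy analyses.
#'
#' @param raster A `spike_raster`.
#' @param center Site center, grid coordinates.
#' @param radius Site radius, grid points.
#' @param bin Window length, ms.
#' @param area Area of the site.
#' @return A [continuous_signal()] in Hz, one sample per ms of the span.
#' @export
mua <- function(raster, center = c(0, 0), radius = 5, bin = 10, area = 1) {
  g <- raster$geometry
  members <- site_neurons(g, center, radius, area = area, type = "e")
  if (!length(members)) stop("no excitatory neurons within the site radius")
  keep <- raster$id %in% members
  t <- raster$t[keep]
  n_ms <- floor(raster$span[2] - raster$span[1])
  counts <- tabulate(pmin(floor(t - raster$span[1]) + 1L, n_ms), nbins = n_ms)
  # centered sliding sum of width `bin`, truncated at the edges
  cs <- c(0, cumsum(counts))
  ms <- seq_len(n_ms)
  lo <- pmax(ms - floor(bin / 2), 1)
  hi <- pmin(ms + ceiling(bin / 2) - 1, n_ms)
  s <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  rate <- s / length(members) * 1000   # spikes/ms/neuron -> Hz
  continuous_signal(rate, fs = 1000, kind = "MUA",
                    site = list(center = center, radius = radius,
                                area = area, n_neurons = length(members)))
}

#' LFP proxy from recorded synaptic current decompositions
#'
#' Gaussian-distance-weighted sum, over excitatory neurons, of the absolute
#' intra-areal excitatory, inter-areal excitatory, and intra-areal
#' inhibitory synaptic currents, with spatial scale `sigma_lfp`.
#'
#' @param currents The `$currents` element of a [simulate_network()] result
#'   recorded for the excitatory neurons of one area.
#' @param geometry The corresponding [network_geometry()].
#' @param center Site center.
#' @param sigma_lfp Spatial scale, grid units (default 7).
#' @return A [continuous_signal()].
#' @export
lfp_proxy <- function(currents, geometry, center = c(0, 0), sigma_lfp = 7) {
  if (is.null(currents)) stop("simulation was run without current recording")
  xy <- as.matrix(geometry_coords(geometry))[currents$neurons, , drop = FALSE]
  d <- torus_distance(xy, matrix(center, nrow(xy), 2, byrow = TRUE),
                      geometry$L)
  w <- exp(-d^2 / (2 * sigma_lfp^2))
  tot <- abs(currents$I_e_intra) + abs(currents$I_e_inter) +
    abs(currents$I_i_intra)
  continuous_signal(as.numeric(tot %*% w), fs = 1000, kind = "LFP",
                    site = list(center = center, sigma = sigma_lfp))
}

# analytic signal via FFT (zero-pad-free Hilbert transform)
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Narrowband phase via zero-phase Butterworth filtering
#'
#' Band-passes the signal with an order-8 Butterworth filter applied
#' forward and backward (zero phase), then extracts the instantaneous phase
#' of the analytic signal. The theta band used for event phases is 3-6 Hz;
#' gamma phase locking uses bands `f_c` +/- 5 Hz.
#'
#' @param signal A [continuous_signal()] or numeric vector at `fs` Hz.
#' @param band Length-2 band edges in Hz (-3 dB points).
#' @param fs Sampling rate when `signal` is a bare vector.
#' @return List with `phase` (radians, in `[-pi, pi)`), `amplitude`, and the
#'   filtered signal.
#' @export
narrowband_phase <- function(signal, band, fs = 1000) {
  x <- sig_values(signal)
  if (inherits(signal, "continuous_signal")) fs <- signal$fs
  nyq <- fs / 2
  if (band[1] <= 0 || band[2] >= nyq) stop("band edges outside (0, Nyquist)")
  xf <- butter_bandpass_filtfilt(x - mean(x), band[1], band[2], fs)
  a <- hilbert_analytic(xf)
  list(phase = Arg(a), amplitude = Mod(a), filtered = xf)
}

# Order-8 Butterworth band-pass (analog prototype order 4, lowpass-to-
# bandpass transform, bilinear with prewarping), realized as a cascade of
# biquad sections and applied forward-backward per section. The cascade
# form stays numerically stable for the narrow low-frequency bands (e.g.
# theta 3-6 Hz at 1 kHz) where the expanded transfer function is not.
butter_bandpass_filtfilt <- function(x, lo, hi, fs, order = 4) {
  w1 <- 2 * tan(pi * lo / fs)
  w2 <- 2 * tan(pi * hi / fs)
  w02 <- w1 * w2
  B <- w2 - w1
  # left-half-plane Butterworth prototype poles
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # each prototype pole maps to a pole pair of the band-pass
  poles <- unlist(lapply(p, function(pk) {
    disc <- sqrt((pk * B)^2 - 4 * w02)
    c((pk * B + disc) / 2, (pk * B - disc) / 2)
  }))
  # group into conjugate pairs (poles come in conjugate sets because the
  # prototype set is self-conjugate); pick one of each pair by Im >= 0
  sel <- poles[Im(poles) >= 0]
  sel <- sel[order(Re(sel), Im(sel))]
  theta0 <- 2 * atan(sqrt(w02) / 2)
  for (s1 in sel) {
    a1 <- -2 * Re(s1)
    a0 <- Mod(s1)^2
    K <- 2
    den <- c(K^2 + a1 * K + a0, 2 * (a0 - K^2), K^2 - a1 * K + a0)
    num <- c(K, 0, -K)
    b <- num / den[1]
    a <- den / den[1]
    # unit gain at the (prewarped) center frequency
    z <- exp(-1i * theta0 * (0:2))
    g <- Mod(sum(b * z) / sum(a * z))
    x <- signal::filtfilt(b / g, a, x)
  }
  x
}
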