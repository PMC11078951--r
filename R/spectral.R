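#' Power spectrum with aperiodic (1/f) separation
#'
#' Epoch-averaged FFT periodogram of a 1 kHz signal together with its
#' aperiodic component estimated by irregular-resampling auto-spectral
#' analysis (IRASA): for each resampling factor `h` the signal is resampled
#' by `h` and `1/h`, the geometric mean of the two periodograms is taken,
#' and the median across factors estimates the fractal (1/f) floor, which
#' oscillatory peaks cannot survive because they are shifted off their
#' frequency by the resampling. The oscillatory residual is raw minus
#' aperiodic, and the 1/f exponent comes from a log-log least-squares fit.
#'
#' @param signal A [continuous_signal()] or numeric vector.
#' @param fs Sampling rate when `signal` is a bare vector.
#' @param epoch Epoch length in seconds; the signal is cut into
#'   non-overlapping epochs, each mean-removed.
#' @param hset Resampling factors (defaults 1.1 to 1.9 in steps of 0.05).
#' @param fit_range Frequency range (Hz) for the 1/f exponent fit.
#' @return List: `freq`, `raw`, `aperiodic`, `residual` and `exponent`.
#' @export
power_spectrum <- function(signal, fs = 1000, epoch = 5,
                           hset = seq(1.1, 1.9, by = 0.05),
                           fit_range = c(1, 100)) {
  x <- sig_values(signal)
  if (inherits(signal, "continuous_signal")) fs <- signal$fs
  n_ep <- floor(length(x) / (epoch * fs))
  if (n_ep < 1) stop("signal shorter than one epoch")
  nfft <- as.integer(epoch * fs)
  freq <- seq(0, fs / 2, by = 1 / epoch)[-1]
  nf <- length(freq)

  pgram <- function(y, nf_out) {
    y <- y - mean(y)
    p <- Mod(stats::fft(y))^2 / length(y)
    p[2:(nf_out + 1)]
  }
  resample_to <- function(y, factor, n_out) {
    # fractional resampling by linear interpolation onto n_out samples
    stats::approx(seq_along(y), y, xout = seq(1, length(y),
                                              length.out = n_out))$y
  }

  raw <- matrix(0, nf, n_ep)
  ap <- matrix(0, nf, n_ep)
  for (e in seq_len(n_ep)) {
    y <- x[((e - 1) * nfft + 1):(e * nfft)]
    raw[, e] <- pgram(y, nf)
    gm <- matrix(0, nf, length(hset))
    for (k in seq_along(hset)) {
      h <- hset[k]
      up <- resample_to(y, h, round(nfft * h))
      dn <- resample_to(y, 1 / h, round(nfft / h))
      # periodograms on the native grids of the resampled series, read back
      # at the original frequencies
      pu <- pgram(up, floor(length(up) / 2))
      fu <- seq_len(length(pu)) * (fs * h / length(up)) / 1  # Hz
      pd <- pgram(dn, floor(length(dn) / 2))
      fd <- seq_len(length(pd)) * (fs / h / length(dn))
      su <- stats::approx(fu, pu, xout = freq, rule = 2)$y
      sd_ <- stats::approx(fd, pd, xout = freq, rule = 2)$y
      gm[, k] <- sqrt(pmax(su, 0) * pmax(sd_, 0))
    }
    ap[, e] <- apply(gm, 1, stats::median)
  }
  raw_m <- rowMeans(raw)
  ap_m <- rowMeans(ap)
  sel <- freq >= fit_range[1] & freq <= fit_range[2] & ap_m > 0
  fit <- stats::lm(log10(ap_m[sel]) ~ log10(freq[sel]))
  list(freq = freq, raw = raw_m, aperiodic = ap_m,
       residual = raw_m - ap_m, exponent = -unname(stats::coef(fit)[2]))
}

# complex Morlet wavelet amplitude at one frequency via FFT convolution
morlet_amplitude <- function(x, f0, fs, n_cycles = 7) {
  n <- length(x)
  sigma_t <- n_cycles / (2 * pi * f0)
  # frequency-domain Gaussian centered at f0 (analytic wavelet)
  freqs <- (seq_len(n) - 1) / n * fs
  H <- exp(-0.5 * ((freqs - f0) * 2 * pi * sigma_t)^2) * 2
  Mod(stats::fft(stats::fft(x) * H, inverse = TRUE) / n)
}

#' Gamma-burst detection mask
#'
#' Complex Morlet wavelet amplitudes over the gamma band (30-80 Hz in 2 Hz
#' steps), smoothed in time by a Gaussian kernel (SD 3 ms), and thresholded
#' at the 85th percentile of the amplitude pooled over all gamma frequencies
#' and times of the realization. By construction 15% of the
#' (frequency, time) amplitude mass exceeds the threshold.
#'
#' @param signal A [continuous_signal()] (1 kHz) or numeric vector.
#' @param freqs Analysis frequencies, Hz.
#' @param smooth_sd Temporal smoothing SD, ms.
#' @param prob Pooled percentile used as threshold.
#' @param n_cycles Morlet mother-wavelet width, cycles.
#' @param fs Sampling rate when `signal` is a bare vector.
#' @return A `burst_mask`: logical matrix (frequency x time), with the
#'   amplitude matrix and threshold as attributes.
#' @export
gamma_burst_mask <- function(signal, freqs = seq(30, 80, by = 2),
                             smooth_sd = 3, prob = 0.85, n_cycles = 7,
                             fs = 1000) {
  x <- sig_values(signal)
  if (inherits(signal, "continuous_signal")) fs <- signal$fs
  x <- x - mean(x)
  sd_samp <- smooth_sd * fs / 1000
  klen <- max(1L, as.integer(round(6 * sd_samp)) %/% 2L * 2L + 1L)
  kern <- stats::dnorm(seq(-(klen %/% 2), klen %/% 2), sd = sd_samp)
  kern <- kern / sum(kern)
  amp <- matrix(0, length(freqs), length(x))
  for (i in seq_along(freqs)) {
    a <- morlet_amplitude(x, freqs[i], fs, n_cycles)
    amp[i, ] <- stats::filter(a, kern, sides = 2)
  }
  # edge samples where the smoother is undefined: fall back to raw amplitude
  nas <- is.na(amp[1, ])
  if (any(nas)) {
    for (i in seq_along(freqs))
      amp[i, nas] <- morlet_amplitude(x, freqs[i], fs, n_cycles)[nas]
  }
  thr <- stats::quantile(amp, prob, names = FALSE)
  mask <- amp >= thr & amp > 0   # a flat signal has no bursts
  structure(mask, amplitude = amp, threshold = thr, freqs = freqs,
            class = "burst_mask")
}
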