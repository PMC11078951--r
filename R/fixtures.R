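#' Synthetic fixtures with known ground truth
#'
#' Generators emitting data whose statistical structure matches what each
#' analysis assumes, together with the truth needed for parameter-recovery
#' tests:
#' \describe{
#'   \item{telegraph-mua}{Two-level telegraph MUA: a hidden On/Off state
#'     with exponential dwell times drives Poisson spiking of an 80-neuron
#'     group; returns the 10 ms-binned MUA and the exact switch times.}
#'   \item{pac-signal}{A slow oscillation whose phase modulates the
#'     amplitude of a fast oscillation, on a 1/f^beta noise floor.}
#'   \item{ar-pair}{Delay-coupled Gaussian pair
#'     `Y_t = c X_{t-u} + sqrt(1-c^2) e_t` with known delay and coupling;
#'     the closed-form Gaussian transfer entropy `-log(1-c^2)/2` is part of
#'     the truth record.}
#'   \item{low-rank-counts}{`Y = X B0 + eps` with a known-rank `B0`.}
#'   \item{poisson-raster}{Homogeneous Poisson spike trains as a
#'     `spike_raster` on a given geometry.}
#'   \item{shaped-noise}{Gaussian noise spectrally shaped to `1/f^beta`.}
#' }
#'
#' @param generator Generator name (see above).
#' @param ... Generator parameters (each has defaults matching the
#'   regimes the analyses are tested in).
#' @param seed Integer seed.
#' @return List with `data` and `truth`.
#' @export
generate_fixture <- function(generator = c("telegraph-mua", "pac-signal",
                                           "ar-pair", "low-rank-counts",
                                           "poisson-raster", "shaped-noise"),
                             ..., seed = 1) {
  generator <- match.arg(generator)
  fn <- switch(generator,
    "telegraph-mua" = fixture_telegraph_mua,
    "pac-signal" = fixture_pac_signal,
    "ar-pair" = fixture_ar_pair,
    "low-rank-counts" = fixture_low_rank_counts,
    "poisson-raster" = fixture_poisson_raster,
    "shaped-noise" = fixture_shaped_noise)
  fn(..., seed = seed)
}

fixture_telegraph_mua <- function(duration = 60000, rate_on = 40,
                                  rate_off = 2, dwell_on = 50,
                                  dwell_off = 250, n_neurons = 80,
                                  bin = 10, seed = 1) {
  with_seed(seed, {
    # alternating exponential dwells until the span is covered
    t <- 0
    on <- runif(1) < dwell_on / (dwell_on + dwell_off)
    switches <- numeric(0)
    states <- logical(0)
    starts <- numeric(0)
    while (t < duration) {
      starts <- c(starts, t)
      states <- c(states, on)
      dwell <- stats::rexp(1, 1 / if (on) dwell_on else dwell_off)
      t <- t + dwell
      switches <- c(switches, t)
      on <- !on
    }
    state_ms <- logical(duration)
    for (i in seq_along(starts)) {
      lo <- floor(starts[i]) + 1
      hi <- min(floor(if (i < length(starts)) starts[i + 1] else duration),
                duration)
      if (hi >= lo) state_ms[lo:hi] <- states[i]
    }
    rate <- ifelse(state_ms, rate_on, rate_off)
    counts <- stats::rpois(duration, rate * n_neurons / 1000)
    cs <- c(0, cumsum(counts))
    ms <- seq_len(duration)
    lo <- pmax(ms - floor(bin / 2), 1)
    hi <- pmin(ms + ceiling(bin / 2) - 1, duration)
    mua <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1) / n_neurons * 1000
    list(data = continuous_signal(mua, kind = "MUA"),
         truth = list(state = state_ms, switch_times = utils::head(
           switches, -1), rate_on = rate_on, rate_off = rate_off))
  })
}

fixture_pac_signal <- function(duration = 50000, f_phase = 3, f_amp = 70,
                               depth = 0.8, floor_beta = 1, floor_sd = 0.5,
                               seed = 1) {
  t <- seq_len(duration) / 1000
  slow <- sin(2 * pi * f_phase * t)
  phase <- 2 * pi * f_phase * t
  envelope <- 1 + depth * cos(phase)   # amplitude tied to slow phase
  fast <- envelope * sin(2 * pi * f_amp * t)
  noise <- fixture_shaped_noise(duration, beta = floor_beta,
                                seed = seed)$data$x
  x <- slow + 0.5 * fast + floor_sd * noise / stats::sd(noise)
  list(data = continuous_signal(x, kind = "LFP"),
       truth = list(f_phase = f_phase, f_amp = f_amp, depth = depth))
}

fixture_ar_pair <- function(n = 50000, delay = 10, coupling = 0.8,
                            seed = 1) {
  with_seed(seed, {
    x <- stats::rnorm(n + delay)
    e <- stats::rnorm(n)
    y <- coupling * x[seq_len(n)] + sqrt(1 - coupling^2) * e
    list(data = list(source = x[delay + seq_len(n)], target = y),
         truth = list(delay = delay, coupling = coupling,
                      te_nats = -0.5 * log(1 - coupling^2)))
  })
}

fixture_low_rank_counts <- function(n = 2000, p = 30, rank = 3,
                                    noise_sd = 1, signal_sd = 1, seed = 1) {
  with_seed(seed, {
    U <- matrix(stats::rnorm(p * rank), p, rank)
    V <- matrix(stats::rnorm(p * rank), p, rank)
    B0 <- signal_sd * U %*% t(V) / sqrt(p)
    X <- matrix(stats::rnorm(n * p), n, p)
    Y <- X %*% B0 + noise_sd * matrix(stats::rnorm(n * p), n, p)
    list(data = list(X = X, Y = Y), truth = list(B0 = B0, rank = rank))
  })
}

fixture_poisson_raster <- function(rate = 10, duration = 10000,
                                   geometry = network_geometry(8),
                                   neurons = NULL, seed = 1) {
  with_seed(seed, {
    if (is.null(neurons)) neurons <- seq_len(geometry$N)
    counts <- stats::rpois(length(neurons), rate * duration / 1000)
    id <- rep(neurons, counts)
    t <- stats::runif(sum(counts), 0, duration)
    list(data = spike_raster(id, t, geometry, c(0, duration)),
         truth = list(rate = rate))
  })
}

fixture_shaped_noise <- function(n = 50000, beta = 1, seed = 1) {
  with_seed(seed, {
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- c(1, seq_len(n - 1))
    f <- pmin(f, n - f + 1)   # symmetric frequency index
    H <- 1 / f^(beta / 2)
    x <- Re(stats::fft(W * H, inverse = TRUE) / n)
    list(data = continuous_signal(x - mean(x), kind = "filtered"),
         truth = list(beta = beta))
  })
}
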