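test_that("CV of ISI separates periodic from Poisson firing", {
  g <- network_geometry(4)
  per <- spike_raster(rep(1L, 100), seq(10, 1000, by = 10), g, c(0, 1010))
  expect_equal(cv_isi(per, 1)$cv[[1]], 0)
  set.seed(61)
  ts <- cumsum(rexp(1000, rate = 0.01))   # Poisson, 10 Hz in ms
  poi <- spike_raster(rep(1L, 1000), ts, g, c(0, max(ts) + 1))
  expect_equal(cv_isi(poi, 1)$cv[[1]], 1, tolerance = 0.05)
  # neurons below the spike minimum are excluded and counted
  few <- spike_raster(c(1L, 1L, 2L), c(1, 2, 3), g, c(0, 10))
  r <- cv_isi(few, 1:2)
  expect_equal(r$n_excluded, 2)
})

test_that("Fano factor calibrates to Poisson and degenerate counts", {
  g <- network_geometry(4)
  per <- spike_raster(rep(1L, 200), seq(2.5, 1000, by = 5), g, c(0, 1000))
  expect_equal(fano(per, 1, window = 50)$fano[[1]], 0)
  fx <- generate_fixture("poisson-raster", rate = 15, duration = 60000,
                         geometry = g, neurons = 1:30, seed = 62)
  f <- fano(fx$data, 1:30, window = 50)
  expect_equal(f$mean, 1, tolerance = 0.06)
})

test_that("mean-matched Fano is ~1 for rate-modulated Poisson trials", {
  g <- network_geometry(4)
  set.seed(63)
  gains <- exp(rnorm(30, 0, 0.4))   # heterogeneous neuron gains
  mk_trials <- function(gain, n_trials = 40) {
    lapply(seq_len(n_trials), function(i) {
      # shared time-varying rate profile, independent Poisson neurons
      prof <- gain * (8 + 2 * sin(2 * pi * seq_len(600) / 300)) / 1000
      rate <- outer(prof, gains)
      idx <- which(matrix(runif(600 * 30), 600, 30) < rate)
      spike_raster(((idx - 1) %/% 600) + 1L, ((idx - 1) %% 600) + runif(length(idx)),
                   g, c(0, 600))
    })
  }
  tr <- list(uncued = mk_trials(1), cued = mk_trials(1.3))
  mmf <- mean_matched_fano(tr, neurons = 1:30, resamples = 20, n_bins = 8,
                           seed = 64)
  expect_equal(mean(mmf$uncued), 1, tolerance = 0.1)
  expect_equal(mean(mmf$cued), 1, tolerance = 0.1)
  # degenerate slope: one mean bin reduces to variance/mean
  m <- c(2, 2, 2); v <- c(3, 3, 3)
  expect_equal(sum(m * v) / sum(m * m), 1.5)
})

test_that("noise correlations vanish for independent neurons and hit 1 for copies", {
  g <- network_geometry(4)
  set.seed(65)
  trials <- lapply(1:40, function(i) {
    idx <- which(matrix(runif(600 * 20), 600, 20) < 0.012)
    spike_raster(((idx - 1) %/% 600) + 1L, ((idx - 1) %% 600) + 0.5,
                 g, c(0, 600))
  })
  nc <- noise_correlation(trials, 1:20)
  expect_lt(abs(mean(nc$r, na.rm = TRUE)), 2 / sqrt(40))
  # a pair with identical counts correlates perfectly
  a <- wavecomm:::trial_counts(trials, 1:2, 50, 10)
  a[, 2, ] <- a[, 1, ]
  M <- a[, , 5]
  expect_equal(stats::cor(M[, 1], M[, 2]), 1)
})
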