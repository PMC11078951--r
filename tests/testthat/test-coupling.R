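test_that("modulation index is zero for uniform phase-amplitude distributions", {
  # analytic: uniform p gives MI = 0 by the entropy formula
  p <- rep(1 / 20, 20)
  expect_equal(1 - (-sum(p * log(p))) / log(20), 0)
  # phase-independent amplitude: corrected MI ~ 0 within the shuffle spread
  wn <- generate_fixture("shaped-noise", n = 40000, beta = 0, seed = 41)$data$x
  r <- pac_mi(wn, c(2, 4), c(60, 80), n_shuffles = 100, seed = 1)
  # the corrected MI fluctuates more than the shuffle spread because the
  # filtered amplitude is autocorrelated; near-zero here means small on the
  # scale of genuine coupling (which sits at 0.01-0.2)
  expect_lt(abs(r$mi), 0.005)
})

test_that("MI shuffle correction is unbiased over noise realizations", {
  mis <- vapply(1:20, function(i) {
    x <- generate_fixture("shaped-noise", n = 15000, beta = 0,
                          seed = 100 + i)$data$x
    pac_mi(x, c(3, 5), c(50, 70), n_shuffles = 60, seed = i)$mi
  }, numeric(1))
  expect_lt(abs(mean(mis)), 0.002)
})

test_that("synthetic phase-amplitude coupling is localized on the comodulogram", {
  fx <- generate_fixture("pac-signal", duration = 50000, f_phase = 3,
                         f_amp = 70, seed = 42)
  cm <- comodulogram(fx$data, phase_freqs = c(2, 3, 4, 6, 8),
                     amp_freqs = c(40, 55, 70, 85, 100),
                     n_shuffles = 40, seed = 2)
  pk <- which(cm == max(cm), arr.ind = TRUE)
  expect_equal(as.numeric(rownames(cm)[pk[1]]), 3)
  expect_equal(as.numeric(colnames(cm)[pk[2]]), 70)
})

test_that("phase locking value behaves at its extremes and under mixing", {
  x <- generate_fixture("shaped-noise", n = 20000, beta = 1, seed = 43)$data$x
  same <- plv(x, x, 50, n_shuffles = 30, seed = 3)
  expect_equal(same$plv_raw, 1, tolerance = 1e-9)
  y <- generate_fixture("shaped-noise", n = 20000, beta = 1, seed = 44)$data$x
  indep <- plv(x, y, 50, n_shuffles = 60, seed = 4)
  expect_lt(abs(indep$plv), 0.05)
  # raw PLV never increases (in expectation) as independent noise is added
  set.seed(45)
  noise <- rnorm(20000)
  lvl <- c(0, 0.5, 1, 2, 4)
  raw <- vapply(lvl, function(a)
    plv(x, x + a * noise * stats::sd(x), 50, n_shuffles = 1, seed = 5)$plv_raw,
    numeric(1))
  expect_true(all(diff(raw) < 0.02))
  expect_lt(raw[5], raw[1])
})

test_that("PLV warns when a state mask selects too few samples", {
  x <- rnorm(5000)
  m <- rep(FALSE, 5000); m[1:100] <- TRUE
  expect_warning(plv(x, x, 40, mask = m, n_shuffles = 2), "unstable")
})

test_that("transfer entropy matches the closed-form Gaussian oracle", {
  fx <- generate_fixture("ar-pair", n = 50000, delay = 10, coupling = 0.8,
                         seed = 46)
  te10 <- transfer_entropy(fx$data$source, fx$data$target, u = 10,
                           k = 1, l = 1, seed = 6)
  expect_equal(te10, fx$truth$te_nats, tolerance = 0.1)
  # the delay profile peaks at the true delay
  tc <- te_curve(fx$data$source, fx$data$target, delays = c(4, 7, 10, 13, 16),
                 seed = 6)
  expect_equal(tc$u[which.max(tc$te)], 10)
  # independent pair: TE ~ 0 (possibly slightly negative)
  y <- rnorm(20000)
  z <- rnorm(20000)
  te0 <- transfer_entropy(y, z, u = 5, k = 1, l = 1, seed = 7)
  expect_lt(abs(te0), 0.01)
})

test_that("transfer entropy respects epoch masks and determinism", {
  fx <- generate_fixture("ar-pair", n = 30000, delay = 5, coupling = 0.7,
                         seed = 47)
  mask <- rep(c(TRUE, FALSE), each = 500, length.out = 30000)
  a <- transfer_entropy(fx$data$source, fx$data$target, u = 5, mask = mask,
                        seed = 8)
  b <- transfer_entropy(fx$data$source, fx$data$target, u = 5, mask = mask,
                        seed = 8)
  expect_identical(a, b)
  expect_gt(a, 0.1)
  # too few valid embeddings -> error
  tiny <- rep(FALSE, 30000); tiny[1:1200] <- rep(c(TRUE, FALSE), 600)
  expect_error(transfer_entropy(fx$data$source, fx$data$target, u = 5,
                                mask = tiny), "embedding")
})

test_that("history selection finds a compact embedding for a Markov pair", {
  fx <- generate_fixture("ar-pair", n = 20000, delay = 3, coupling = 0.9,
                         seed = 48)
  sel <- select_history(fx$data$source, fx$data$target, u = 3, kl_max = 3,
                        n_eval = 800, seed = 9)
  expect_lte(sel$k + sel$l, 4)
})
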