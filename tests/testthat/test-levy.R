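test_that("alpha-stable draws honor the Gaussian limit and heavy tails", {
  # alpha = 2 reduces to N(0, 2 * scale^2)
  x <- sample_sas_step(200000, alpha = 2, scale = 1, seed = 71)
  expect_equal(stats::var(x), 2, tolerance = 0.03)
  expect_lt(abs(mean(x)), 0.02)
  # alpha = 1.2: Hill tail index on the top 1%
  y <- sample_sas_step(100000, alpha = 1.2, scale = 1, seed = 72)
  expect_equal(wavecomm:::hill_tail_index(y, 0.01), 1.2, tolerance = 0.1)
  expect_error(sample_sas_step(10, alpha = 0.9), "tail index")
})

test_that("increment scale grows as dt^(1/alpha)", {
  q1 <- stats::quantile(abs(sample_sas_step(200000, 1.2, 0.001^(1 / 1.2), 73)),
                        c(0.5, 0.9))
  q2 <- stats::quantile(abs(sample_sas_step(200000, 1.2, 0.002^(1 / 1.2), 74)),
                        c(0.5, 0.9))
  expect_equal(unname(q2 / q1), rep(2^(1 / 1.2), 2), tolerance = 0.05)
})

test_that("the drift field is the analytic gradient of the landscape", {
  land <- potential_landscape(D_s = 50, D_a1 = 25)
  # outside all wells and at well centers the drift vanishes
  expect_equal(drift(c(16, 16), land), matrix(0, 1, 2))
  expect_equal(drift(c(0, 0), land), matrix(0, 1, 2))
  # central-difference oracle inside the center well
  for (p in list(c(4, -3), c(-8, 6), c(10, 10))) {
    eps <- 1e-6
    num <- -c(potential_at(p + c(eps, 0), land) - potential_at(p - c(eps, 0), land),
              potential_at(p + c(0, eps), land) - potential_at(p - c(0, eps), land)) /
      (2 * eps) * land$prefactor
    expect_equal(as.numeric(drift(p, land)), num, tolerance = 1e-6)
  }
  # continuity at the rim: |rho| < 1e-9 on a ring at distance sigma_p
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  ring <- cbind(15 * cos(th), 15 * sin(th))
  # ring points may fall inside the corner well's image; test the bare rim
  rim <- potential_landscape(D_s = 50, D_a1 = 0,
                             centers = list(c(0, 0)))
  expect_lt(max(abs(potential_at(ring, rim))), 1e-9)
})

test_that("walker occupancy concentrates in deep wells", {
  wp <- walker_params(trial_duration = 100, trials = 1)
  land <- potential_landscape(D_s = 50, D_a1 = 50,
                              centers = list(c(0, 0)))
  tr <- integrate_walker(wp, land, seed = 75)
  d <- torus_distance(cbind(tr$x, tr$y), matrix(0, nrow(tr), 2), 64)
  frac <- mean(d < 10)
  expect_gt(frac, pi * 100 / 64^2)   # far above uniform occupancy
  expect_true(all(abs(tr$x) <= 32 & abs(tr$y) <= 32))
})

test_that("center dwell durations grow with attention depth", {
  wp <- walker_params(trial_duration = 150, trials = 4)
  on_ms <- vapply(c(0, 25, 50), function(Da) {
    tab <- walker_variability(wp, depths = Da, seed = 76,
                              keep_on_durations = TRUE)
    tab$mean_on_ms
  }, numeric(1))
  expect_gt(on_ms[3], on_ms[1])
  expect_gt(on_ms[2], 0.9 * on_ms[1])
})

test_that("rate field combines walker bump and attention baseline", {
  land0 <- potential_landscape(D_a1 = 0)
  land50 <- potential_landscape(D_a1 = 50)
  # neuron outside the center well: baseline 3 Hz plus the distant bump tail
  d2 <- torus_distance(c(20, 20), c(0, 0), 64)^2
  expect_equal(rate_field_at(c(0, 0), c(20, 20), land0),
               20 * exp(-d2 / 288) + 3, tolerance = 1e-9)
  expect_equal(rate_field_at(c(-20, -20), c(12, 12), land0), 3,
               tolerance = 0.01)   # opposite corner of the torus
  # neuron at the walker position outside the center well: 23 Hz
  expect_equal(rate_field_at(c(20, 20), c(20, 20), land0), 23)
  # attention boost at the center well's bottom: A_b + 0.2 * D_a1 (+ tail)
  expect_equal(rate_field_at(c(20, 20), c(0, 0), land50),
               20 * exp(-d2 / 288) + 3 + 10, tolerance = 1e-9)
  expect_true(all(rate_field_at(c(0, 0), walker_lattice_pts <- as.matrix(
    expand.grid(seq(-31.5, 31.5, 7), seq(-31.5, 31.5, 7))), land50) >= 3))
})

test_that("spike generation is a calibrated Poisson thinning", {
  expect_length(generate_spikes(matrix(0, 100, 3))$id, 0)
  rates <- matrix(10, 100000, 1)
  sp <- generate_spikes(rates, dt = 0.001, seed = 77)
  expect_lt(abs(length(sp$id) - 1000), 3 * sqrt(1000))
  expect_warning(generate_spikes(matrix(2000, 10, 1)), "truncated")
  # a static rate field gives Fano ~ 1 and zero correlation
  cnt <- matrix(0, 363, 80)
  sp2 <- generate_spikes(matrix(10, 19965, 80), seed = 78)
  win <- floor((sp2$t * 1000) / 55) + 1
  for (k in seq_along(sp2$id)) cnt[win[k], sp2$id[k]] <- cnt[win[k], sp2$id[k]] + 1
  f <- apply(cnt, 2, function(v) stats::var(v) / mean(v))
  expect_equal(mean(f), 1, tolerance = 0.05)
  C <- stats::cor(cnt)
  expect_lt(abs(mean(C[upper.tri(C)])), 0.01)
})

test_that("variability declines monotonically with attention depth", {
  wp <- walker_params(trial_duration = 60, trials = 4)
  tab <- walker_variability(wp, depths = c(0, 25, 50), seed = 79)
  expect_true(all(diff(tab$fano) < 0))
  expect_true(all(diff(tab$noise_cor) < 0))
})
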