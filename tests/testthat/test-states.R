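test_that("constant MUA yields a single degenerate state", {
  expect_warning(st <- detect_on_off(rep(5, 3000)), "constant")
  expect_true(all(st$on))
  expect_true(st$degenerate)
})

test_that("telegraph MUA is segmented to >= 90% agreement with truth", {
  fx <- generate_fixture("telegraph-mua", duration = 60000, seed = 21)
  st <- detect_on_off(fx$data)
  agree <- mean(st$on == fx$truth$state)
  expect_gt(agree, 0.9)
  # threshold optimality: no scanned alternative has lower SSE
  expect_equal(st$theta, st$thetas[which.min(st$sse)])
  expect_true(all(st$sse >= min(st$sse)))
})

test_that("segmentation degrades gracefully when rate contrast halves", {
  fx <- generate_fixture("telegraph-mua", duration = 60000, rate_on = 20,
                         rate_off = 2, seed = 22)
  st <- detect_on_off(fx$data)
  expect_gt(mean(st$on == fx$truth$state), 0.8)
})

test_that("segmentation is robust to the smoothing window choice", {
  fx <- generate_fixture("telegraph-mua", duration = 40000, seed = 23)
  a <- detect_on_off(fx$data, sg_window = 81)
  b <- detect_on_off(fx$data, sg_window = 101)
  expect_gt(mean(a$on == fx$truth$state), 0.88)
  expect_gt(mean(b$on == fx$truth$state), 0.88)
})

test_that("joint states partition the timeline as a cross-product", {
  mk <- function(on) structure(list(on = on), class = "state_labels")
  on1 <- mk(rep(TRUE, 100))
  expect_true(all(joint_states(on1, on1) == "S-On"))
  set.seed(31)
  a <- mk(runif(20000) < 0.3)
  b <- mk(runif(20000) < 0.6)
  j <- joint_states(a, b)
  expect_equal(sum(table(j)), 20000)       # partition, no overlap
  expect_equal(mean(j == "S-On"), 0.3 * 0.6, tolerance = 0.15)
  expect_equal(mean(j == "S-Off"), 0.7 * 0.4, tolerance = 0.15)
  expect_error(joint_states(on1, mk(rep(TRUE, 99))), "span")
})

test_that("state statistics are exact on constructed labels", {
  on <- rep(rep(c(TRUE, FALSE), 10), times = rep(c(50, 150), 10))
  ss <- state_stats(on)
  expect_equal(ss$mean_on, 50)
  expect_equal(ss$mean_off, 150)
  expect_equal(sum(ss$t_on) + sum(ss$t_off), length(on))
  # midpoints sit inside On runs
  expect_true(all(on[round(ss$on_midpoints)]))
  # durations sum per state equals labeled time
  st <- detect_on_off(generate_fixture("telegraph-mua", duration = 20000,
                                       seed = 24)$data)
  s2 <- state_stats(st)
  expect_equal(sum(s2$t_on) + sum(s2$t_off), 20000)
})

test_that("event theta phases are read off the filtered oscillation", {
  t <- seq_len(30000) / 1000
  x <- sin(2 * pi * 4 * t)         # pure 4 Hz tone
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  ep <- event_theta_phase(continuous_signal(x), peaks[5:90])
  expect_lt(min(abs(c(ep$mean_deg, ep$mean_deg - 360))), 6)
  expect_equal(event_theta_phase(continuous_signal(x), numeric(0))$mean_deg,
               NA_real_)
})
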