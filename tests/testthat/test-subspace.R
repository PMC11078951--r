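test_that("state conditioning removes per-state means exactly", {
  X <- matrix(5L, 40, 6)
  st <- rep(c(TRUE, FALSE), 20)
  fl <- state_conditioned_fluctuations(X, st)
  expect_true(all(fl == 0))
  set.seed(51)
  X2 <- matrix(rnorm(400), 100, 4) + ifelse(rep(runif(100) < 0.5, 4), 3, 0)
  st2 <- rep(c("On", "Off"), 50)
  fl2 <- suppressWarnings(state_conditioned_fluctuations(X2, st2))
  for (s in c("On", "Off"))
    expect_equal(colMeans(fl2[st2 == s, ]), rep(0, 4), tolerance = 1e-12)
})

test_that("state conditioning removes spurious cross-area correlation", {
  # two mean levels shared by both areas inflate correlation when ignored
  set.seed(52)
  n <- 1000
  state <- rep(c(TRUE, FALSE), n / 2)
  lift <- ifelse(state, 4, 0)
  X <- matrix(rnorm(n * 5), n, 5) + lift
  Y <- matrix(rnorm(n * 5), n, 5) + lift
  raw_cor <- mean(abs(cor(X, Y)))
  fl_cor <- mean(abs(cor(state_conditioned_fluctuations(X, state),
                         state_conditioned_fluctuations(Y, state))))
  expect_gt(raw_cor, 0.5)
  expect_lt(fl_cor, 0.1)
})

test_that("ridge regression recovers identity and known coefficient maps", {
  set.seed(53)
  X <- matrix(rnorm(3000), 300, 10)
  f0 <- ridge_fit(X, X, lambda_grid = c(1e-4, 1e-2))
  expect_gt(f0$performance, 0.99)
  expect_equal(unname(f0$B), diag(10), tolerance = 0.01)
  # independent target: out-of-fold performance <= noise level
  Yind <- matrix(rnorm(3000), 300, 10)
  find <- ridge_fit(X, Yind)
  expect_lt(find$performance, 0.05)
  # known B0 at n = 4000: close recovery
  fx <- generate_fixture("low-rank-counts", n = 4000, p = 20, rank = 20,
                         noise_sd = 0.5, seed = 54)
  fr <- ridge_fit(fx$data$X, fx$data$Y, lambda_grid = c(0.1, 1, 10))
  relerr <- norm(fr$B - fx$truth$B0, "F") / norm(fx$truth$B0, "F")
  expect_lt(relerr, 0.1)
})

test_that("reduced-rank regression nests and saturates at the true rank", {
  fx <- generate_fixture("low-rank-counts", n = 2000, p = 30, rank = 3,
                         noise_sd = 1, seed = 55)
  X <- fx$data$X
  Y <- fx$data$Y
  sa <- subspace_analysis(X, Y, m_range = 1:10)
  expect_equal(sa$m_star, 3)
  # full-rank RRR equals the ridge fit exactly
  fr <- ridge_fit(X, Y)
  rr <- reduced_rank_fit(X, Y, m = ncol(Y), lambda = fr$lambda, folds = 0)
  expect_lt(norm(rr$B - fr$B, "F") / norm(fr$B, "F"), 1e-10)
  # training-fold performance is non-decreasing in m (exact nesting)
  perf_tr <- vapply(c(1, 3, 5, 10, 30), function(m)
    reduced_rank_fit(X, Y, m, fr$lambda, folds = 0)$performance, numeric(1))
  expect_true(all(diff(perf_tr) >= -1e-12))
})

test_that("rank recovery succeeds across ranks and repetitions", {
  hits <- 0
  reps <- expand.grid(r = 1:5, i = 1:4)
  for (k in seq_len(nrow(reps))) {
    fx <- generate_fixture("low-rank-counts", n = 1200, p = 20,
                           rank = reps$r[k], noise_sd = 1,
                           seed = 500 + k)
    sa <- subspace_analysis(fx$data$X, fx$data$Y, m_range = 1:8,
                            lambda = 1)
    hits <- hits + (identical(sa$m_star, as.integer(reps$r[k])))
  }
  expect_gte(hits, 18)
})

test_that("the one-SEM lambda rule is reproducible and monotone-curve picks m=1", {
  set.seed(56)
  X <- matrix(rnorm(2000), 200, 10)
  Y <- X %*% diag(10) * 0.9 + 0.1 * matrix(rnorm(2000), 200, 10)
  a <- ridge_fit(X, Y)
  b <- ridge_fit(X, Y)
  expect_identical(a$lambda, b$lambda)
  curve <- data.frame(m = 1:3, performance = c(0.95, 0.96, 0.95),
                      sem = c(0.02, 0.02, 0.02))
  expect_equal(subspace_dimension(curve, 0.96, 0.01), 1L)
})
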