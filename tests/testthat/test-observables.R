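# helper: raster with hand-placed spikes on the full-size geometry
manual_raster <- function(xy, times, geometry = network_geometry(32)) {
  ex <- as.matrix(geometry$exc)
  ids <- apply(matrix(xy, ncol = 2), 1, function(p)
    which(ex[, 1] == p[1] & ex[, 2] == p[2]))
  spike_raster(ids, times, geometry, c(0, max(times) + 10))
}

test_that("center of mass reproduces point masses and symmetry", {
  r <- manual_raster(c(5.5, -3.5), 50)
  com <- center_of_mass(r, times = 50)
  expect_equal(c(com$x, com$y), c(5.5, -3.5))
  # equal masses at opposite points: zero resultant on that axis
  r2 <- manual_raster(rbind(c(16.5, 0.5), c(-15.5, 0.5)), c(50, 50))
  com2 <- center_of_mass(r2, times = 50)
  expect_true(is.na(com2$x))
  expect_equal(com2$y, 0.5)
  # no spikes in window -> undefined, carried as NA
  com3 <- center_of_mass(r, times = 200)
  expect_true(is.na(com3$x))
})

test_that("center of mass handles boundary-crossing clouds correctly", {
  g <- network_geometry(32)
  ex <- as.matrix(g$exc)
  set.seed(77)
  # isotropic Gaussian cloud centered at (30, 30), wrapping the seam
  pts <- cbind(30 + rnorm(500, sd = 3), 30 + rnorm(500, sd = 3))
  pts <- (pts + 32) %% 64 - 32
  snap <- cbind(floor(pts[, 1]) + 0.5, floor(pts[, 2]) + 0.5)
  r <- manual_raster(snap, rep(50, 500))
  com <- center_of_mass(r, times = 50)
  expect_lt(torus_distance(c(com$x, com$y), c(30, 30), 64), 1)
  # brute-force circular-mean oracle on the same points
  oracle <- sapply(1:2, function(z)
    Arg(sum(exp(1i * snap[, z] * pi / 32))) * 32 / pi)
  expect_equal(c(com$x, com$y), oracle, tolerance = 1e-9)
})

test_that("center of mass is equivariant under torus translation", {
  g <- network_geometry(32)
  set.seed(78)
  pts <- cbind(rnorm(300, 10, 4), rnorm(300, -5, 4))
  snap <- cbind(floor(pts[, 1]) + 0.5, floor(pts[, 2]) + 0.5)
  base <- center_of_mass(manual_raster(snap, rep(50, 300)), times = 50)
  for (dv in list(c(7, 0), c(0, -13), c(31, 31))) {
    shifted <- sweep(snap, 2, dv, "+")
    shifted <- (shifted + 32) %% 64 - 32
    com <- center_of_mass(manual_raster(shifted, rep(50, 300)), times = 50)
    expect_lt(torus_distance(c(com$x, com$y),
                             c(base$x + dv[1], base$y + dv[2]), 64), 1e-6)
  }
})

test_that("MUA measures the site group's mean rate", {
  g <- network_geometry(32)
  # silent raster
  r0 <- spike_raster(integer(0), numeric(0), g, c(0, 1000))
  expect_true(all(mua(r0, c(0, 0))$x == 0))
  # homogeneous Poisson at 10 Hz
  fx <- generate_fixture("poisson-raster", rate = 10, duration = 20000,
                         geometry = g, neurons = site_neurons(g, c(0, 0), 5),
                         seed = 3)
  m <- mua(fx$data, c(0, 0), bin = 10)
  expect_equal(mean(m$x), 10, tolerance = 0.05)
  # doubling the spikes doubles the MUA
  r2 <- fx$data
  r2$id <- c(r2$id, r2$id)
  r2$t <- c(r2$t, r2$t)
  m2 <- mua(r2, c(0, 0), bin = 10)
  expect_equal(m2$x, 2 * m$x, tolerance = 1e-12)
})

test_that("LFP proxy weights currents by periodic Gaussian distance", {
  g <- network_geometry(8)
  n_ms <- 100
  cur <- list(I_e_intra = matrix(0, n_ms, 2), I_e_inter = matrix(0, n_ms, 2),
              I_i_intra = matrix(0, n_ms, 2), neurons = c(1L, 2L))
  expect_equal(lfp_proxy(cur, g, c(0, 0))$x, rep(0, n_ms))
  cur$I_e_intra[, 1] <- 1
  d <- torus_distance(as.matrix(g$exc[1, ]), c(0, 0), g$L)
  lfp <- lfp_proxy(cur, g, c(0, 0), sigma_lfp = 7)
  expect_equal(lfp$x, rep(exp(-d^2 / 98), n_ms), tolerance = 1e-12)
  # linearity: scaling currents scales the proxy
  cur2 <- cur
  cur2$I_e_intra <- 3 * cur$I_e_intra
  expect_equal(lfp_proxy(cur2, g, c(0, 0))$x, 3 * lfp$x)
  expect_error(lfp_proxy(NULL, g, c(0, 0)), "without current")
})

test_that("narrowband phase tracks a pure tone and rejects bad bands", {
  t <- seq_len(4000) / 1000
  x <- sin(2 * pi * 50 * t)
  ph <- narrowband_phase(x, c(45, 55))$phase
  # unwrap-linear advance of 2*pi*50 per second
  dp <- diff(ph[500:3500])
  dp <- (dp + pi) %% (2 * pi) - pi
  expect_equal(mean(dp) * 1000 / (2 * pi), 50, tolerance = 1e-3)
  expect_error(narrowband_phase(x, c(400, 600)), "Nyquist")
  # independent white-noise channels: phase differences uniform
  set.seed(9)
  p1 <- narrowband_phase(rnorm(20000), c(35, 45))$phase
  p2 <- narrowband_phase(rnorm(20000), c(35, 45))$phase
  dphi <- ((p1 - p2 + pi) %% (2 * pi)) - pi
  # subsample beyond the filter's correlation time so the KS test sees
  # approximately independent draws
  ks <- suppressWarnings(stats::ks.test(dphi[seq(1, 20000, by = 100)],
                                        "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
})
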