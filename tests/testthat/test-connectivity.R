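test_that("connection probability follows P0 * exp(-d / tau_P)", {
  # direct evaluation at d = 0 and d = tau_P for every class
  rule <- connectivity_rule()
  p_of <- function(P0, tauP, d) P0 * exp(-d / tauP)
  expect_equal(p_of(0.8057, 7.5, 0), 0.8057)
  for (i in seq_len(nrow(rule$classes))) {
    cl <- rule$classes[i, ]
    expect_equal(p_of(cl$P0, cl$tau_P, cl$tau_P), cl$P0 / exp(1))
  }

  # empirical connection frequency per distance bin on >= 1e5 sampled pairs
  g <- network_geometry(16)
  ex <- as.matrix(g$exc)
  pr <- wavecomm:::.sample_pairs(ex[, 1], ex[, 2], ex[, 1], ex[, 2],
                                 0.8057, 7.5, g$L, rep(TRUE, nrow(ex)),
                                 TRUE, 99)
  d <- torus_distance(ex[pr$pre, ], ex[pr$post, ], g$L)
  # count all candidate pairs per distance bin via the distance distribution
  # of the full lattice relative to one reference neuron (translation
  # invariance of the torus)
  d_all <- torus_distance(ex, matrix(ex[1, ], nrow(ex), 2, byrow = TRUE), g$L)
  brk <- c(0.5, 3, 6, 9, 12, 16)
  for (b in seq_len(length(brk) - 1)) {
    n_pairs <- sum(d_all > brk[b] & d_all <= brk[b + 1]) * nrow(ex)
    n_conn <- sum(d > brk[b] & d <= brk[b + 1])
    d_mid <- (brk[b] + brk[b + 1]) / 2
    # representative probability over the bin (average over actual distances)
    sel <- d_all > brk[b] & d_all <= brk[b + 1]
    p_exp <- mean(0.8057 * exp(-d_all[sel] / 7.5))
    ci <- stats::qbinom(c(0.005, 0.995), n_pairs, p_exp)
    expect_gte(n_conn, ci[1])
    expect_lte(n_conn, ci[2])
  }
})

test_that("sampled network reproduces the printed mean indegrees", {
  g <- cached("full_geom", network_geometry(32))
  syn <- cached("full_conn", sample_connectivity(g, connectivity_rule(),
                                                 seed = 1))
  kin <- function(cls, n_post, off = 0) {
    mean(tabulate(syn$post[syn$class == cls] - off, n_post))
  }
  expect_equal(kin("e1e1", g$N_e), 270, tolerance = 0.03)
  expect_equal(kin("e1i1", g$N_i, g$offset[["i1"]]), 350, tolerance = 0.03)
  expect_equal(kin("i1e1", g$N_e), 130, tolerance = 0.03)
  expect_equal(kin("i1i1", g$N_i, g$offset[["i1"]]), 180, tolerance = 0.03)
})

test_that("per-neuron mean weight scales as J / sqrt(indegree)", {
  g <- cached("full_geom", network_geometry(32))
  syn <- cached("full_conn", sample_connectivity(g, connectivity_rule(),
                                                 seed = 1))
  sel <- syn$class == "e1e1"
  K <- tabulate(syn$post[sel], g$N_e)
  wbar <- tapply(syn$weight[sel], syn$post[sel], mean)
  K <- K[as.integer(names(wbar))]
  # w_j * sqrt(K_j) should be constant (= J) up to the 5% weight CV
  j_hat <- wbar * sqrt(K)
  expect_lt(stats::sd(j_hat) / mean(j_hat), 0.02)
  # and the class-wide mean weight equals the prescribed overall mean
  expect_equal(mean(syn$weight[sel]), 7.857, tolerance = 0.01)
  # interareal weights are drawn around the fixed printed mean
  expect_equal(mean(syn$weight[syn$class == "e1e2"]), 3.656, tolerance = 0.01)
  expect_equal(mean(syn$weight[syn$class == "e2e1"]), 0.578, tolerance = 0.01)
})

test_that("interareal sources are a designated excitatory half", {
  g <- cached("full_geom", network_geometry(32))
  syn <- cached("full_conn", sample_connectivity(g, connectivity_rule(),
                                                 seed = 1))
  lab <- wavecomm:::geometry_labels(g)
  inter <- syn$class %in% c("e1e2", "e1i2", "e2e1", "e2i1")
  expect_true(all(lab$type[syn$pre[inter]] == "e"))
  src1 <- unique(syn$pre[syn$class %in% c("e1e2", "e1i2")])
  expect_lte(length(src1), g$N_e / 2)
  expect_true(all(src1 %in% attr(syn, "sources")$e1))
  # weights non-negative everywhere
  expect_true(all(syn$weight >= 0))
})

test_that("empty geometry and disconnection behave as identities", {
  expect_length(wavecomm:::empty_synapse_table(), 0)
  nw <- small_net()
  syn0 <- disconnect_interareal(nw$syn, "both")
  expect_false(any(syn0$class %in% c("e1e2", "e1i2", "e2e1", "e2i1")))
  expect_equal(sum(nw$syn$class %in% c("e1e1", "i1i1")),
               sum(syn0$class %in% c("e1e1", "i1i1")))
  ff <- disconnect_interareal(nw$syn, "bottom-up")
  expect_false(any(ff$class %in% c("e1e2", "e1i2")))
  expect_true(any(ff$class == "e2e1"))
  expect_error(disconnect_interareal(nw$syn, "sideways"))
})

test_that("degenerate connectivity parameters raise configuration errors", {
  g <- network_geometry(8)
  bad <- connectivity_rule()
  bad$classes$tau_P[1] <- -1
  expect_error(sample_connectivity(g, bad, seed = 1), "decay")
})
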