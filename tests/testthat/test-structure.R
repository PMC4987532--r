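test_that("NODF hits its closed forms and matches the pairwise-loop oracle", {
  expect_equal(nodf(nested_triangle()), 100)
  expect_equal(nodf(perfect_matching(2)), 0)  # checkerboard: no overlap

  # equal-fill pairs contribute zero: verify against the brute-force oracle
  m_eq <- matrix(c(1, 1, 0,
                   0, 1, 1,
                   1, 0, 0), 3, 3, byrow = TRUE,
                 dimnames = list(paste0("h", 1:3), paste0("p", 1:3)))
  expect_equal(nodf(coext:::network_from_matrix(m_eq)), nodf_oracle(m_eq))

  for (s in 1:8) {
    net <- random_network(sample(4:8, 1), sample(4:8, 1), seed = 600 + s)
    m <- incidence_matrix(net)
    expect_equal(nodf(net), nodf_oracle(m), tolerance = 1e-9)
    # invariant to simultaneous row/column permutation
    mp <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(nodf(coext:::network_from_matrix(mp)), nodf(net), tolerance = 1e-9)
  }
})

test_that("Barber modularity recovers block structure and the complete-network zero", {
  b2 <- blocks_network(2)
  r2 <- bipartite_modularity(b2, seed = 1)
  expect_equal(r2$q, 0.5, tolerance = 1e-9)
  # the two blocks are the modules
  mods <- r2$modules
  expect_length(unique(mods[paste0("h1_", 1:3)]), 1L)
  expect_length(unique(mods[paste0("h2_", 1:3)]), 1L)
  expect_false(mods[["h1_1"]] == mods[["h2_1"]])
  expect_equal(mods[["h1_1"]], mods[["p1_1"]])

  expect_equal(bipartite_modularity(blocks_network(4, 2, 2), seed = 1)$q, 0.75,
               tolerance = 1e-9)
  expect_equal(bipartite_modularity(complete_bipartite(4, 5), seed = 1)$q, 0,
               tolerance = 1e-9)

  # reported Q always matches the definitional double-loop on the returned
  # partition, and never falls below the single-module floor of 0
  for (s in 1:6) {
    net <- random_network(6, 7, seed = 700 + s)
    r <- bipartite_modularity(net, seed = s, n_restarts = 10)
    m <- incidence_matrix(net)
    expect_equal(r$q, barber_q_oracle(m, r$modules[net$hosts], r$modules[net$parasites]),
                 tolerance = 1e-9)
    expect_gte(r$q, 0)
  }
})

test_that("C-score matches hand values and the double-loop oracle", {
  expect_equal(c_score(perfect_matching(2)), 1)
  # identical host sets contribute zero checkerboards
  same <- bipartite_network(data.frame(host = c("h1", "h2", "h1", "h2"),
                                       parasite = c("p1", "p1", "p2", "p2")))
  expect_equal(c_score(same), 0)
  for (s in 1:6) {
    net <- random_network(5, 5, seed = 800 + s)
    expect_equal(c_score(net), c_score_oracle(incidence_matrix(net)), tolerance = 1e-12)
  }
})

test_that("curveball nulls preserve both degree sequences on every draw", {
  for (s in 1:4) {
    net <- random_network(sample(5:9, 1), sample(5:9, 1), seed = 850 + s)
    m <- incidence_matrix(net)
    nulls <- coext:::curveball_nulls(m, n_nulls = 25, n_swaps = 5 * sum(m), seed = s)
    for (nm in nulls) {
      expect_equal(rowSums(nm), rowSums(m))
      expect_equal(colSums(nm), colSums(m))
    }
  }
})

test_that("null z-scores behave: degenerate nulls flagged, nestedness detected", {
  # complete bipartite: the only degree-preserving matrix is itself
  nz <- null_z(complete_bipartite(4, 4), "nodf", n_nulls = 20, seed = 1)
  expect_false(nz$defined)
  expect_true(is.na(nz$z))
  expect_error(null_z(toy2(), "nodf", n_nulls = 5, seed = 1), "n_nulls")

  # a perfectly nested (prefix-row) matrix is the unique realization of its
  # degree sequences, so its curveball null is degenerate too — and flagged
  nz2 <- null_z(nested_triangle(), "nodf", n_nulls = 20, seed = 2)
  expect_false(nz2$defined)

  # a strongly nested network: NODF z > 0 in nearly all seeded runs
  nested <- noisy_nested()
  zs <- vapply(1:10, function(s) null_z(nested, "nodf", n_nulls = 60, seed = s)$z,
               numeric(1))
  expect_gte(sum(zs > 0), 9L)

  # determinism
  expect_equal(null_z(nested, "c_score", n_nulls = 20, seed = 3),
               null_z(nested, "c_score", n_nulls = 20, seed = 3))
})

test_that("robustness-structure correlations detect monotone links and flag constants", {
  df <- data.frame(auc = seq(0.4, 0.9, length.out = 10),
                   connectance = seq(0.1, 0.5, length.out = 10),  # monotone with auc
                   const = rep(0.3, 10))
  out <- robustness_vs_structure(df)
  expect_equal(out$rho[out$property == "connectance"], 1)
  expect_false(out$defined[out$property == "const"])
  expect_true(is.na(out$rho[out$property == "const"]))
  expect_error(robustness_vs_structure(df[1:3, ]), ">= 5")

  # permutation null: a shuffled property shows no association
  prop <- coext:::with_seed(1, sample(seq_len(200)))
  df2 <- data.frame(auc = seq_len(200) / 200, shuffled = prop)
  out2 <- robustness_vs_structure(df2)
  expect_lt(abs(out2$rho[out2$property == "shuffled"]), 0.25)
})
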