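test_that("the 2-host worked example produces the hand-derived curves and AUCs", {
  net <- toy2()
  c12 <- disassemble(net, c("h1", "h2"))
  c21 <- disassemble(net, c("h2", "h1"))
  expect_equal(c12$parasites_frac, c(1, 0.5, 0))
  expect_equal(c21$parasites_frac, c(1, 1, 0))
  expect_equal(robustness_auc(c12), 0.5)
  expect_equal(robustness_auc(c21), 0.75)
  expect_valid_curve(c12); expect_valid_curve(c21)
})

test_that("closed-form AUCs: diagonal for matchings, 1 - 1/(2H) for complete networks", {
  for (H in c(3, 5, 8)) {
    pm <- perfect_matching(H)
    ord <- coext:::with_seed(H, sample(pm$hosts))
    cv <- disassemble(pm, ord)
    expect_equal(cv$parasites_frac, seq(H, 0) / H)  # diagonal
    expect_equal(robustness_auc(cv), 0.5)
  }
  for (H in c(4, 10)) {
    cb <- complete_bipartite(H, 3)
    ord <- coext:::with_seed(H, sample(cb$hosts))
    cv <- disassemble(cb, ord)
    expect_equal(cv$parasites_frac, c(rep(1, H), 0))
    expect_equal(robustness_auc(cv), 1 - 1 / (2 * H))
  }
})

test_that("disassembly validates its inputs", {
  net <- toy2()
  expect_error(disassemble(net, c("h1", "h1")), "permutation")
  expect_error(disassemble(net, "h1"), "permutation")
  expect_error(disassemble(net, c("h1", "hX")), "permutation")
  only_hosts <- bipartite_network(data.frame(host = "h1", parasite = "p1"))
  only_hosts$parasites <- character(0)
  only_hosts$edges <- only_hosts$edges[0, ]
  expect_error(disassemble(only_hosts, "h1"), "no parasites")
})

test_that("curves are monotone and AUC in [0,1] on random networks and orders", {
  for (s in 1:15) {
    net <- random_network(sample(4:10, 1), sample(3:12, 1), fill = runif(1, 0.2, 0.7),
                          seed = 200 + s)
    ord <- removal_order(net, "random", seed = s)
    cv <- disassemble(net, ord)
    expect_valid_curve(cv)
    auc <- robustness_auc(cv)
    expect_gte(auc, 0); expect_lte(auc, 1)
  }
})

test_that("best/worst orders are forced by degrees on the toy and tie-randomized otherwise", {
  net <- toy2()  # h1 has 2 parasites, h2 has 1
  for (s in 1:5) {
    expect_equal(as.character(removal_order(net, "best", seed = s)), c("h2", "h1"))
    expect_equal(as.character(removal_order(net, "worst", seed = s)), c("h1", "h2"))
  }
  # all-ties: each of the 6 permutations of a complete 3x3 appears ~ 1/6
  cb <- complete_bipartite(3, 3)
  perms <- vapply(1:1200, function(s) {
    paste(as.character(removal_order(cb, "best", seed = s)), collapse = "")
  }, character(1))
  counts <- table(perms)
  expect_length(counts, 6L)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("score-ranked orders follow the direction flag deterministically", {
  net <- toy2()
  hi <- score_table(c(h1 = 0.9, h2 = 0.1))
  lo <- score_table(c(h1 = 0.9, h2 = 0.1), higher_is_vulnerable = FALSE)
  for (s in 1:5) {
    expect_equal(as.character(removal_order(net, "by_score", scores = hi, seed = s)),
                 c("h1", "h2"))
    expect_equal(as.character(removal_order(net, "by_score", scores = lo, seed = s)),
                 c("h2", "h1"))
  }
  expect_error(removal_order(net, "by_score", seed = 1), "score table")
  expect_error(removal_order(net, "by_score", scores = score_table(c(h1 = 1)), seed = 1),
               "h2")
})

test_that("greedy and static best-case coincide without parasite overlap, differ with it", {
  # disjoint parasite sets: recomputation changes nothing
  pm <- perfect_matching(6)
  for (s in 1:5) {
    expect_equal(as.character(removal_order(pm, "best", seed = s, recompute = "static")),
                 as.character(removal_order(pm, "best", seed = s, recompute = "greedy")))
  }
  # shared parasites: greedy worst re-ranks after extinctions; both stay valid
  for (s in 1:5) {
    net <- random_network(7, 9, seed = 300 + s)
    for (mode in c("static", "greedy")) {
      ord <- removal_order(net, "worst", seed = s, recompute = mode)
      expect_setequal(as.character(ord), net$hosts)
    }
  }
})

test_that("replicate robustness aggregates curves, AUCs and bootstrap bands", {
  net <- toy2()
  rs <- replicate_robustness(net, "random", n_replicates = 2000, seed = 7, n_boot = 200)
  # exhaustive mean over both orders is (0.75 + 0.5)/2
  expect_lt(abs(rs$auc_mean - 0.625), 0.01)
  expect_true(all(rs$ci_low <= rs$mean_curve + 1e-12))
  expect_true(all(rs$ci_high >= rs$mean_curve - 1e-12))
  expect_true(all(rs$auc_values >= 0 & rs$auc_values <= 1))

  # strict scores, no ties: every replicate identical, sd = 0
  net2 <- random_network(6, 8, seed = 11)
  sc <- score_table(stats::setNames(seq_len(6), net2$hosts))
  rs2 <- replicate_robustness(net2, "by_score", scores = sc, n_replicates = 20, seed = 1)
  expect_equal(rs2$auc_sd, 0)
  expect_equal(length(unique(rs2$auc_values)), 1L)

  # complete bipartite: every scenario forced to 1 - 1/(2H), bands collapse
  cb <- complete_bipartite(5, 4)
  for (sc_name in c("best", "worst", "random")) {
    rs3 <- replicate_robustness(cb, sc_name, n_replicates = 30, seed = 2, n_boot = 50)
    expect_equal(rs3$auc_values, rep(1 - 1 / 10, 30))
    expect_equal(rs3$ci_low, rs3$mean_curve)
    expect_equal(rs3$ci_high, rs3$mean_curve)
  }

  # determinism of the whole summary
  expect_identical(replicate_robustness(net2, "random", n_replicates = 50, seed = 5),
                   replicate_robustness(net2, "random", n_replicates = 50, seed = 5))
})

test_that("exhaustive oracle matches hand values, the closed form, and Monte Carlo", {
  expect_equal(expected_random_auc_exhaustive(toy2()), 0.625)
  expect_equal(expected_random_auc_exhaustive(perfect_matching(4)), 0.5)
  expect_error(expected_random_auc_exhaustive(perfect_matching(9)), "Monte Carlo")

  for (s in 1:6) {
    net <- random_network(sample(3:6, 1), sample(3:8, 1), seed = 400 + s)
    ex <- expected_random_auc_exhaustive(net)
    expect_equal(ex, closed_form_random_auc(net), tolerance = 1e-12)
    mc <- replicate_robustness(net, "random", n_replicates = 3000, seed = s, n_boot = 0)
    se <- sd(mc$auc_values) / sqrt(3000)
    expect_lt(abs(mc$auc_mean - ex), 3.5 * se + 1e-9)
  }
})
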