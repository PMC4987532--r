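test_that("construction enforces the network invariants", {
  net <- toy2()
  expect_s3_class(net, "bipartite_network")
  expect_equal(n_hosts(net), 2L)
  expect_equal(n_parasites(net), 2L)
  expect_equal(n_edges(net), 3L)

  # duplicate edges are a loud error naming the pair
  expect_error(
    bipartite_network(data.frame(host = c("h1", "h1"), parasite = c("p1", "p1"))),
    "duplicate edge.*h1.*p1")
  expect_error(bipartite_network(data.frame(host = character(), parasite = character())),
               "empty edge set")
  # hosts and parasites must be disjoint identifier sets
  expect_error(
    bipartite_network(data.frame(host = c("a", "b"), parasite = c("b", "c"))),
    "both as host and as parasite")
  # a parasite cannot be declared without an edge
  expect_error(
    bipartite_network(data.frame(host = "h1", parasite = "p1"), parasites = c("p1", "p2")),
    "absent from the edge list")
})

test_that("degree-0 hosts are representable and summaries are as defined", {
  net <- bipartite_network(data.frame(host = c("h1", "h1", "h2"),
                                      parasite = c("p1", "p2", "p2")),
                           hosts = c("h1", "h2", "h3"))
  expect_equal(n_hosts(net), 3L)
  expect_equal(unname(host_degrees(net)["h3"]), 0L)
  s <- summary(net)
  expect_equal(s$connectance, 3 / (3 * 2))

  expect_equal(summary(complete_bipartite(2, 3))$connectance, 1)
  expect_equal(summary(perfect_matching(5))$connectance, 0.2)
  expect_equal(summary(toy2())$connectance, 0.75)
})

test_that("edge-list reader honours column names, extra hosts and errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("host,parasite", "h1,p1", "h1,p2", "h2,p2"), f)
  net <- read_edge_list(f)
  expect_equal(n_hosts(net), 2L); expect_equal(n_parasites(net), 2L)
  expect_equal(n_edges(net), 3L)
  expect_equal(net$hosts, c("h1", "h2"))  # first-appearance order

  net3 <- read_edge_list(f, extra_hosts = "h3")
  expect_equal(n_hosts(net3), 3L)
  expect_equal(unname(host_degrees(net3)["h3"]), 0L)

  fdup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("host,parasite", "h1,p1", "h1,p1"), fdup)
  expect_error(read_edge_list(fdup), "duplicate edge")

  expect_error(read_edge_list(f, extra_hosts = "p1"), "used as parasite")
  expect_error(read_edge_list(f, host_column = "nope"), "column 'nope'")

  fsemi <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fish;worm", "h1;p1"), fsemi)
  expect_equal(n_edges(read_edge_list(fsemi, "fish", "worm", sep = ";")), 1L)
})

test_that("adjacency reader accepts binary matrices and rejects bad cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("host\tp1\tp2", "h1\t1\t0", "h2\t0\t1"), f)
  net <- read_adjacency_matrix(f)
  expect_equal(n_edges(net), 2L)
  expect_equal(sort(as.integer(parasite_degrees(net))), c(1L, 1L))

  fbad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("host\tp1", "h1\t2"), fbad)
  expect_error(read_adjacency_matrix(fbad), "non-binary")

  fzero <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("host\tp1\tp2", "h1\t1\t0", "h2\t1\t0"), fzero)
  expect_error(read_adjacency_matrix(fzero), "all-zero parasite")
})

test_that("writers round-trip hosts, parasites and edges exactly", {
  nets <- list(toy2(),
               random_network(7, 9, seed = 4),
               bipartite_network(data.frame(host = "h1", parasite = "p1"),
                                 hosts = c("h1", "h0")))  # degree-0 host
  for (net in nets) {
    fe <- withr::local_tempfile(fileext = ".csv")
    paths <- write_network(net, fe, "edge_list")
    back <- read_edge_list(fe, node_file = if (length(paths) > 1) paths[2] else NULL)
    expect_equal(back$hosts, net$hosts)
    expect_equal(back$parasites, net$parasites)
    expect_equal(back$edges[order(back$edges$host, back$edges$parasite), ],
                 net$edges[order(net$edges$host, net$edges$parasite), ],
                 ignore_attr = TRUE)

    fa <- withr::local_tempfile(fileext = ".tsv")
    write_network(net, fa, "adjacency")
    back2 <- read_adjacency_matrix(fa)
    expect_equal(incidence_matrix(back2), incidence_matrix(net))
  }
})

test_that("subsampling keeps round(f*E) edges, drops empty parasites, keeps hosts", {
  net <- random_network(6, 8, seed = 2)
  expect_identical(subsample_interactions(net, 1, seed = 1), net)

  cb <- complete_bipartite(3, 3)
  sub <- subsample_interactions(cb, 4 / 9, seed = 7)
  expect_equal(n_edges(sub), 4L)
  expect_lte(n_parasites(sub), 3L)
  expect_equal(n_hosts(sub), 3L)  # hosts retained even at degree 0
  expect_true(all(parasite_degrees(sub) >= 1L))

  # a single-edge parasite disappears when its edge is dropped
  for (s in 1:20) {
    sm <- subsample_interactions(toy2(), 1 / 3, seed = s)
    expect_equal(n_edges(sm), 1L)
    expect_true(all(parasite_degrees(sm) >= 1L))
  }

  expect_error(subsample_interactions(net, 0, seed = 1), "keep_fraction")
  expect_error(subsample_interactions(net, 1.2, seed = 1), "keep_fraction")

  # property: exact edge count and parasite invariant on random networks
  for (s in 1:10) {
    n2 <- random_network(8, 10, seed = 100 + s)
    f <- runif(1, 0.3, 0.9)
    sb <- subsample_interactions(n2, f, seed = s)
    expect_equal(n_edges(sb), round(f * n_edges(n2)))
    expect_true(all(parasite_degrees(sb) >= 1L))
    expect_true(summary(sb)$connectance >= 0 && summary(sb)$connectance <= 1)
  }
  # determinism
  expect_identical(subsample_interactions(net, 0.5, seed = 3),
                   subsample_interactions(net, 0.5, seed = 3))
})
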