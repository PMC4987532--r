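# Fixture builders (all generated in code) and independent brute-force
# oracles used to cross-check the package implementations.

# The 2-host worked example: h1 carries parasites A and B, h2 carries B only.
toy2 <- function() {
  bipartite_network(data.frame(host = c("h1", "h1", "h2"),
                               parasite = c("A", "B", "B")))
}

perfect_matching <- function(n) {
  bipartite_network(data.frame(host = sprintf("h%d", 1:n),
                               parasite = sprintf("p%d", 1:n)))
}

complete_bipartite <- function(h, p) {
  bipartite_network(expand.grid(host = sprintf("h%d", 1:h),
                                parasite = sprintf("p%d", 1:p),
                                stringsAsFactors = FALSE))
}

# perfectly nested 3x3 triangle: host rows 111 / 110 / 100
nested_triangle <- function() {
  bipartite_network(data.frame(
    host = c("h1", "h1", "h1", "h2", "h2", "h3"),
    parasite = c("p1", "p2", "p3", "p1", "p2", "p1")))
}

# m disconnected complete-bipartite blocks of a hosts x b parasites each
blocks_network <- function(m, a = 3, b = 3) {
  edges <- do.call(rbind, lapply(seq_len(m), function(i) {
    expand.grid(host = sprintf("h%d_%d", i, seq_len(a)),
                parasite = sprintf("p%d_%d", i, seq_len(b)),
                stringsAsFactors = FALSE)
  }))
  bipartite_network(edges)
}

# random valid network: every parasite guaranteed >= 1 host
random_network <- function(H, P, fill = 0.4, seed = 1) {
  m <- coext:::with_seed(seed, {
    m <- matrix(rbinom(H * P, 1, fill), H, P)
    empty <- which(colSums(m) == 0)
    for (j in empty) m[sample.int(H, 1), j] <- 1L
    m
  })
  dimnames(m) <- list(sprintf("h%d", 1:H), sprintf("p%d", 1:P))
  idx <- which(m == 1, arr.ind = TRUE)
  bipartite_network(data.frame(host = rownames(m)[idx[, 1]],
                               parasite = colnames(m)[idx[, 2]]),
                    hosts = rownames(m))
}

# --- independent oracles ---------------------------------------------------

# NODF by the definitional double loop over row pairs and column pairs.
nodf_oracle <- function(m) {
  pair_sum <- function(mm) {
    n <- nrow(mm); fills <- rowSums(mm)
    tot <- 0
    for (i in seq_len(n - 1)) for (k in (i + 1):n) {
      hi <- which(fills[c(i, k)] == max(fills[i], fills[k]))[1]
      a <- if (hi == 1) i else k; b <- if (hi == 1) k else i
      if (fills[a] > fills[b] && fills[b] > 0) {
        tot <- tot + 100 * sum(mm[a, ] & mm[b, ]) / fills[b]
      }
    }
    tot
  }
  npairs <- choose(nrow(m), 2) + choose(ncol(m), 2)
  unname((pair_sum(m) + pair_sum(t(m))) / npairs)
}

# strongly (not perfectly) nested 8x8 fixture: a nested band with tied
# degrees and two displaced cells, so the degree sequences admit multiple
# realizations (curveball can mix) while the observed overlap stays above
# what the margins alone imply
noisy_nested <- function() {
  m <- matrix(0L, 8, 8, dimnames = list(sprintf("h%d", 1:8), sprintf("p%d", 1:8)))
  deg <- c(6, 6, 5, 5, 3, 3, 2, 2)
  for (i in 1:8) m[i, seq_len(deg[i])] <- 1L
  m[2, 6] <- 0L; m[2, 7] <- 1L
  m[4, 5] <- 0L; m[4, 8] <- 1L
  coext:::network_from_matrix(m)
}

# C-score by explicit double loop over parasite pairs.
c_score_oracle <- function(m) {
  P <- ncol(m); vals <- c()
  for (a in seq_len(P - 1)) for (b in (a + 1):P) {
    S <- sum(m[, a] & m[, b])
    vals <- c(vals, (sum(m[, a]) - S) * (sum(m[, b]) - S))
  }
  mean(vals)
}

# Barber Q of a given partition straight from the definition (double loop).
barber_q_oracle <- function(m, host_mod, par_mod) {
  E <- sum(m); k <- rowSums(m); d <- colSums(m)
  q <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (host_mod[i] == par_mod[j]) q <- q + (m[i, j] - k[i] * d[j] / E) / E
  }
  unname(q)
}

# Exact expected random-removal AUC without enumeration: a parasite with
# host range g is extinct after k removals with probability C(k,g)/C(H,g),
# and the AUC is linear in the expected curve.
closed_form_random_auc <- function(net) {
  H <- n_hosts(net)
  g <- parasite_degrees(net)
  y <- vapply(0:H, function(k) mean(1 - choose(k, g) / choose(H, g)), numeric(1))
  sum((y[-1] + y[-length(y)]) / 2) / H
}

expect_valid_curve <- function(curve) {
  y <- curve$parasites_frac
  expect_equal(curve$hosts_frac, seq(length(y) - 1, 0) / (length(y) - 1))
  expect_equal(y[1], 1)
  expect_equal(y[length(y)], 0)
  expect_true(all(diff(y) <= 0))
  expect_true(all(y >= 0 & y <= 1))
}
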