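# Structure metrics (NODF, Barber bipartite modularity, C-score) and
# curveball fixed-degree null models.

#' NODF nestedness of a bipartite network
#'
#' Standard NODF (nestedness metric based on overlap and decreasing fill):
#' for every ordered pair of rows whose fills strictly decrease, the paired
#' overlap is the percentage of the poorer row's interactions shared with
#' the richer row; pairs with equal fills contribute 0. Same over column
#' pairs; NODF is the mean over all row and column pairs, on a 0-100 scale.
#' Computation is delegated to [vegan::nestednodf()].
#'
#' @param net a [bipartite_network()] with >= 2 hosts and >= 2 parasites.
#' @return NODF in \eqn{[0, 100]}.
#' @export
nodf <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (n_hosts(net) < 2L || n_parasites(net) < 2L) {
    stopf("NODF needs >= 2 hosts and >= 2 parasites")
  }
  nodf_matrix(incidence_matrix(net))
}

nodf_matrix <- function(m) {
  # order = TRUE: canonical NODF sorts rows/columns by fill, making the
  # metric invariant to the storage order of the matrix
  unname(vegan::nestednodf(m, order = TRUE, weighted = FALSE)$statistic["NODF"])
}

#' Barber bipartite modularity
#'
#' Maximizes Barber's bipartite modularity
#' \deqn{Q = \frac{1}{E} \sum_{i,j:\, c_i = c_j} \left(A_{ij} - \frac{k_i d_j}{E}\right)}
#' over joint module assignments of hosts and parasites, using an
#' alternating label-optimization heuristic (BRIM-style) with seeded random
#' restarts plus one deterministic restart from the connected components.
#' Exact maximization is NP-hard; the heuristic is adequate for
#' ensemble-level comparisons and recovers the exact optimum on cleanly
#' modular networks.
#'
#' @param net a [bipartite_network()] with >= 1 edge.
#' @param seed integer seed for restarts and tie-breaking.
#' @param n_restarts random restarts in addition to the component-based one.
#' @return a list with `q` (the best modularity found, in \eqn{[-1, 1]}) and
#'   `modules`, a named integer vector over hosts and parasites.
#' @export
bipartite_modularity <- function(net, seed = 1, n_restarts = 20) {
  stopifnot(inherits(net, "bipartite_network"))
  if (n_edges(net) < 1L) stopf("modularity needs at least one edge")
  res <- modularity_matrix(incidence_matrix(net), seed = seed, n_restarts = n_restarts)
  names(res$host_modules) <- net$hosts
  names(res$parasite_modules) <- net$parasites
  list(q = res$q, modules = c(res$host_modules, res$parasite_modules))
}

barber_q <- function(A, k, d, E, lh, lp) {
  labs <- sort(unique(c(lh, lp)))
  q <- 0
  for (m in labs) {
    hi <- lh == m; pj <- lp == m
    if (!any(hi) || !any(pj)) next
    q <- q + sum(A[hi, pj, drop = FALSE]) / E -
      sum(k[hi]) * sum(d[pj]) / E^2
  }
  q
}

modularity_matrix <- function(A, seed = 1, n_restarts = 20) {
  H <- nrow(A); P <- ncol(A)
  k <- rowSums(A); d <- colSums(A); E <- sum(A)
  B <- A - outer(k, d) / E
  assign_best <- function(scores) {
    # scores: (n x labels) matrix; argmax per row, first max wins (label
    # order is itself randomized per restart, so ties are seed-random)
    max.col(scores, ties.method = "first")
  }
  refine <- function(lh) {
    # alternating greedy label optimization; each half-step is the exact
    # argmax given the other side, so Q is non-decreasing
    best <- list(q = -Inf, lh = lh, lp = rep(1L, P))
    repeat {
      labs <- sort(unique(lh))
      S <- rowsum(B, group = lh)                # labels x P (host-side sums)
      lp <- labs[assign_best(t(S))]
      labs2 <- sort(unique(lp))
      S2 <- rowsum(t(B), group = lp)            # labels x H
      lh <- labs2[assign_best(t(S2))]
      q <- barber_q(A, k, d, E, lh, lp)
      if (q <= best$q + 1e-12) break
      best <- list(q = q, lh = lh, lp = lp)
    }
    best
  }
  # restart 1: connected components (exact for disconnected block structure)
  comp <- components_bipartite(A)
  best <- refine(comp$host)
  if (n_restarts > 0) {
    seeds <- child_seeds(seed, n_restarts, stream = 3L)
    cmax <- max(2L, min(H, P))
    for (r in seq_len(n_restarts)) {
      init <- with_seed(seeds[r], sample.int(sample.int(cmax, 1L), H, replace = TRUE))
      cand <- refine(init)
      if (cand$q > best$q) best <- cand
    }
  }
  # single-module partition is always admissible: Q = 0 floor
  if (best$q < 0) {
    best <- list(q = barber_q(A, k, d, E, rep(1L, H), rep(1L, P)),
                 lh = rep(1L, H), lp = rep(1L, P))
  }
  labs <- unique(c(best$lh, best$lp))
  list(q = best$q,
       host_modules = match(best$lh, labs),
       parasite_modules = match(best$lp, labs))
}

# connected components of the bipartite graph, labels per host and parasite
components_bipartite <- function(A) {
  H <- nrow(A); P <- ncol(A)
  lh <- integer(H); lp <- integer(P)
  cid <- 0L
  for (s in seq_len(H)) {
    if (lh[s] != 0L) next
    cid <- cid + 1L
    qh <- s
    while (length(qh)) {
      newh <- qh[lh[qh] == 0L]
      lh[newh] <- cid
      pj <- which(colSums(A[newh, , drop = FALSE]) > 0 & lp == 0L)
      lp[pj] <- cid
      qh <- which(rowSums(A[, pj, drop = FALSE]) > 0 & lh == 0L)
    }
  }
  list(host = lh, parasite = lp)
}

#' C-score (checkerboard segregation) of the parasite assemblage
#'
#' Mean number of checkerboard units over all parasite pairs:
#' \eqn{(r_a - S)(r_b - S)} where \eqn{r_a, r_b} are the two parasites' host
#' ranges and \eqn{S} the number of hosts they share. High values mean
#' parasites segregate (minimize partner overlap); identical host sets give
#' 0 for that pair.
#'
#' @param net a [bipartite_network()] with >= 2 parasites.
#' @return mean checkerboard units, >= 0.
#' @export
c_score <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (n_parasites(net) < 2L) stopf("C-score needs >= 2 parasites")
  c_score_matrix(incidence_matrix(net))
}

c_score_matrix <- function(m) {
  S <- crossprod(m)            # shared hosts, parasites x parasites
  r <- colSums(m)
  P <- length(r)
  CU <- (matrix(r, P, P) - S) * (matrix(r, P, P, byrow = TRUE) - S)
  mean(CU[upper.tri(CU)])
}

#' Curveball null-model z-score for a structure metric
#'
#' Generates `n_nulls` degree-preserving randomizations of the network by
#' curveball trades (random exchanges of partner sets between row pairs,
#' which preserve both degree sequences exactly) and standardizes the
#' observed metric: \eqn{z = (obs - \bar{x}_{null}) / sd_{null}}. Null
#' networks are produced by [vegan::nullmodel()] with `n_swaps` trades of
#' burn-in before the first sample and between consecutive samples.
#'
#' @param net a [bipartite_network()]
#' @param metric `"nodf"`, `"modularity"` or `"c_score"`.
#' @param n_nulls number of null networks (>= 10).
#' @param n_swaps curveball trades per null; default `5 * E`.
#' @param seed integer seed.
#' @param ... further arguments to the metric (e.g. `n_restarts` for
#'   modularity; nulls default to 5 restarts for speed).
#' @return an object of class `null_z`: observed value, null mean/sd, `z`
#'   (NA with `defined = FALSE` when the null distribution is degenerate,
#'   e.g. a complete network whose only degree-preserving rewiring is
#'   itself), the null values, and the settings echo.
#' @export
null_z <- function(net, metric = c("nodf", "modularity", "c_score"),
                   n_nulls = 100, n_swaps = NULL, seed = 1, ...) {
  stopifnot(inherits(net, "bipartite_network"))
  metric <- match.arg(metric)
  if (n_nulls < 10) stopf("`n_nulls` must be >= 10")
  m <- incidence_matrix(net)
  n_swaps <- n_swaps %||% (5L * n_edges(net))
  fun <- switch(metric,
    nodf = nodf_matrix,
    c_score = c_score_matrix,
    modularity = function(x, n_restarts = 5, ...) {
      modularity_matrix(x, seed = seed, n_restarts = n_restarts)$q
    })
  obs <- fun(m, ...)
  nulls <- curveball_nulls(m, n_nulls, n_swaps, seed)
  null_values <- vapply(nulls, fun, numeric(1), ...)
  mu <- mean(null_values); s <- sd(null_values)
  structure(
    list(metric = metric, observed = obs, null_mean = mu, null_sd = s,
         z = if (s > 0) (obs - mu) / s else NA_real_,
         defined = s > 0, null_values = null_values,
         n_nulls = n_nulls, n_swaps = n_swaps, seed = seed),
    class = "null_z")
}

#' @export
print.null_z <- function(x, ...) {
  cat(sprintf("%s = %.4f; curveball null mean %.4f (sd %.4f, %d nulls): %s\n",
              x$metric, x$observed, x$null_mean, x$null_sd, x$n_nulls,
              if (x$defined) sprintf("z = %.2f", x$z)
              else "z undefined (degenerate null distribution)"))
  invisible(x)
}

# n_nulls degree-preserving matrices via vegan's curveball sampler.
curveball_nulls <- function(m, n_nulls, n_swaps, seed) {
  nm <- vegan::nullmodel(m, "curveball")
  sims <- with_seed(seed,
    stats::simulate(nm, nsim = n_nulls, burnin = n_swaps, thin = max(1L, n_swaps)))
  lapply(seq_len(n_nulls), function(i) {
    s <- sims[, , i]
    dimnames(s) <- dimnames(m)
    s
  })
}

#' Structure report for a network
#'
#' Convenience wrapper computing NODF, Barber modularity and C-score plus
#' their curveball z-scores in one call.
#'
#' @inheritParams null_z
#' @param n_restarts modularity restarts for the observed network.
#' @return an object of class `structure_report`: observed metrics, module
#'   assignment, z-scores (with defined flags) and null settings echo.
#' @export
structure_report <- function(net, n_nulls = 100, n_swaps = NULL, seed = 1,
                             n_restarts = 20) {
  mod <- bipartite_modularity(net, seed = seed, n_restarts = n_restarts)
  zs <- lapply(c(nodf = "nodf", modularity = "modularity", c_score = "c_score"),
               function(met) null_z(net, met, n_nulls = n_nulls,
                                    n_swaps = n_swaps, seed = seed))
  structure(
    list(nodf = nodf(net), modularity_q = mod$q, modules = mod$modules,
         c_score = c_score(net),
         z = vapply(zs, `[[`, numeric(1), "z"),
         z_defined = vapply(zs, `[[`, logical(1), "defined"),
         n_nulls = n_nulls, n_swaps = zs[[1]]$n_swaps, seed = seed),
    class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf("NODF %.2f (z %.2f) | Barber Q %.3f (z %.2f, %d modules) | C-score %.3f (z %.2f)\n",
              x$nodf, x$z["nodf"], x$modularity_q, x$z["modularity"],
              length(unique(x$modules)), x$c_score, x$z["c_score"]))
  if (!all(x$z_defined)) {
    cat("  undefined z (degenerate nulls):",
        paste(names(x$z)[!x$z_defined], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Correlate robustness with network structure across an ensemble
#'
#' For each structural property, the Spearman rank correlation with
#' random-scenario robustness (AUC), its square (variance explained on the
#' rank scale) and a two-sided p-value. Constant properties are flagged
#' rather than producing NaN.
#'
#' @param df a data frame with a numeric `auc` column (random-scenario AUC
#'   per network) and one column per structural property; >= 5 rows.
#' @return a data frame with columns `property`, `rho`, `rho_sq`, `p`,
#'   `defined`.
#' @export
robustness_vs_structure <- function(df) {
  if (!is.data.frame(df) || !"auc" %in% names(df)) {
    stopf("`df` must be a data frame with an `auc` column")
  }
  if (nrow(df) < 5L) stopf("need >= 5 networks, got %d", nrow(df))
  props <- setdiff(names(df), "auc")
  rows <- lapply(props, function(p) {
    x <- df[[p]]
    if (!is.numeric(x)) return(NULL)
    ct <- spearman_test(x, df$auc)
    data.frame(property = p, rho = ct$rho, rho_sq = ct$rho^2, p = ct$p,
               defined = ct$defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
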