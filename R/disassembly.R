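# Disassembly engine: removal orders, secondary-extinction curves,
# robustness AUC, replicate aggregation with bootstrap bands.

# list: for each parasite, integer indices of its hosts (into net$hosts)
parasite_host_index <- function(net) {
  hi <- match(net$edges$host, net$hosts)
  split(hi, factor(net$edges$parasite, levels = net$parasites))
}

# Given host removal positions pos (pos[i] = step at which host i is removed)
# return, per parasite, the step at which its last host is removed (= its
# secondary-extinction step).
last_host_step <- function(phi, pos) {
  vapply(phi, function(h) max(pos[h]), numeric(1))
}

# AUC directly from extinction steps: with y_0 = 1, y_H = 0 and trapezoids of
# width 1/H, AUC = (mean_j step_j - 0.5) / H.
auc_from_steps <- function(steps, H) (mean(steps) - 0.5) / H

#' Build a host removal order under a scenario
#'
#' The four scenario families:
#' \describe{
#'   \item{`best`}{hosts removed in increasing order of parasite richness —
#'     hosts with many parasites persist longest, maximizing robustness.}
#'   \item{`worst`}{decreasing order of parasite richness — parasite-rich
#'     hosts go first, minimizing robustness.}
#'   \item{`random`}{a uniform random permutation (the novel-conditions
#'     proxy).}
#'   \item{`by_score`}{ranked by an external [score_table()] (historical
#'     vulnerability, IUCN-like categories, complexity, ...), most
#'     vulnerable first per the table's direction flag.}
#' }
#' Ties are broken uniformly at random, deterministically per seed. For
#' `best`/`worst`, `recompute = "static"` (default) ranks hosts once by
#' initial parasite richness, while `recompute = "greedy"` re-ranks after
#' every removal by richness among the still-surviving parasites.
#'
#' @param net a [bipartite_network()]
#' @param scenario one of `"best"`, `"worst"`, `"random"`, `"by_score"`.
#' @param scores a [score_table()] covering every host; required for
#'   `by_score`.
#' @param seed integer seed for tie randomization.
#' @param recompute `"static"` or `"greedy"` richness ranking (only
#'   `best`/`worst`).
#' @return an object of class `removal_order`: a character permutation of
#'   the network's hosts with `scenario` and `seed` attributes.
#' @export
removal_order <- function(net, scenario = c("best", "worst", "random", "by_score"),
                          scores = NULL, seed = 1,
                          recompute = c("static", "greedy")) {
  stopifnot(inherits(net, "bipartite_network"))
  scenario <- match.arg(scenario)
  recompute <- match.arg(recompute)
  H <- n_hosts(net)
  ord <- with_seed(seed, {
    tie <- sample.int(H)  # one uniform tie-break draw per host
    switch(scenario,
      random = sample.int(H),
      best = order_by_richness(net, decreasing = FALSE, recompute, tie),
      worst = order_by_richness(net, decreasing = TRUE, recompute, tie),
      by_score = {
        if (is.null(scores)) stopf("scenario 'by_score' requires a score table")
        key <- removal_key(scores, net)  # larger = removed earlier
        order(-key, tie)
      })
  })
  structure(net$hosts[ord], scenario = scenario, seed = seed,
            recompute = if (scenario %in% c("best", "worst")) recompute else NULL,
            class = "removal_order")
}

order_by_richness <- function(net, decreasing, recompute, tie) {
  H <- n_hosts(net)
  if (recompute == "static") {
    key <- as.numeric(host_degrees(net))
    if (decreasing) key <- -key
    return(order(key, tie))
  }
  # greedy: after each removal, re-rank by richness among extant parasites
  A <- incidence_matrix(net) > 0L
  remaining_hosts <- rep(TRUE, H)
  p_hosts_left <- colSums(A)          # hosts left per parasite
  ord <- integer(H)
  for (k in seq_len(H)) {
    extant <- p_hosts_left > 0L
    rich <- if (any(extant)) rowSums(A[, extant, drop = FALSE]) else rep(0, H)
    rich[!remaining_hosts] <- NA
    key <- if (decreasing) -rich else rich
    cand <- which(remaining_hosts)
    pick <- cand[order(key[cand], tie[cand])][1L]
    ord[k] <- pick
    remaining_hosts[pick] <- FALSE
    p_hosts_left <- p_hosts_left - A[pick, ]
    A[pick, ] <- FALSE
  }
  ord
}

#' @export
print.removal_order <- function(x, ...) {
  cat(sprintf("Removal order (%s scenario, %d hosts): %s%s\n",
              attr(x, "scenario"), length(x),
              paste(head(unclass(x), 8L), collapse = " > "),
              if (length(x) > 8L) " > ..." else ""))
  invisible(x)
}

#' Disassemble a network under a removal order
#'
#' Removes hosts one by one in the given order. A parasite suffers secondary
#' extinction the moment its last host is removed; after the final removal
#' no parasites remain. The result is the extinction trajectory: H + 1
#' points of (fraction of hosts remaining, fraction of parasites remaining),
#' from (1, 1) down to (0, 0). A pure function: same order, same curve.
#'
#' @param net a [bipartite_network()] with at least one parasite.
#' @param order a [removal_order()] or character permutation of the
#'   network's hosts.
#' @return an object of class `disassembly_curve`: a data frame with columns
#'   `hosts_frac` (strictly decreasing by 1/H) and `parasites_frac`
#'   (non-increasing), plus `scenario` attribute.
#' @export
disassemble <- function(net, order) {
  stopifnot(inherits(net, "bipartite_network"))
  H <- n_hosts(net); P <- n_parasites(net)
  if (P < 1L) stopf("no parasites to track")
  ord <- as.character(order)
  if (length(ord) != H || anyDuplicated(ord) || !all(ord %in% net$hosts)) {
    stopf("`order` is not a permutation of the network's %d hosts", H)
  }
  pos <- match(net$hosts, ord)            # removal step of each host
  steps <- last_host_step(parasite_host_index(net), pos)
  # parasites surviving after k removals = #{j : step_j > k}
  ext_per_step <- tabulate(steps, nbins = H)
  y <- c(P, P - cumsum(ext_per_step)) / P
  structure(
    data.frame(hosts_frac = seq(H, 0) / H, parasites_frac = y),
    scenario = attr(order, "scenario") %||% "custom",
    H = H, P = P,
    class = c("disassembly_curve", "data.frame"))
}

#' Robustness as area under the extinction curve
#'
#' Trapezoidal area under the parasite-fraction vs host-fraction curve over
#' its H + 1 points: \eqn{\sum_{k=1}^{H} (1/H)\,(y_{k-1} + y_k)/2}. Ranges
#' over \eqn{[0, 1]}; 1 means maximally robust (no parasite lost until the
#' last host goes).
#'
#' @param curve a [disassemble()] result.
#' @return a single number in \eqn{[0, 1]}.
#' @export
robustness_auc <- function(curve) {
  stopifnot(inherits(curve, "disassembly_curve"))
  y <- curve$parasites_frac
  H <- length(y) - 1L
  sum((y[-1L] + y[-length(y)]) / 2) / H
}

#' @export
plot.disassembly_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    plot.default(x$hosts_frac, x$parasites_frac, type = "s",
                 xlim = c(1, 0), ylim = c(0, 1), col = col,
                 xlab = "fraction of hosts remaining",
                 ylab = "fraction of parasites remaining", ...)
  } else {
    lines(x$hosts_frac, x$parasites_frac, type = "s", col = col, ...)
  }
  invisible(x)
}

#' Replicate-averaged robustness for a scenario
#'
#' Runs [removal_order()] + [disassemble()] + [robustness_auc()]
#' `n_replicates` times (ties — and, in the random scenario, the whole
#' order — are re-randomized each replicate via derived child seeds),
#' averages the curves pointwise, and computes 95% bootstrap confidence
#' bands by resampling whole replicate curves with replacement (percentile
#' method), which preserves the within-curve autocorrelation.
#'
#' @inheritParams removal_order
#' @param n_replicates number of replicate disassemblies (>= 1).
#' @param n_boot bootstrap resamples for the confidence bands; 0 skips the
#'   bands.
#' @param conf_level confidence level for the bands.
#' @return an object of class `robustness_summary`: scenario label,
#'   `auc_values`, `auc_mean`, `auc_sd`, the grid `hosts_frac`, pointwise
#'   `mean_curve`, `ci_low`, `ci_high`, and the seeds used.
#' @examples
#' net <- generate_network(12, 20, maturity = 0.5, seed = 3)$network
#' rs <- replicate_robustness(net, "random", n_replicates = 50, seed = 9)
#' rs
#' @export
replicate_robustness <- function(net, scenario = c("best", "worst", "random", "by_score"),
                                 scores = NULL, n_replicates = 100, seed = 1,
                                 n_boot = 1000, conf_level = 0.95,
                                 recompute = c("static", "greedy")) {
  stopifnot(inherits(net, "bipartite_network"))
  scenario <- match.arg(scenario)
  recompute <- match.arg(recompute)
  if (n_replicates < 1) stopf("`n_replicates` must be >= 1")
  H <- n_hosts(net); P <- n_parasites(net)
  if (P < 1L) stopf("no parasites to track")
  phi <- parasite_host_index(net)
  seeds <- child_seeds(seed, n_replicates, stream = 1L)
  ycurves <- matrix(NA_real_, n_replicates, H + 1L)
  auc <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    ord <- removal_order(net, scenario, scores = scores, seed = seeds[r],
                         recompute = recompute)
    pos <- match(net$hosts, as.character(ord))
    steps <- last_host_step(phi, pos)
    ycurves[r, ] <- c(P, P - cumsum(tabulate(steps, nbins = H))) / P
    auc[r] <- auc_from_steps(steps, H)
  }
  mean_curve <- colMeans(ycurves)
  ci <- NULL
  if (n_boot > 0) {
    alpha <- (1 - conf_level) / 2
    bmeans <- with_seed(child_seeds(seed, 1L, stream = 2L), {
      t(vapply(seq_len(n_boot), function(b) {
        colMeans(ycurves[sample.int(n_replicates, replace = TRUE), , drop = FALSE])
      }, numeric(H + 1L)))
    })
    ci <- apply(bmeans, 2L, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  }
  structure(
    list(scenario = scenario, n_replicates = n_replicates,
         auc_values = auc, auc_mean = mean(auc), auc_sd = sd(auc),
         hosts_frac = seq(H, 0) / H, mean_curve = mean_curve,
         ci_low = if (is.null(ci)) NULL else pmin(ci[1L, ], mean_curve),
         ci_high = if (is.null(ci)) NULL else pmax(ci[2L, ], mean_curve),
         seed = seed, n_boot = n_boot, conf_level = conf_level,
         recompute = recompute),
    class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("Robustness (%s scenario): AUC = %.4f (sd %.4f over %d replicates)\n",
              x$scenario, x$auc_mean,
              if (is.na(x$auc_sd)) 0 else x$auc_sd, x$n_replicates))
  invisible(x)
}

#' Plot a mean extinction curve with bootstrap ribbon
#'
#' @param x a [replicate_robustness()] result.
#' @param add overlay on an existing plot.
#' @param col curve colour; the ribbon uses a transparent version.
#' @param ... passed to the underlying plot call.
#' @export
plot.robustness_summary <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    plot.default(NA, NA, xlim = c(1, 0), ylim = c(0, 1),
                 xlab = "fraction of hosts remaining",
                 ylab = "fraction of parasites remaining", ...)
  }
  if (!is.null(x$ci_low)) {
    polygon(c(x$hosts_frac, rev(x$hosts_frac)), c(x$ci_low, rev(x$ci_high)),
            border = NA, col = adjustcolor(col, alpha.f = 0.25))
  }
  lines(x$hosts_frac, x$mean_curve, col = col, lwd = 2)
  invisible(x)
}

#' Exact expected random-removal robustness by enumeration
#'
#' Brute-force oracle: the mean AUC over all H! equally likely removal
#' orders, computed by full enumeration. Only feasible for small networks
#' (H <= 8); for larger networks use [replicate_robustness()] with the
#' `random` scenario.
#'
#' @param net a [bipartite_network()] with at most 8 hosts.
#' @return the exact expected AUC.
#' @export
expected_random_auc_exhaustive <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  H <- n_hosts(net)
  if (H > 8L) stopf("H = %d > 8: factorial enumeration infeasible, use Monte Carlo", H)
  if (n_parasites(net) < 1L) stopf("no parasites to track")
  phi <- parasite_host_index(net)
  perms <- permutations(H)   # each row: removal steps pos[1..H] of hosts? see below
  # row r of perms is a permutation p; interpret p[i] as the removal step of
  # host i (equivalent to enumerating orders, by symmetry of the full set).
  total <- 0
  for (r in seq_len(nrow(perms))) {
    total <- total + auc_from_steps(last_host_step(phi, perms[r, ]), H)
  }
  total / nrow(perms)
}

# All permutations of 1..n as an (n! x n) integer matrix, lexicographic.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- sub + (sub >= i)
  }
  out
}
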