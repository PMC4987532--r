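# Sensitivity experiments: incomplete interaction data, tied vulnerability
# rankings, paired scenario comparisons, assemblage-maturity sweeps.

#' Robustness under incomplete interaction data
#'
#' Emulates under-sampled networks: for each deletion fraction, interactions
#' are removed uniformly at random ([subsample_interactions()]; parasites
#' losing every interaction drop out and parasite fractions renormalize to
#' the observed assemblage), the network is disassembled under the given
#' scenario, and replicate robustness is recorded. A control row at
#' deletion 0 carries the full-network robustness. Incomplete data tends to
#' slightly underestimate robustness because surviving parasites have
#' narrower observed host ranges.
#'
#' @param net a [bipartite_network()]
#' @param fractions deletion fractions in (0, 1), e.g. `seq(0.1, 0.6, 0.1)`.
#' @param n_reps independent subsampled networks per fraction.
#' @param scenario,scores,recompute passed to [replicate_robustness()].
#' @param n_replicates disassembly replicates per subsampled network.
#' @param seed master integer seed.
#' @return an `experiment_grid` data frame: one row per (deletion fraction,
#'   subsample replicate) with `auc_mean`, `auc_sd`.
#' @export
partial_information_experiment <- function(net, fractions = seq(0.1, 0.6, by = 0.1),
                                           n_reps = 10,
                                           scenario = "by_score", scores = NULL,
                                           n_replicates = 20, seed = 1,
                                           recompute = "static") {
  stopifnot(inherits(net, "bipartite_network"))
  if (any(fractions <= 0 | fractions >= 1)) {
    stopf("`fractions` must lie strictly inside (0, 1)")
  }
  levels <- c(0, sort(fractions))
  rows <- list()
  for (li in seq_along(levels)) {
    f <- levels[li]
    reps <- if (f == 0) 1L else as.integer(n_reps)
    sseeds <- child_seeds(seed, reps, stream = 10L + li)
    for (r in seq_len(reps)) {
      sub <- if (f == 0) net else subsample_interactions(net, 1 - f, seed = sseeds[r])
      sub_scores <- scores  # coverage over hosts is unchanged by subsampling
      rs <- replicate_robustness(sub, scenario, scores = sub_scores,
                                 n_replicates = n_replicates,
                                 seed = sseeds[r], n_boot = 0,
                                 recompute = recompute)
      rows[[length(rows) + 1L]] <- data.frame(
        deletion_fraction = f, replicate = r,
        auc_mean = rs$auc_mean, auc_sd = rs$auc_sd)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_grid", "data.frame")
  attr(out, "factors") <- "deletion_fraction"
  out
}

#' Tied (binned) versus continuous vulnerability rankings
#'
#' Groups continuous host scores into `n_bins` equal-width intervals over
#' the observed score range, disassembles under the binned ranking with
#' within-bin ties randomized per replicate, and compares the mean binned
#' extinction curve with the mean continuous-score curve by pointwise linear
#' regression (binned on continuous): R-squared, slope and intercept close
#' to 1, 1, 0 mean binning is innocuous. With `n_bins` equal to the number
#' of distinct equally spaced scores, binning is the identity; with
#' `n_bins = 1` every host is tied and the scenario reduces to random
#' removal.
#'
#' @param net a [bipartite_network()]
#' @param scores a continuous [score_table()] covering every host.
#' @param n_bins number of equal-width bins (>= 1).
#' @param n_reps replicates for each of the two scenarios.
#' @param seed master integer seed.
#' @return an object of class `binning_comparison`: `r_squared`, `slope`,
#'   `intercept`, the two mean curves, and the settings echo.
#' @export
tie_binning_experiment <- function(net, scores, n_bins = 5, n_reps = 100, seed = 1) {
  stopifnot(inherits(net, "bipartite_network"), inherits(scores, "score_table"))
  if (n_bins < 1) stopf("`n_bins` must be >= 1")
  check_score_coverage(scores, net, strict = TRUE)
  s <- as.numeric(scores)
  if (diff(range(s)) == 0) stopf("all scores identical: binning is undefined")
  breaks <- seq(min(s), max(s), length.out = n_bins + 1L)
  bin <- findInterval(s, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  binned <- score_table(stats::setNames(as.numeric(bin), names(scores)),
                        higher_is_vulnerable = attr(scores, "higher_is_vulnerable"))
  cont <- replicate_robustness(net, "by_score", scores = scores,
                               n_replicates = n_reps,
                               seed = child_seeds(seed, 1L, stream = 20L),
                               n_boot = 0)
  binr <- replicate_robustness(net, "by_score", scores = binned,
                               n_replicates = n_reps,
                               seed = child_seeds(seed, 1L, stream = 21L),
                               n_boot = 0)
  fit <- lm(binr$mean_curve ~ cont$mean_curve)
  # an exactly reproduced curve is a legitimate outcome here (identity
  # binning), so the perfect-fit warning from summary.lm is expected
  structure(
    list(r_squared = suppressWarnings(summary(fit)$r.squared),
         slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         continuous_curve = cont$mean_curve, binned_curve = binr$mean_curve,
         hosts_frac = cont$hosts_frac,
         auc_continuous = cont$auc_mean, auc_binned = binr$auc_mean,
         n_bins = n_bins, n_reps = n_reps, seed = seed),
    class = "binning_comparison")
}

#' @export
print.binning_comparison <- function(x, ...) {
  cat(sprintf("Binned (%d bins) vs continuous historical curve: R^2 = %.4f, slope = %.4f, intercept = %.2g\n",
              x$n_bins, x$r_squared, x$slope, x$intercept))
  cat(sprintf("  AUC continuous %.4f, binned %.4f (%d replicates each)\n",
              x$auc_continuous, x$auc_binned, x$n_reps))
  invisible(x)
}

#' Paired comparison of two removal scenarios across networks
#'
#' Classical paired t-test on per-network mean AUC values from two
#' scenarios. Inputs are named numeric vectors (names = network
#' identifiers); the pairing is by name and the two sets must match. A zero
#' variance of the differences (e.g. identical inputs) is flagged
#' degenerate rather than producing NaN.
#'
#' @param a,b named numeric vectors of per-network AUC means.
#' @return an object of class `scenario_comparison`: `mean_difference`
#'   (a - b), `t`, `df`, `p`, `n`, `degenerate`.
#' @export
compare_scenarios <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b))) {
    stopf("`a` and `b` must be named by network identifier for pairing")
  }
  if (!setequal(names(a), names(b))) {
    stopf("network sets differ between scenarios: %s",
          paste(union(setdiff(names(a), names(b)), setdiff(names(b), names(a))),
                collapse = ", "))
  }
  if (length(a) < 3L) stopf("need >= 3 paired networks, got %d", length(a))
  d <- a - b[names(a)]
  if (sd(d) == 0) {
    return(structure(list(mean_difference = mean(d), t = NA_real_,
                          df = length(d) - 1L,
                          p = if (all(d == 0)) 1 else NA_real_,
                          n = length(d), degenerate = TRUE),
                     class = "scenario_comparison"))
  }
  tt <- t.test(d)
  structure(list(mean_difference = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 n = length(d), degenerate = FALSE),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("Paired scenario comparison over %d networks: mean AUC difference %.4f%s\n",
              x$n, x$mean_difference,
              if (x$degenerate) " (zero-variance differences; degenerate)"
              else sprintf(", t = %.2f (df %d), p = %.3g", x$t, x$df, x$p)))
  invisible(x)
}

#' Robustness versus assemblage maturity
#'
#' Generates ensembles along a maturity gradient (see
#' [maturity_schedule()]) and measures each assemblage's robustness under
#' the historical scenario (removal by its own vulnerability ranking) and
#' the random scenario. Reports the Spearman trend of each response against
#' maturity, computed on all raw per-network values. Mature assemblages are
#' expected to gain historical robustness while losing robustness to novel
#' (random) removal — the adaptation tradeoff.
#'
#' @param tau_levels maturity levels in \eqn{[0, 1]}.
#' @param n_per networks per level.
#' @param n_reps random-scenario replicates per network.
#' @param seed master integer seed.
#' @param n_hosts,n_parasites network dimensions for the generator.
#' @return an object of class `maturity_sweep`: `grid` (one row per
#'   network: `tau`, `auc_historical`, `auc_random`, `specialization`) and
#'   Spearman trends `trend_historical`, `trend_random`,
#'   `trend_specialization`.
#' @export
maturity_sweep <- function(tau_levels = seq(0.1, 1, by = 0.1), n_per = 50,
                           n_reps = 100, seed = 1, n_hosts = 40, n_parasites = 60) {
  stopifnot(all(tau_levels >= 0 & tau_levels <= 1))
  rows <- list()
  for (ti in seq_along(tau_levels)) {
    tau <- tau_levels[ti]
    asms <- generate_ensemble(
      list(list(n_hosts = n_hosts, n_parasites = n_parasites, maturity = tau)),
      n_per = n_per, seed = child_seeds(seed, 1L, stream = 30L + ti))
    for (i in seq_along(asms)) {
      asm <- asms[[i]]
      rseed <- child_seeds(asm$seed, 2L, stream = 40L)
      hist_rs <- replicate_robustness(asm$network, "by_score",
                                      scores = asm$vulnerability,
                                      n_replicates = 1L, seed = rseed[1L],
                                      n_boot = 0)
      rand_rs <- replicate_robustness(asm$network, "random",
                                      n_replicates = n_reps, seed = rseed[2L],
                                      n_boot = 0)
      rows[[length(rows) + 1L]] <- data.frame(
        tau = tau, network = i,
        auc_historical = hist_rs$auc_mean, auc_random = rand_rs$auc_mean,
        specialization = specialization_index(asm$network))
    }
  }
  grid <- do.call(rbind, rows)
  structure(
    list(grid = grid,
         trend_historical = spearman_test(grid$tau, grid$auc_historical),
         trend_random = spearman_test(grid$tau, grid$auc_random),
         trend_specialization = spearman_test(grid$tau, grid$specialization),
         tau_levels = tau_levels, n_per = n_per, n_reps = n_reps, seed = seed),
    class = "maturity_sweep")
}

#' @export
print.maturity_sweep <- function(x, ...) {
  cat(sprintf("Maturity sweep over tau = {%s}, %d networks per level:\n",
              paste(format(x$tau_levels), collapse = ", "), x$n_per))
  cat(sprintf("  historical AUC trend: r_s = %+.3f (p = %.3g)\n",
              x$trend_historical$rho, x$trend_historical$p))
  cat(sprintf("  random AUC trend:     r_s = %+.3f (p = %.3g)\n",
              x$trend_random$rho, x$trend_random$p))
  cat(sprintf("  specialization trend: r_s = %+.3f (p = %.3g)\n",
              x$trend_specialization$rho, x$trend_specialization$p))
  invisible(x)
}
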