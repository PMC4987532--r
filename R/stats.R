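# Statistical readouts: Spearman machinery, vulnerability correlations,
# ensemble summaries, specialization index.

# Spearman rank correlation with a two-sided p-value: exact permutation
# p for n <= 9 (full enumeration over rank permutations, valid with ties),
# t-approximation for larger n. Returns rho = NA with defined = FALSE for
# constant inputs instead of NaN.
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L || sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE,
                p_defined = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n < 4L) {
    # correlation defined but meaningless to test
    return(list(rho = rho, p = NA_real_, n = n, defined = TRUE,
                p_defined = FALSE))
  }
  if (n <= 9L) {
    perms <- permutations(n)
    # Sum_i rx_i * ry_perm(i) for every permutation, vectorized
    s <- matrix(ry[perms], nrow(perms), n) %*% rx
    denom <- (n - 1) * sd(rx) * sd(ry)
    rho_perm <- (s - n * mean(rx) * mean(ry)) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * pt(-abs(t_stat), n - 2)
    p <- min(1, max(p, .Machine$double.xmin))
  }
  list(rho = rho, p = p, n = n, defined = TRUE, p_defined = TRUE)
}

#' Vulnerability correlations of one network
#'
#' The two per-network readouts relating host vulnerability to the parasite
#' assemblage:
#' \itemize{
#'   \item standardized parasite richness of host i: (number of parasites on
#'     i) / P, correlated with vulnerability over \emph{all} hosts;
#'   \item standardized mean host range of host i's parasites: mean over i's
#'     parasites of (parasite degree) / H, correlated with vulnerability over
#'     \emph{parasitized} hosts only (an uninfected host has no defined mean
#'     host range).
#' }
#' In assemblages where parasites specialize on dependable hosts, the
#' richness correlation is negative (vulnerable hosts carry fewer parasites)
#' and the host-range correlation positive (vulnerable hosts carry
#' generalists).
#'
#' @param net a [bipartite_network()]
#' @param vulnerability a [score_table()] covering every host.
#' @return an object of class `vulnerability_correlations`: lists `richness`
#'   and `host_range`, each with `rho`, `p`, `n`, `defined`, `p_defined`
#'   (`p_defined = FALSE` flags samples too small for a p-value).
#' @export
vulnerability_correlations <- function(net, vulnerability) {
  stopifnot(inherits(net, "bipartite_network"))
  check_score_coverage(vulnerability, net, strict = TRUE)
  H <- n_hosts(net); P <- n_parasites(net)
  dir <- if (attr(vulnerability, "higher_is_vulnerable")) 1 else -1
  v <- dir * as.numeric(vulnerability)[match(net$hosts, names(vulnerability))]
  dh <- as.numeric(host_degrees(net))
  richness <- dh / P
  dp <- parasite_degrees(net)
  # mean standardized host range of each host's parasites
  mean_range <- rep(NA_real_, H)
  by_host <- split(dp[net$edges$parasite], factor(net$edges$host, levels = net$hosts))
  has <- lengths(by_host) > 0L
  mean_range[has] <- vapply(by_host[has], mean, numeric(1)) / H
  structure(
    list(richness = spearman_test(v, richness),
         host_range = spearman_test(v[has], mean_range[has])),
    class = "vulnerability_correlations")
}

#' @export
print.vulnerability_correlations <- function(x, ...) {
  fmt <- function(lab, ct) {
    cat(sprintf("  r_s(vulnerability, %s) = %s (n = %d%s)\n", lab,
                if (ct$defined) sprintf("%.3f", ct$rho) else "undefined (constant input)",
                ct$n,
                if (ct$p_defined) sprintf(", p = %.3g", ct$p)
                else ", n too small for p"))
  }
  cat("Vulnerability correlations:\n")
  fmt("parasite richness", x$richness)
  fmt("mean parasite host range", x$host_range)
  invisible(x)
}

#' Summarize vulnerability correlations over an ensemble
#'
#' Aggregates per-network correlation pairs the way ensemble results are
#' conventionally reported: mean and standard deviation of each correlation
#' over the networks where it is defined, and the fraction of networks
#' significant at `alpha`.
#'
#' @param pairs a list of [vulnerability_correlations()] results (>= 2).
#' @param alpha significance level for the "fraction significant" readout.
#' @return an object of class `correlation_report` with per-correlation
#'   `mean`, `sd`, `frac_significant`, `n_defined`.
#' @export
ensemble_correlation_summary <- function(pairs, alpha = 0.05) {
  if (length(pairs) < 2L) stopf("need >= 2 networks, got %d", length(pairs))
  pull <- function(which) {
    rho <- vapply(pairs, function(p) p[[which]]$rho, numeric(1))
    pv <- vapply(pairs, function(p) p[[which]]$p %||% NA_real_, numeric(1))
    ok <- !is.na(rho)
    if (!any(ok)) return(NULL)
    list(mean = mean(rho[ok]), sd = sd(rho[ok]),
         frac_significant = mean(pv[ok & !is.na(pv)] < alpha),
         n_defined = sum(ok))
  }
  rich <- pull("richness"); hr <- pull("host_range")
  if (is.null(rich) && is.null(hr)) {
    stopf("all correlations undefined in the ensemble")
  }
  structure(list(richness = rich, host_range = hr, alpha = alpha,
                 n_networks = length(pairs)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Ensemble correlations over %d networks (alpha = %.2f):\n",
              x$n_networks, x$alpha))
  show <- function(lab, s) {
    if (is.null(s)) { cat(sprintf("  %s: undefined in all networks\n", lab)); return() }
    cat(sprintf("  r_s(vulnerability, %s) = %.3f +/- %.3f, P < %.2f in %.0f%% of cases (n = %d)\n",
                lab, s$mean, s$sd, x$alpha, 100 * s$frac_significant, s$n_defined))
  }
  show("parasite richness", x$richness)
  show("mean parasite host range", x$host_range)
  invisible(x)
}

#' Specialization index of a parasite assemblage
#'
#' One minus the average fraction of hosts used by parasites:
#' \eqn{1 - \frac{1}{P}\sum_j g_j / H}. Equals 0 exactly when every parasite
#' uses every host, and approaches 1 as parasites become extreme
#' specialists on single hosts in a large host pool.
#'
#' @param net a [bipartite_network()] with >= 1 parasite.
#' @return specialization in \eqn{[0, 1)}.
#' @export
specialization_index <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (n_parasites(net) < 1L) stopf("no parasites")
  1 - mean(parasite_degrees(net)) / n_hosts(net)
}
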