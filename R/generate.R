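#' Generate a synthetic host-parasite assemblage
#'
#' Emulates the statistical structure that co-evolved host-parasite
#' assemblages show: specialist parasites concentrate on dependable
#' (low-vulnerability) hosts, whereas generalists use hosts nearly
#' indifferently, so vulnerable hosts end up carrying fewer and more
#' generalist parasites. The generation procedure is:
#'
#' 1. Hosts receive distinct vulnerability ranks \eqn{v_i = (r_i - 0.5)/H}
#'    over a seeded random permutation; dependability is \eqn{d_i = 1 - v_i}.
#' 2. Each parasite draws a host range \eqn{g_j} from a geometric
#'    distribution with parameter `generality_q`, truncated to
#'    \eqn{\{1, \dots, H\}}; its specialization is
#'    \eqn{s_j = 1 - (g_j - 1)/\max(1, H - 1)}.
#' 3. The parasite attaches to \eqn{g_j} distinct hosts sampled without
#'    replacement with weights \eqn{w_i \propto (d_i + 10^{-6})^{\gamma s_j}}.
#'
#' `gamma` controls the dependability coupling: at `gamma = 0` attachment is
#' uniform and vulnerability is unrelated to parasite richness; as `gamma`
#' grows, specialists (large \eqn{s_j}) avoid vulnerable hosts ever more
#' strongly while generalists (\eqn{s_j \approx 0}) remain near-indifferent.
#' The \eqn{10^{-6}} floor keeps every host at non-zero weight.
#'
#' Instead of `generality_q` and `gamma`, a single `maturity` knob in
#' \eqn{[0, 1]} can be given; it maps through the fixed monotone schedule
#' `generality_q = 0.1 + 0.8 * maturity`, `gamma = 8 * maturity`, so that
#' older (more mature) assemblages are simultaneously more specialized and
#' more tightly coupled to host dependability.
#'
#' @param n_hosts number of host species (>= 2).
#' @param n_parasites number of parasite species (>= 1).
#' @param generality_q truncated-geometric parameter in (0, 1) for parasite
#'   host range; larger values mean more specialists. The default 0.1 keeps
#'   the host-range distribution spread over its full support (mode at 1,
#'   heavy generalist tail), which the attachment mechanism needs: only
#'   parasites with host ranges comparable to the host pool are genuinely
#'   indifferent to dependability, and those are what allow vulnerable
#'   hosts to retain (generalist) parasites at all.
#' @param gamma dependability coupling exponent, >= 0.
#' @param maturity optional value in \eqn{[0, 1]}; overrides `generality_q`
#'   and `gamma` through the schedule above.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return an object of class `synthetic_assemblage`: a list with elements
#'   `network` (a [bipartite_network()]), `vulnerability` (a [score_table()],
#'   higher = more vulnerable = removed earlier historically), `params` and
#'   `seed`.
#' @examples
#' asm <- generate_network(n_hosts = 10, n_parasites = 15, maturity = 0.5, seed = 1)
#' summary(asm$network)
#' @export
generate_network <- function(n_hosts, n_parasites, generality_q = 0.1, gamma = 1,
                             maturity = NULL, seed = 1) {
  if (!is.null(maturity)) {
    if (!is.numeric(maturity) || maturity < 0 || maturity > 1) {
      stopf("`maturity` must be in [0, 1]")
    }
    sched <- maturity_schedule(maturity)
    generality_q <- sched$generality_q
    gamma <- sched$gamma
  }
  if (n_hosts < 2) stopf("`n_hosts` must be >= 2")
  if (n_parasites < 1) stopf("`n_parasites` must be >= 1")
  if (generality_q <= 0 || generality_q >= 1) stopf("`generality_q` must be in (0, 1)")
  if (gamma < 0) stopf("`gamma` must be >= 0")
  H <- as.integer(n_hosts); P <- as.integer(n_parasites)
  hosts <- sprintf("h%03d", seq_len(H))
  parasites <- sprintf("p%03d", seq_len(P))
  res <- with_seed(seed, {
    ranks <- sample.int(H)                   # random permutation of 1..H
    v <- (ranks - 0.5) / H                   # distinct vulnerability ranks
    d <- 1 - v                               # dependability
    g <- rtrunc_geom(P, generality_q, H)     # host ranges
    s <- 1 - (g - 1) / max(1L, H - 1L)       # specialization per parasite
    edge_h <- vector("list", P)
    for (j in seq_len(P)) {
      w <- (d + 1e-6)^(gamma * s[j])
      edge_h[[j]] <- sample.int(H, g[j], replace = FALSE, prob = w)
    }
    list(v = v, g = g, edge_h = edge_h)
  })
  edges <- data.frame(
    host = hosts[unlist(res$edge_h)],
    parasite = rep(parasites, lengths(res$edge_h)),
    stringsAsFactors = FALSE)
  structure(
    list(network = bipartite_network(edges, hosts = hosts, parasites = parasites),
         vulnerability = score_table(stats::setNames(res$v, hosts),
                                     higher_is_vulnerable = TRUE),
         params = list(n_hosts = H, n_parasites = P,
                       generality_q = generality_q, gamma = gamma,
                       maturity = maturity),
         seed = seed),
    class = "synthetic_assemblage")
}

#' @export
print.synthetic_assemblage <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic assemblage (q = %.3f, gamma = %.2f%s, seed %s)\n",
              p$generality_q, p$gamma,
              if (!is.null(p$maturity)) sprintf(", maturity %.2f", p$maturity) else "",
              format(x$seed)))
  print(summary(x$network))
  invisible(x)
}

#' Maturity schedule mapping one knob to (generality_q, gamma)
#'
#' The fixed monotone schedule used by [generate_network()]:
#' `generality_q = 0.1 + 0.8 * maturity`, `gamma = 8 * maturity`. Higher
#' maturity produces both more specialized parasites and a stronger
#' dependability coupling.
#'
#' @param maturity value(s) in \eqn{[0, 1]}.
#' @return list with numeric elements `generality_q` and `gamma`.
#' @export
maturity_schedule <- function(maturity) {
  stopifnot(all(maturity >= 0 & maturity <= 1))
  list(generality_q = 0.1 + 0.8 * maturity, gamma = 8 * maturity)
}

# Geometric(q) on {1, 2, ...} truncated to {1..H}, sampled by inverse CDF.
rtrunc_geom <- function(n, q, H) {
  Fmax <- 1 - (1 - q)^H
  u <- runif(n, 0, Fmax)
  g <- ceiling(log1p(-u) / log1p(-q))
  pmin(pmax(g, 1L), H)
}

#' Generate a novel vulnerability ranking with tunable similarity
#'
#' Produces a new host ranking whose Spearman rank correlation with the
#' historical one is approximately `target_rho`, via a Gaussian copula:
#' latent \eqn{z_i = a\,\Phi^{-1}(u_i) + \sqrt{1 - a^2}\,\varepsilon_i} with
#' \eqn{u_i} the historical rank-uniforms and \eqn{a = 2\sin(\pi\rho_s/6)}
#' (the exact inverse of the Spearman correlation of a bivariate Gaussian).
#' `target_rho = 1` returns the historical table unchanged; `target_rho = 0`
#' is a uniform random permutation.
#'
#' @param historical a [score_table()] covering >= 3 hosts (unless
#'   `target_rho` is exactly 0 or 1).
#' @param target_rho desired Spearman correlation in \eqn{[-1, 1]} between
#'   the new and historical vulnerability rankings.
#' @param seed integer seed.
#' @return a [score_table()] with values \eqn{(r_i - 0.5)/H} (higher = more
#'   vulnerable).
#' @export
generate_novel_ranking <- function(historical, target_rho, seed) {
  stopifnot(inherits(historical, "score_table"))
  if (!is.numeric(target_rho) || target_rho < -1 || target_rho > 1) {
    stopf("`target_rho` must be in [-1, 1]")
  }
  H <- length(historical)
  if (H < 3 && !(target_rho %in% c(0, 1))) {
    stopf("need >= 3 hosts for intermediate target_rho (correlation ill-defined on %d)", H)
  }
  if (target_rho == 1) {
    return(score_table(stats::setNames(as.numeric(historical), names(historical)),
                       higher_is_vulnerable = attr(historical, "higher_is_vulnerable")))
  }
  dir <- if (attr(historical, "higher_is_vulnerable")) 1 else -1
  r_hist <- rank(dir * as.numeric(historical), ties.method = "average")
  u <- (r_hist - 0.5) / H
  a <- 2 * sin(pi * target_rho / 6)
  a <- min(1, max(-1, a))
  z <- with_seed(seed, a * qnorm(u) + sqrt(1 - a^2) * rnorm(H))
  r_new <- rank(z, ties.method = "first")
  score_table(stats::setNames((r_new - 0.5) / H, names(historical)),
              higher_is_vulnerable = TRUE)
}

#' Generate an ensemble of synthetic assemblages
#'
#' `n_per` assemblages are generated for each parameter set, with child
#' seeds derived deterministically from the master seed, so ensembles are
#' reproducible and stable in order (parameter-set major).
#'
#' @param params_list a list of parameter lists; each element holds
#'   arguments for [generate_network()] (`n_hosts`, `n_parasites`, and
#'   either `generality_q`/`gamma` or `maturity`).
#' @param n_per assemblages per parameter set (>= 1).
#' @param seed master integer seed.
#' @return list of `synthetic_assemblage` objects, length
#'   `length(params_list) * n_per`.
#' @export
generate_ensemble <- function(params_list, n_per, seed) {
  if (!is.list(params_list) || length(params_list) == 0L) {
    stopf("`params_list` must be a non-empty list of parameter sets")
  }
  if (!all(vapply(params_list, is.list, TRUE))) {
    stopf("each element of `params_list` must itself be a list of generator arguments")
  }
  if (n_per < 1) stopf("`n_per` must be >= 1")
  out <- vector("list", length(params_list) * n_per)
  k <- 0L
  for (i in seq_along(params_list)) {
    seeds <- child_seeds(seed, n_per, stream = i)
    for (r in seq_len(n_per)) {
      k <- k + 1L
      out[[k]] <- do.call(generate_network, c(params_list[[i]], list(seed = seeds[r])))
    }
  }
  out
}
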