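# coext

Co-extinction robustness analysis of bipartite host-parasite networks.

When hosts are lost from an ecosystem, parasites whose entire host set
disappears go secondarily extinct. How quickly a parasite assemblage erodes
depends on the *order* of host loss: assemblages whose parasites
specialized on dependable (low-vulnerability) hosts are robust to the
historical extinction order but can be fragile under novel orders, as
expected under environmental change. `coext` is for ecologists who want to
quantify that contrast — on real networks converted to simple CSV
contracts, or on synthetic assemblages with a known, tunable coupling
between host dependability and parasite specialization.

## The core quantities

A bipartite network with `H` hosts and `P` parasites is *disassembled* by
removing hosts one at a time; a parasite goes extinct when its last host is
removed. The extinction trajectory is the sequence of points
(fraction of hosts remaining, fraction of parasites remaining), and
**robustness** is the trapezoidal area under it:

    R = sum_{k=1..H} (1/H) * (y_{k-1} + y_k) / 2,   R in [0, 1]

Removal scenarios: `best` (parasite-poor hosts first), `worst`
(parasite-rich hosts first), `random` (novel-conditions proxy), and
`by_score` (an external vulnerability ranking — historical scores,
IUCN-like ordinal categories, etc.). Ties are randomized across replicates;
replicate curves are averaged with bootstrap confidence bands.

The synthetic generator assigns hosts distinct vulnerability ranks
`v = (r - 0.5)/H`, draws each parasite's host range `g` from a truncated
geometric(`q`), and attaches it to `g` hosts with weights
`(1 - v + 1e-6)^(gamma * s)` where `s` is the parasite's specialization —
so specialists avoid vulnerable hosts while generalists barely care.

## Worked example

```r
library(coext)

asm <- generate_network(n_hosts = 40, n_parasites = 60, gamma = 4, seed = 101)
asm
#> Synthetic assemblage (q = 0.100, gamma = 4.00, seed 101)
#> Bipartite network: 40 hosts, 60 parasites, 609 interactions (connectance 0.254)

vulnerability_correlations(asm$network, asm$vulnerability)
#> Vulnerability correlations:
#>   r_s(vulnerability, parasite richness) = -0.980 (n = 40, p = 2.4e-28)
#>   r_s(vulnerability, mean parasite host range) = 0.956 (n = 40, p = 6.75e-22)

replicate_robustness(asm$network, "by_score", scores = asm$vulnerability,
                     n_replicates = 100, seed = 1)
#> Robustness (by_score scenario): AUC = 0.9412 (sd 0.0000 over 100 replicates)
replicate_robustness(asm$network, "random", n_replicates = 100, seed = 2)
#> Robustness (random scenario): AUC = 0.8157 (sd 0.0464 over 100 replicates)

specialization_index(asm$network)
#> [1] 0.746

structure_report(asm$network, n_nulls = 100, seed = 3)
#> NODF 65.78 (z 0.35) | Barber Q 0.187 (z 1.03, 4 modules) | C-score 11.710 (z 2.04)
```

Reading the output: vulnerable hosts carry far fewer parasites
(r_s = -0.98) and the parasites they do carry are generalists
(r_s = +0.96), so removing hosts in historical vulnerability order
(`by_score`, most vulnerable first) barely dents the assemblage until the
end — robustness 0.94, with zero variance because the ranking has no ties —
while a random (novel) order costs about 0.13 of robustness on the same
network. The structure report shows the network is nested (NODF) but not
unusually so for its degree sequences (z = 0.35 against curveball nulls).

Real data enter through `read_edge_list()` / `read_adjacency_matrix()` plus
`read_scores()` (ordinal categories via `category_levels`, direction via
`higher_is_vulnerable`), are checked by `validate_inputs()`, and run
through the same functions. `run_experiment()` drives the whole pipeline
from a YAML config and writes plotting-ready CSVs plus a run log.

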