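---
title: "Co-extinction robustness of host-parasite networks: models and methods"
author: "coext package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-extinction robustness of host-parasite networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coext)
```

## The problem

When a host species goes extinct, every parasite that depends on it alone
goes extinct with it. Across a whole bipartite host-parasite network, the
order in which hosts are lost therefore decides how fast the parasite
assemblage erodes: if parasite-rich, heavily-used hosts disappear late,
parasite diversity is buffered; if they disappear early, it collapses.
`coext` implements the full analysis around this idea: disassembling a
network host by host under competing removal scenarios, quantifying the
assemblage's robustness, generating synthetic assemblages whose
specialization structure is coupled to host dependability, and running the
sensitivity experiments (incomplete sampling, tied vulnerability rankings,
assemblage maturity) that probe how fragile the conclusions are.

The scientific question behind the machinery: assemblages that formed under
stable conditions should have parasites that avoided specializing on
vulnerable hosts, making them robust to the *historical* extinction order
but not to *novel* orders (environmental change). The package lets you
measure exactly that contrast.

## Disassembly and robustness

A network has $H$ hosts, $P$ parasites and binary interactions. Hosts are
removed one at a time in a prescribed order; a parasite suffers secondary
extinction the moment its last host is removed. Recording the fraction of
surviving parasites after each removal yields an extinction trajectory of
$H + 1$ points $(x_k, y_k)$, from $(1, 1)$ down to $(0, 0)$, with
$x_k = (H - k)/H$. Robustness is the trapezoidal area under this curve,

$$R = \sum_{k=1}^{H} \frac{1}{H}\,\frac{y_{k-1} + y_k}{2} \in [0, 1],$$

with $R = 1 - \tfrac{1}{2H}$ (the maximum) when no parasite is lost before
the last removal, and $R = 0.5$ for a perfect one-to-one matching, whose
curve is the diagonal under every order. Extinction is evaluated after
every single removal (no batching), and $y$ is always normalized by the
*initial* parasite richness of the network being disassembled.

Internally the engine uses the identity $R = (\bar{s} - 0.5)/H$, where
$\bar{s}$ is the mean removal step at which parasites lose their last host;
this makes a replicate cost $O(E)$ and keeps Monte-Carlo studies with
$10^4$ replicates cheap. `robustness_auc()` integrates the explicit curve;
the two routes agree to machine precision and are cross-checked in the test
suite, together with a factorial-enumeration oracle
(`expected_random_auc_exhaustive()`, $H \le 8$) and a closed form for the
random scenario based on $P(\text{extinct after } k) = \binom{k}{g}/\binom{H}{g}$
for a parasite with host range $g$.

## Removal scenarios

* **best** — hosts removed in increasing order of parasite richness;
  parasite-rich hosts persist longest. This maximizes robustness among
  degree heuristics.
* **worst** — decreasing order of parasite richness.
* **random** — a uniform permutation; the proxy for novel conditions.
* **by_score** — ranked by an external per-host score table (historical
  vulnerability, an IUCN-like ordinal category mapped to integer ranks, a
  complexity measure, ...). The table carries an explicit
  `higher_is_vulnerable` flag; the most vulnerable host is removed first.

Ties are broken uniformly at random, re-randomized per replicate with
derived child seeds; `replicate_robustness()` averages the replicate curves
pointwise and attaches 95% confidence bands obtained by bootstrapping whole
replicate curves (percentile method, default 1000 resamples). Resampling
entire curves rather than individual points preserves the within-curve
autocorrelation.

Best/worst default to a **static** ranking by initial richness. The
phrase "removing, in sequence, the host with the least parasites" can also
be read adaptively, so a **greedy** mode (`recompute = "greedy"`) re-ranks
hosts after every removal by richness among still-extant parasites. The two
coincide whenever parasite sets do not overlap; both are exposed and tested,
and static is the documented default.

## The synthetic assemblage generator

The generator emulates the statistical signature of assemblages that
evolved under stable conditions, without simulating evolution itself:

1. Hosts get distinct vulnerability ranks $v_i = (r_i - 0.5)/H$ over a
   seeded random permutation; dependability is $d_i = 1 - v_i$.
2. Parasite $j$ draws a host range $g_j$ from a geometric distribution with
   parameter $q$ (`generality_q`) truncated to $\{1, \dots, H\}$;
   specialization is $s_j = 1 - (g_j - 1)/(H - 1)$.
3. It attaches to $g_j$ distinct hosts sampled without replacement with
   weights $w_i \propto (d_i + 10^{-6})^{\gamma s_j}$.

The exponent couples host choice to dependability *in proportion to
specialization*: extreme specialists ($s_j = 1$) feel the full coupling
$\gamma$, while broad generalists ($s_j \approx 0$) are nearly indifferent.
That asymmetry is what produces the empirical pattern this design targets:
vulnerable hosts end up with fewer parasites (negative
vulnerability-richness correlation) and the parasites they do have are
generalists (positive vulnerability-host-range correlation). The $10^{-6}$
floor keeps every host reachable at any $\gamma$.

Parameter defaults, and why:

* `generality_q = 0.1`. The coupling mechanism only differentiates
  parasites if host ranges actually spread over $1..H$. At $H = 40$, a
  geometric with $q = 0.5$ puts ~94% of parasites at $g \le 4$, so every
  parasite is effectively a specialist ($s_j > 0.9$), no generalists exist
  to occupy vulnerable hosts, and the host-range correlation collapses
  towards zero (and can even turn negative at larger $q$). With $q = 0.1$
  the distribution keeps its mode at $g = 1$ (many specialists) but has a
  substantial generalist tail, and the ensemble shows both correlations
  with the expected signs, strengthening monotonically in $\gamma$.
* `gamma = 1` as a neutral default; ensemble studies in the tests use
  $\gamma \in \{0, 1, 2, 4, 8\}$, with $\gamma = 0$ the exact null (uniform
  attachment) and $\gamma = 4$ the standard "coupled" condition.
* `maturity` (optional, $\tau \in [0,1]$) maps through the fixed monotone
  schedule $q(\tau) = 0.1 + 0.8\tau$, $\gamma(\tau) = 8\tau$: older
  assemblages are simultaneously more specialized and more tightly coupled
  to dependability. Any monotone pair would express the same idea; this one
  is frozen as the shipped default so sweeps are comparable across studies.

`generate_novel_ranking()` produces a second vulnerability ranking with a
tunable Spearman correlation $\rho$ to the historical one via a Gaussian
copula: $z_i = a\,\Phi^{-1}(u_i) + \sqrt{1 - a^2}\,\varepsilon_i$ with
$u_i$ the historical rank-uniforms and $a = 2\sin(\pi\rho/6)$, the exact
inverse of the Spearman correlation of a bivariate Gaussian. $\rho = 1$
returns the input unchanged, $\rho = 0$ is a uniform permutation; at
$H = 100$ the realized mean correlation is within $\pm 0.05$ of the target
(verified by simulation in the tests).

### What the generator does and does not emulate

It reproduces the *association structure* the analysis needs — the joint
distribution of vulnerability, richness and host range — not the process
that creates it. There is no mutation, reproduction, virulence or resource
competition; vulnerability is exogenous rather than emerging from
competitive dynamics; all parasites have simple (single-host) life cycles;
and there is no spatial structure or recolonization. Tests passing on
synthetic ensembles therefore demonstrate that the *pipeline* measures what
it claims under a known ground truth; they do not certify how strongly real
assemblages express the dependability coupling, which must be estimated
from data via `vulnerability_correlations()`.

## Structure metrics and null models

* **NODF** (0-100): mean paired overlap over row pairs and column pairs,
  counting a pair only when fills strictly decrease. Computed by
  `vegan::nestednodf` with fill-sorting enabled, which makes the metric
  invariant to storage order; the test suite checks it against a
  definitional pairwise-loop oracle. Chosen as the field-standard
  overlap-and-decreasing-fill nestedness measure; it sits behind the
  `nodf()` interface so a different variant could be substituted without
  touching the rest of the pipeline.
* **Barber bipartite modularity** $Q = \frac{1}{E}\sum_{c_i = c_j}
  (A_{ij} - k_i d_j / E)$, maximized by an alternating (BRIM-style) label
  optimizer with seeded random restarts plus one deterministic restart from
  the connected components. Exact maximization is NP-hard and unnecessary
  for ensemble correlations; the component restart guarantees the exact
  optimum on cleanly modular networks ($Q = 1 - 1/m$ for $m$ equal blocks),
  and the returned $Q$ is never below the single-module floor of 0.
* **C-score**: mean checkerboard units $(r_a - S)(r_b - S)$ over parasite
  pairs; measures partner segregation.
* **Curveball nulls** (`null_z()`): degree-preserving randomizations via
  `vegan`'s curveball sampler, with `n_swaps` trades (default $5E$) of
  burn-in and the same thinning between draws;
  $z = (\mathrm{obs} - \bar{x}_\mathrm{null})/s_\mathrm{null}$.

Degenerate nulls are flagged (`defined = FALSE`) rather than propagating
NaN. Two cases matter in practice: complete networks, whose only
degree-preserving rewiring is themselves, and *perfectly nested* matrices —
prefix-row matrices contain no 2x2 checkerboard, so they are the unique
realization of their degree sequences and curveball cannot move at all.
Null-model significance for nestedness is consequently only meaningful for
imperfectly nested networks, and even there fixed-degree nulls absorb the
nestedness implied by skewed degrees; expect modest z-scores.

## Statistical readouts

`vulnerability_correlations()` computes, per network, Spearman correlations
of host vulnerability with (i) standardized parasite richness
(host degree / $P$) over **all** hosts and (ii) standardized mean host
range of the host's parasites (mean parasite degree / $H$) over
**parasitized hosts only** — an uninfected host has no defined mean host
range. `ensemble_correlation_summary()` reports ensemble means, SDs and the
fraction of networks significant at $\alpha = 0.05$, the conventional
reporting style for such ensembles.

Spearman p-values are exact for $n \le 9$ (full enumeration over rank
permutations, valid under ties) and use the t-approximation otherwise;
samples with $n < 4$ are flagged "too small for p" instead of being tested.
Degenerate inputs (constant vectors) yield flagged, not silent, results.

The specialization index is $1 - \overline{g}/H$, zero exactly when every
parasite uses every host.

## Sensitivity experiments

* `partial_information_experiment()` deletes a fraction of interactions
  uniformly at random (parasites losing all interactions drop out, and
  fractions renormalize to the observed assemblage), then re-measures
  robustness; a control row at deletion 0 anchors the comparison. Deletion
  narrows observed host ranges, so robustness is slightly underestimated —
  the expected direction, confirmed on coupled ensembles in the tests.
* `tie_binning_experiment()` coarsens a continuous vulnerability ranking
  into `n_bins` **equal-width** intervals over the observed score range
  (fixed intervals, not quantiles, mirroring fixed vulnerability scales),
  randomizes within-bin ties per replicate, and regresses the binned mean
  curve on the continuous one. One bin per distinct equally spaced score is
  exactly the identity ($R^2 = 1$, slope 1); a single bin reduces to the
  random scenario; five bins on a large coupled network stay above
  $R^2 = 0.95$.
* `compare_scenarios()` runs the classical paired t-test on per-network
  mean AUCs, with zero-variance differences flagged degenerate.
* `maturity_sweep()` generates ensembles along the maturity schedule and
  reports Spearman trends of historical- and random-scenario robustness
  against $\tau$; on the shipped generator the historical trend is positive
  and the random trend negative — the adaptation tradeoff the package is
  built to exhibit.

## Reproducibility and numerical choices

Every stochastic function takes an integer seed and derives child seeds
through a fixed counter scheme (`seed`, a stream index and a counter fed
through a Lehmer-style map), so adding one analysis never shifts another's
draws, and whole-object results are bit-reproducible across runs. RNG state
is scoped: package functions never disturb the caller's `.Random.seed`.
Curve conventions (the $H+1$ points including $(1,1)$), trapezoidal
integration, per-step extinction evaluation, the $10^{-6}$ attachment
floor, equal-width binning, $\alpha = 0.05$, and the 0-floored modularity
are all fixed as described above and are not configuration surface.

Study sizes used by the test suite and the acceptance script — ensembles of
100-200 networks at $H = 40$, $P = 60$, 100 disassembly replicates, a
10-level maturity grid with 50 networks per level, $10^4$ Monte-Carlo
replicates against exhaustive oracles on $H \le 6$ fixtures, and a
$200 \times 300$ network for the binning study — were chosen to keep
Monte-Carlo standard errors well inside the asserted margins while running
in seconds on one core.

## Loading external archives

Co-evolved network collections and their historical extinction sequences
are loaded through the generic readers rather than a bespoke parser.
Convert each network to an edge-list CSV with header `host,parasite` (plus
an optional `id,role` node sidecar for uninfected hosts) and each extinction
sequence to a `host,score` CSV in which higher scores mark more vulnerable
hosts (set `higher_is_vulnerable = FALSE` at read time if the source codes
the opposite direction — e.g. survival time instead of extinction order).
The analysis pipeline expects such a converted archive under
`inst/extdata/avida/` as `network_001.csv` ... and `sequence_001.csv` ...;
`validate_inputs()` checks a converted archive before analysis.

## Known limitations

Parasites are treated as if they had simple life cycles; complex cycles
(which lower robustness) are out of scope, as are host-side secondary
extinctions through non-parasite resources, weighted interactions, and any
spatial or recolonization dynamics. The modularity optimizer is a
heuristic: for single networks with near-degenerate module structure,
report `q` with its seed and restart count. Best/worst scenarios are degree
heuristics bounding the practical range, not exact extremal orders over all
$H!$ permutations.
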