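---
title: "Methods: network-based, binless frequency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based, binless frequency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Given a sample $\{x_1,\dots,x_n\}$ of finite reals and a half-width
$\zeta \ge 0$, `netfreq` forms the simple graph with one node per value and
an edge between $i \ne j$ whenever $|x_i - x_j| \le \zeta$. The degree
$d_i$ counts the values similar to $x_i$ and plays the role of a histogram
bar height with a bin *centred on every observation*; the value attaining
$\max_i d_i$ is the mode estimate $M$, with ties resolved by the arithmetic
mean of all tied values. Degree here is, up to the factor $2n\zeta$, a
uniform-kernel density estimate evaluated at the observations; the method
differs from kernel density estimation in how the bandwidth is chosen (graph
stability rather than error minimisation) and in the extra graph structure
it exposes (clusters, path lengths, outliers).

Two structural facts drive the implementation:

* **Interval-graph connectivity.** On a line, connected components are
  exactly the maximal runs of the sorted sample whose consecutive gaps are
  $\le \zeta$. The fast path (`build_network_fast`) computes degrees by
  binary search on the sorted values and clusters by the gap rule, in
  $O(n\log n)$; the reference path (`build_network_reference`) materialises
  the literal adjacency (capped at $n \le 1000$) and exists as a testing
  oracle.
* **Greedy shortest paths.** In a unit interval graph the farthest-reach
  walk is an optimal path, and for a fixed source the distance to nodes on
  its right is a step function whose breakpoints are successive reaches.
  `shortest_paths_interval` accumulates all-pairs path sums from this;
  `shortest_paths_bfs` recomputes them by breadth-first search as the
  independent route. The two are asserted equal on random instances.

## Bandwidth selection

$\zeta$ is swept over a grid, by default 10 equally spaced values from 1% to
10% of the sample median (`default_grid`). The median is the natural scale
statistic for the positively valued data the method targets; when the
median is not positive the span $\max-\min$ replaces it so that the grid
stays positive for any non-constant sample (a constant, non-positive sample
admits no grid and is reported as degenerate rather than an error).

As $\zeta$ grows, edges only appear and clusters only merge, so the edge
count, every degree, and the giant-cluster proportion $p_g = V_g/V$ are
non-decreasing along the grid (tested as properties). Selection
(`select_zeta`) looks for the first run of consecutive grid points over
which the giant-cluster *node count* $V_g$ is identical — integer equality,
deliberately, to avoid float comparisons of $p_g$ — with run length
$\lceil 0.30\,k \rceil$ for a $k$-point grid (clamped to $\ge 2$). The
returned $\zeta_s$ is the *smallest* $\zeta$ of that run: the onset of the
plateau, before the window starts inflating the mode. An optional
`min_pg` gate (off by default) additionally requires the plateau to hold at
least that share of the nodes, e.g. 0.68 by analogy with the one-sigma mass
of a normal distribution. If no run qualifies, the last grid value is
returned with `stable = FALSE` — a reported state, not an error.

The diameter $D$ and mean shortest-path length $L_{avg}$ rise to a peak
(connecting previously disconnected nodes) and then decay to 1 (shortening
existing paths) as $\zeta$ grows; the sweep exposes them as diagnostics
(`with_paths = TRUE`) but never uses them for automatic selection — "at or
shortly after the peak" is a visual rule with no defensible automatic
threshold, so automating it would pretend to a precision the rule lacks.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `zeta_min_frac`, `zeta_max_frac` | 0.01, 0.10 | fraction of median | grid span |
| `zeta_steps` | 10 | – | grid resolution; larger grids need proportionally longer plateaus |
| `window_frac` | 0.30 | fraction of grid | plateau length defining "stable" |
| `min_pg` | off | – | optional minimum giant-cluster share for a plateau |
| `min_prominence_frac` (`local_modes`) | 0.10 | fraction of max degree | secondary-peak shortlist threshold; a package convention with no external definition |
| `fraction` (`subsample`) | – | – | seeded draw *without replacement* for large inputs (reported unweighted) |

## Derived summaries

* $H = \zeta_s / M$: a dimensionless homogeneity index; small values mean
  the stable window is narrow relative to the mode's location. Undefined at
  $M = 0$ (reported as not computable, the run continues).
* $D$: longest shortest path within the largest cluster only. $L_{avg}$:
  mean over *all connected unordered pairs*, across clusters — the
  alternative (giant cluster only) is noted; cross-cluster pairs are
  excluded either way because their distance is infinite.
* Outliers: values outside the giant cluster at $\zeta_s$. Removing them
  and rebuilding at the same $\zeta_s$ cannot change any degree inside the
  giant cluster, so the mode is unchanged **provided the maximum degree is
  attained inside the giant cluster**. That proviso is real: a tight
  secondary cluster that is denser but smaller than the giant one carries
  the mode away with the "outliers". Tests exercise the claim in its
  intended scenario (unimodal core plus isolated extremes).

## The boundary-artifact flag and its limits

For densities that are maximal at the support edge and monotone
(exponential, power law), linking near-equal values fabricates a degree
peak near the edge. `boundary_check` flags a mode within one $\zeta$ of the
sample minimum or maximum. This margin is knife-edge by construction: for a
monotone density the *expected* degree-curve argmax sits about one $\zeta$
inside the edge, but its sampling fluctuation at $n = 100$ spans several
$\zeta$, so the realized mode frequently lands 2–7 $\zeta$ from the
minimum and the flag fires only sporadically (about 10% of seeds for
Exp(1), about 38% for Pareto($\alpha = 2.5$), measured in the acceptance
suite, which keeps the corresponding majority assertion deliberately
failing rather than widening the margin after the fact). When screening
edge-peaked data, inspect the degree-versus-value curve rather than relying
on the flag alone.

## The synthetic-data generator

`simulate_sample` draws seeded samples from a twelve-family catalog:
normal(100, 20) and lognormal$(\mu{=}1, \sigma{=}0.5)$ (the two families
the method's own walkthroughs use), logistic(100, 10), Exp(1),
Pareto($x_{min}{=}1, \alpha{=}2.5$), uniform(0, 1), gamma(2, rate 0.5),
beta(2, 5), Weibull(1.5, 10), Gumbel(10, 2), $\chi^2_4$, and an equal
two-component normal mixture N(0,1)/N(10,1) separated by ten standard
deviations. The exact families and parameters of the original
twelve-distribution study are not published in the available text, so this
catalog is a reconstruction fixed once; parameters were chosen to give each
family its textbook shape at $n = 100$ (a distinct interior mode where one
exists, a fat right tail for lognormal/Pareto, well-separated mixture
components). Gumbel and Pareto samplers use inverse-CDF forms since base R
lacks them.

`run_validation` compares the min–max standardised degree curve with the
standardised true density at the sample points; "agreement" is their
Pearson correlation, a numerical surrogate for the visual overlay the
method is usually judged by, and documented as an invention of this
package. A uniform density standardises degenerately (all zero), so its
agreement is reported `NA` rather than a spurious number.

What a green simulation test does **not** establish: behaviour on real
data with measurement error, rounding/heaping, or serial structure; the
generator draws i.i.d. values only, never contaminated or truncated
samples, and agreement at $n = 100$ says nothing about the flag's power
discussed above.

## Numerical choices

* **Simple graph.** The diagonal of the adjacency rule is excluded, so a
  singleton has degree 0, matching "number of connections" and keeping
  outliers at low or nil degree. At $\zeta = 0$ exact duplicates are still
  adjacent ($|x_i-x_j| = 0 \le 0$), permitted and documented.
* **Difference semantics everywhere.** The binary-search bounds are nudged
  until they agree exactly with $|x_i - x_j| \le \zeta$: computing
  $s_i + \zeta$ can round across a boundary value (e.g.
  $\min + (\max-\min)$ can round below $\max$, breaking the complete-graph
  limit), so the guess from `findInterval` is corrected by direct
  difference comparisons. Fast, reference and path routes therefore share
  one adjacency.
* **Deterministic tie-breaks.** Clusters are labelled by their smallest
  member; among equal-size largest clusters the one containing the smallest
  value is the giant. Mode ties average all tied values; degree-curve
  plateaus collapse to a single peak at their tie-average. Everything is
  permutation-invariant (tested).
* **Seeding.** All randomness (simulation, subsampling) flows through
  explicit seed arguments and restores the caller's RNG state afterwards.

## Known limitations

One-dimensional, unweighted, undirected similarity only. The $O(n^2)$
reference and BFS routes are capped (n ≤ 1000 / 3000); beyond that use the
fast routes or seeded subsampling. Bandwidth selection assumes the grid
scale (median or span) is meaningful; heavily heaped or discretised data
can plateau immediately at the smallest $\zeta$. The homogeneity index is
scale-dependent through $M$ and is not defined for $M = 0$; for data
spanning signs, analyse on a shifted or log scale (the CLI's
`--log-transform` records the scale it used).
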