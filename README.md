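# netfreq — network-based, binless frequency analysis

`netfreq` estimates the shape of a one-dimensional distribution without
binning it. Instead of fixed histogram intervals, every value *x<sub>i</sub>*
of a sample {x₁, …, xₙ} gets a window ±ζ around it, and two values are
linked when they fall inside each other's window:

    A_ij = 1  if |x_i − x_j| ≤ ζ   (i ≠ j),   0 otherwise

This is the construction of a similarity network. The degree
d<sub>i</sub> = Σ<sub>j</sub> A<sub>ij</sub> of each value is a binless
analogue of a histogram bar height; the value with the highest degree is the
**mode** M of the distribution (ties are averaged). Because adjacency on a
line is an interval relation, clusters of the network are exactly the
maximal runs of the sorted values whose consecutive gaps are ≤ ζ, which
gives an O(n log n) construction alongside the literal O(n²) oracle.

The half-width ζ is selected automatically: a grid of candidates (1%–10% of
the median by default) is swept, and the chosen ζ<sub>s</sub> is the onset
of the first plateau where the node count of the **giant cluster**
V<sub>g</sub> stays identical over 30% of the grid (stability of
p<sub>g</sub> = V<sub>g</sub>/V). The package then reports:

- **H = ζ<sub>s</sub>/M**, a homogeneity index (small = homogeneous);
- **D** (diameter of the largest cluster) and **L<sub>avg</sub>** (mean
  shortest-path length over connected pairs), network measures of spread;
- **outliers**: values outside the giant cluster, which by construction
  cannot influence the mode;
- a per-value table (value, degree, cluster, outlier and mode-tie flags).

It is aimed at anyone doing exploratory frequency analysis on messy
univariate data — census tract densities, per-state consumption, national
indicators — where means and medians are skewed by heavy tails and fixed-bin
histograms (e.g. Scott's rule, 3.49·σ·n^(−1/3)) blur multi-modal structure.

## Worked example

```r
library(netfreq)
s   <- simulate_sample(dist_spec("normal", list(mean = 100, sd = 20),
                                 n = 100, seed = 1))
res <- run_pipeline(s)
print(res)
```

```
Network-based frequency analysis — normal (n=100, seed=1)
  V = 100, E = 475
  zeta_s = 3.06835 (stable)
  mode M = 109.51 (max degree 18, 1 tied)
  H = 0.0280
  p_g = 0.9400, outliers = 6
  D = 24, L_avg = 6.89
```

Reading: the 100 values form a network with 475 links at the selected
half-width ζ_s ≈ 3.07 (the giant-cluster size was identical over ≥ 3
consecutive grid points, hence "stable"). The most-connected value, 109.51,
has 18 neighbours within ±ζ_s and is the mode estimate; H = 3.07/109.51 ≈
0.028 marks the distribution as homogeneous. 94% of values sit in the giant
cluster; the 6 values outside it are reported as outliers. For comparison,
`scott_bin_width(s)` gives a fixed bin width of 13.51 for the same sample.
The per-value "binless histogram" is in `res$table` (plot `degree` against
`value`); `res$sweep` holds the p_g/E/D/L_avg curves behind the selection.

## Command line

```sh
Rscript -e 'netfreq::nb_cli()' analyze  --input data.csv --column density --out run1
Rscript -e 'netfreq::nb_cli()' sweep    --input data.csv --column 1 --zeta-steps 20
Rscript -e 'netfreq::nb_cli()' validate --n 100 --seed 7 --out study
Rscript -e 'netfreq::nb_cli()' simulate --family lognormal --n 500 --seed 3
```

`analyze` writes `<out>_summary.csv` / `.json` (columns V, E, zeta_s, M, H,
p_g, D, L_avg, …) and `<out>_values.csv`. Common flags: `--zeta-min-frac`,
`--zeta-max-frac`, `--zeta-steps`, `--window-frac`, `--min-pg`,
`--sample-fraction` (seeded subsampling without replacement for large
files), `--seed`, `--log-transform`, `--config FILE` (key=value lines
mirroring every flag). `inst/exec/netfreq` is an equivalent Rscript entry
point.

## Simulation study

`run_validation()` draws seeded samples from a twelve-family catalog
(normal, lognormal, logistic, exponential, power/Pareto, uniform, gamma,
beta, Weibull, Gumbel, chi-square, two-component normal mixture), runs the
full pipeline on each, and correlates the min-max-standardised degree curve
with the standardised true density at the sample points. Families whose
density peaks at the support edge (exponential, power) are where the method
fabricates boundary peaks; see the methods vignette for how these are
flagged and for the limits of that flag.

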