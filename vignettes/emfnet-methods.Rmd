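---
title: "Methods: multifunctionality, co-occurrence networks and path analysis in emfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifunctionality, co-occurrence networks and path analysis in emfnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emfnet)
```

emfnet implements a complete plot-network analysis linking above- and
below-ground biodiversity to ecosystem multifunctionality (EMF): it
quantifies four ecosystem functions per forest plot, averages them into an
EMF index, runs the multithreshold diversity–multifunctionality analysis,
builds microbial co-occurrence networks with random-matrix-theory (RMT)
threshold selection, scores per-sample subnetwork complexity, and relates
everything through regression, random-forest importance and recursive path
analysis. This vignette explains each model, its assumptions, the tunable
parameters and their defaults, and the design choices made where the
methodology was genuinely open.

## Ecosystem functions and the EMF index

Four functions are computed per 20 m × 20 m plot:

* **Biomass production** — above-ground biomass (AGB) of all woody stems
  with DBH ≥ 1 cm, from the allometric power law
  $\mathrm{AGB} = [0.0673\,(WD \cdot DBH^2 \cdot H)^{0.976}] \times 25/1000$
  with wood density $WD$ (g cm⁻³), diameter $DBH$ (cm) and height $H$ (m).
  The trailing factor converts a per-plot kilogram total to t hm⁻²
  (25 plots of 400 m² per hectare, 1000 kg per tonne); the formula is
  applied verbatim, summed over a plot's stems.
* **Carbon stock** — soil organic carbon stock
  $\mathrm{SOCS} = 0.1\,c\,d\,r\,(1 - D)$ (t hm⁻²) from carbon content $c$
  (g kg⁻¹), bulk density $d$ (g cm⁻³), layer thickness $r$ (cm, default
  20 cm sampling depth) and volumetric gravel fraction $D$.
* **Nutrient cycling** — a composite of six soil nutrient pools (TN, TP,
  TK, HN, AP, AK): each column is z-scored and the per-plot mean taken.
  Averaging exactly four function scores requires condensing the six
  nutrients first; the alternative of letting all six enter as separate
  functions (nine in total) is exposed via
  `compute_functions(..., composite = FALSE)`, since either reading is
  defensible.
* **Water regulation** — soil water-holding capacity (SWHC), used directly.

The **averaging approach** z-scores the four columns across plots (sample
standard deviation, denominator $n-1$, the convention of mainstream
statistical environments) and takes the per-plot mean. Zero-variance
function columns are an error rather than being silently dropped, because
dropping changes the definition of the index. EMF is invariant to any
positive affine rescaling of a raw function — z-scoring absorbs units —
which the test suite asserts numerically.

## The multithreshold analysis

The averaging approach hides trade-offs: a plot can score a high mean while
no single function is near its maximum. The **multithreshold approach**
rescales each function to $[0,1]$ by its observed range and, for every
threshold $t$ on a grid, counts the functions of each plot at or above $t$
(the MFt index), then regresses that count on a diversity predictor by OLS.
The slope curve over thresholds is summarised by:

* $T_{min}$, $T_{max}$ — smallest and largest grid threshold with a
  significant slope ($p < \alpha$, default $\alpha = 0.05$),
* $T_{mde}$ — the significant threshold of maximal $|$slope$|$ (ties break
  to the smaller threshold),
* $R_{mde}$ — the signed slope at $T_{mde}$, in functions per unit of
  diversity (e.g. per liana species).

Defaults: grid 1 %–99 % in 1 % steps (matching the percent-labelled
convention of threshold plots), linear OLS with normal-theory 95 % CIs.
Counts are small integers, so a quasi-Poisson GLM family is exposed
(`family = "quasipoisson"`) but not default — the slope is reported as a
linear "functions per species" effect. Two conventions are deliberately
pinned down because the literature varies: the threshold is compared with
`>=`, and the per-function maximum is the single observed maximum
(`max_method = "top_mean"` anchors on the mean of the top 5 % instead, a
guard against one outlier plot defining the scale). When no threshold is
significant all four summary fields are absent rather than zero. A constant
count response (e.g. every plot passing every function) gives slope 0 and
$p = 1$: no detectable effect, not an error.

## Co-occurrence networks with RMT thresholding

OTUs with overall relative abundance strictly above 0.01 % are retained;
pairwise mid-rank Spearman correlations are computed on per-sample
proportions (Spearman is invariant to monotone per-sample scaling, so
counts and proportions agree when depths are equal — proportions are the
safer default for real, unevenly sequenced data). Two-sided p-values use
the t approximation and are Benjamini–Hochberg adjusted over the upper
triangle. An edge requires **both** $|\rho| \ge$ threshold **and**
BH $q < 0.05$ — the two filters are coupled because both are stated for the
method, though whether the original workflow applied them jointly is
ambiguous; either filter can be relaxed through its argument.

The similarity threshold is selected by random matrix theory. For each
candidate $t$ (default scan 0.30–0.99, step 0.01) the correlation matrix is
hard-thresholded, its eigenvalue spectrum unfolded by Gaussian broadening
of the cumulative spectral function (bandwidth 2.5 × the mean level
spacing), and the nearest-neighbour spacing distribution (NNSD) tested by
chi-square (40 bins, bins − 1 d.o.f.) against the Poisson law $e^{-s}$.
Below the transition the spectrum shows Wigner/GOE level repulsion
(correlated noise); the selected threshold is the smallest $t$ whose NNSD
is Poisson-compatible ($p > 0.05$). All knobs (bandwidth factor, bin count,
scan grid, compatibility level) are exposed. The full scan trace is always
returned; when no candidate passes, the scan reports a `no-selection`
status instead of guessing. Fixed thresholds (e.g. the published 0.850 for
bacteria and 0.540 for fungi) can be supplied directly via
`rmt_fixed` in the pipeline configuration, bypassing the scan. The NNSD is
meaningless for tiny matrices; fewer than 20 OTUs is an error.

**Per-sample complexity.** Each sample's subnetwork is the induced subgraph
on the OTUs present (count > 0) in that sample. Topology metrics are node
and edge counts, average degree $2E/N$, mean local clustering (degree < 2
nodes contribute 0), average path length and diameter on the largest
connected component, graph density, and modularity of a deterministic
greedy (fast-greedy) partition — chosen because the partition is
reproducible without a seed, where Louvain-style algorithms are not.
Average path length and diameter shrink as networks get denser, so they are
replaced by their reciprocal $1/x$ (larger = more complex); all metrics are
then $\log_{10}(x+1)$-transformed for normality, z-scored across samples,
and condensed by classical (Torgerson) metric MDS on Euclidean distances.
The first axis, sign-oriented to correlate positively with average degree,
is the complexity composite (BNC for bacteria, FNC for fungi). Degenerate
cases are defined rather than left to error: a largest component with fewer
than 2 nodes has path length and diameter 0, and the reciprocal maps
$x \le 0$ to 0; constant metric columns are dropped with a warning
(all-constant input is an error).

## Association analyses

* **OLS fits** of EMF (or single functions) on each predictor are produced
  at degree 1 and 2, with raw and standardized coefficients; the
  lower-AIC shape is flagged rather than deciding a priori which
  predictors may be hump-shaped.
* **Correlation heatmap**: pairwise Spearman correlations between all
  predictor and function columns, BH-adjusted over all cells. (The display
  style this emulates sometimes pairs a Mantel test with Pearson cells;
  plain pairwise correlation is the default here.)
* **Random-forest importance**: a 500-tree regression forest (one-third of
  features tried per split), reporting per-feature permutation importance
  as the percent increase in out-of-bag MSE,
  $100 \cdot \Delta\mathrm{MSE}_{perm} / \mathrm{MSE}_{OOB}$,
  deterministic given the seed.

## Recursive path analysis

The structural model is observed-variable path analysis on z-scored data:
each endogenous variable is regressed on its parents, which for a recursive
(acyclic) system with independent errors is the maximum-likelihood
estimator, and the coefficients are standardized path coefficients.
Residual variances are method-of-moments on the correlation matrix, so a
saturated model reproduces the observed covariance exactly. Global fit uses
the ML discrepancy: $\chi^2 = (n-1)\,[\ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1})
- \ln|S| - p]$ with $\Sigma = (I-B)^{-1}\Psi(I-B)^{-T}$, free covariances
among exogenous variables, GFI $= 1 - \mathrm{tr}[(\Sigma^{-1}S - I)^2] /
\mathrm{tr}[(\Sigma^{-1}S)^2]$ and RMSEA
$= \sqrt{\max(\chi^2 - df, 0) / (df\,(n-1))}$, reported as 0 for saturated
models ($df = 0$). Direct effects are edge coefficients; indirect effects
sum coefficient products over all directed paths of length ≥ 2, computed
through the nilpotent series $(I-B)^{-1} - I$. Latent-variable measurement
models are out of scope: the near-saturated fit reported for this class of
analysis is consistent with indicator-level wiring, and
`default_emf_path_spec()` is documented as an editable default — the exact
indicator-level edge list of such diagrams is never fully enumerable from a
figure, so any edge list can be passed as plain `"A -> B"` lines.

## The synthetic-data generator

Plot and soil data of this kind are rarely deposited, so the package ships
a generator whose defaults are the study conditions: 75 plots, a recursive
driver model with standardized coefficients (TSR → EMF 0.306, LSR → EMF
−0.450, BNC → EMF 0.471, FNC → EMF −0.20, diversity → complexity 0.50,
environment → LSR/FNC −0.30 — signs and magnitudes typical of reported
tropical-forest path analyses), four function drivers loading 0.9 on the
latent EMF, and modular OTU tables (bacteria 120 OTUs / 4 modules, fungi
80 OTUs / 4 modules, within-module latent correlation 0.8). Exogenous
variables are unit-variance Gaussians and each endogenous variable's noise
is scaled so its population variance is 1, making generative coefficients
directly comparable to standardized estimates. Counts arise by
rank-preserving quantile mapping of the latent Gaussians onto
negative-binomial marginals (lognormal per-OTU means, dispersion
configurable), which preserves the Spearman copula the network stage
consumes. Stem inventories are drawn per plot and heights rescaled so plot
AGB equals its generative target exactly (biomass scales as $H^{0.976}$,
and rescaling height — not DBH — cannot violate the DBH ≥ 1 cm inventory
rule). All randomness flows from one integer seed through derived
sub-streams; identical (config, seed) is byte-identical.

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real data: compositional closure (counts are
generated on an absolute latent scale; real sequencing data are
compositional, and dividing by depth can induce spurious between-module
correlations — recovery tests therefore correlate counts directly),
spatial autocorrelation among plots (plots are exchangeable; the three
1-hm² sites are not modelled), phylogenetic signal in taxonomy (phylum
labels follow modules), and sequencing-level noise (no read simulation,
chimeras or clustering).

## Numerical choices and problem sizes

Tolerances: standardized matrices are validated to |mean| < 1e−8 and
|sd − 1| < 1e−8; the saturated path model reproduces $S$ to χ² < 1e−8;
graph metrics match an exhaustive Floyd–Warshall/triangle oracle to 1e−12
on small graphs. Ties: mid-ranks in Spearman, smallest threshold on
$|$slope$|$ ties in $T_{mde}$, first-listed feature order in forests.
The test suite exercises the study scale directly — 75-plot recovery runs
(100 repetitions for the multithreshold sign, 200 for path-coefficient
bias), a 200-sample × 100-OTU RMT recovery with a step-0.001 dense-scan
cross-check, and a full double pipeline run for byte-identical
determinism — sizes chosen to keep each property comfortably estimable
while the whole suite stays fast.

## Known limitations

* RMT selection on small, strongly modular matrices tends to select the
  threshold where within-module correlation blocks fragment, which can sit
  well above the noise scale; the full trace is returned so users can
  inspect the transition.
* The chi-square NNSD test uses fixed equal-width bins; very long spacing
  tails thin the expected counts per bin, making the test conservative.
* Permutation importances can be slightly negative for uninformative
  features; they are reported as computed, not truncated at zero.
* The path model assumes linearity and independent errors; hump-shaped
  relationships detected by the quadratic OLS fits are not representable
  in the path diagram.
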