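# emfnet

Biodiversity–ecosystem multifunctionality analysis for forest plot
networks, with microbial co-occurrence networks as a mediating layer.

Field studies of tropical forest plots increasingly ask not whether
diversity raises a single function, but whether plant diversity, soil
microbial diversity and the *structure* of the soil community together
sustain many functions at once. emfnet implements that full analysis for
plot-level data — a stem inventory, a soil table and bacterial/fungal OTU
tables per plot — and ships a seeded synthetic-data generator with known
ground truth, so every stage is testable end to end.

The pipeline:

1. **Ecosystem functions and EMF.** Biomass production from the allometric
   law AGB = [0.0673·(WD·DBH²·H)^0.976]·25/1000 (t hm⁻²) summed over stems
   with DBH ≥ 1 cm; carbon stock SOCS = 0.1·c·d·r·(1−D); a nutrient-cycling
   composite (mean of six z-scored nutrient pools); water-holding capacity.
   EMF is the per-plot mean of the four z-scored functions.
2. **Multithreshold analysis.** At every threshold t (1–99 %), the number
   of functions a plot holds above t × (function maximum) is regressed on
   a diversity predictor; the slope curve is summarised by Tmin, Tmax,
   Tmde and Rmde.
3. **Co-occurrence networks.** Spearman correlations among OTUs (> 0.01 %
   relative abundance), similarity threshold selected by random matrix
   theory (the smallest cutoff whose eigenvalue spacing distribution is
   Poisson-compatible), edges additionally filtered at BH q < 0.05.
   Per-sample subnetwork topology is condensed by classical MDS into one
   complexity score per sample (BNC/FNC).
4. **Drivers of EMF.** Linear/quadratic OLS fits, an FDR-corrected
   correlation heatmap, random-forest permutation importance (% increase
   in OOB MSE), and a recursive path model with standardized coefficients
   and ML fit indices (χ², GFI, RMSEA) plus direct/indirect effect
   decomposition.

See `vignettes/emfnet-methods.Rmd` for the models, assumptions, parameter
defaults and design decisions.

## Worked example

```r
library(emfnet)

ds  <- generate_dataset(seed = 42)                 # 75 synthetic plots
fm  <- compute_functions(ds$stems, ds$plots)       # plots x 4 functions
emf <- emf_average(standardize_functions(fm))      # averaged EMF index

# does liana species richness depress multifunctionality?
mt <- multithreshold_analysis(fm, ds$plots$lsr, predictor_name = "LSR")
mt$summary
#> Multithreshold summary for LSR (alpha = 0.05):
#>   Tmin = 0.39  Tmax = 0.62  Tmde = 0.60  Rmde = -0.1005
```

Liana richness has a significant negative effect between the 39 % and 62 %
thresholds; at its strongest (60 %), one extra liana species costs about
0.10 functions. The bacterial network and its per-sample complexity:

```r
filt <- filter_otus(ds$bacterial_otus)             # > 0.01% abundance
corr <- spearman_matrix(filt)
scan <- rmt_threshold(corr$rho)
scan
#> RMT threshold scan: selected t = 0.320 (NNSD Poisson p = 0.232)
#>   scanned 70 thresholds in [0.300, 0.990]

net <- build_network(corr, scan$threshold)
topology(net)
#> Topology: 120 nodes, 2091 edges | avg degree 34.850, clustering 0.836,
#>   avg path length 2.042, diameter 3, density 0.293, modularity 0.562

bnc <- subnetwork_complexity(net, filt)            # one score per plot
```

`run_pipeline(list(seed = 1, out_dir = "run"))` executes every stage and
writes one TSV per output plus a `manifest.json` with content hashes;
re-running the same configuration is byte-identical. A thin CLI wrapper
with per-stage subcommands lives at `inst/cli/emfnet.R`.

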