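# seascaper

Seascape genetics of clonal marine plants: from microsatellite genotypes,
simulated propagule dispersal and habitat covariates to a variance
partitioning of genetic differentiation.

## What it is for

Partially clonal marine plants such as tropical seagrasses disperse with
ocean currents, and their population structure at scales of tens of
kilometres reflects a mix of geographic distance, oceanographic
connectivity and local habitat filtering.  `seascaper` implements the full
inferential chain a seascape-genetics study of such a species needs:

* **Clonal diversity** — multilocus genotype (MLG) assignment with strict or
  wildcard missing-data matching, clonal richness *R* = (*G* − 1)/(*N* − 1),
  probability of identity (PID, PID×N), *P*<sub>gen</sub>/*P*<sub>sex</sub>
  clone-mate tests, observed and Nei unbiased heterozygosity, rarefied
  allelic and private-allele richness, Weir–Cockerham *F*<sub>IS</sub> with
  permutation tests, Kalinowski–Taper null-allele maximum likelihood, and the
  standardized index of association r̄<sub>d</sub>.
* **Differentiation** — multi-allelic Weir–Cockerham *F*<sub>ST</sub>
  (global and pairwise, permutation-tested), Rousset linearization
  *F*/(1 − *F*), the *G*<sub>ST</sub>–*H*<sub>S</sub> mutation-bias
  correlation, Smouse–Peakall individual spatial autocorrelation over
  distance classes, and the Evanno ΔK statistic on clustering
  log-likelihoods.
* **Dispersal** — Lagrangian particle tracking on gridded hourly currents
  (RK4 sub-stepping, bilinear/linear interpolation, 1 m²/s random walk,
  7-day competency window, 500-m detection cells) producing a directed
  site-by-site connectivity matrix; least-cost overwater distances on the
  sea-cell graph.
* **Seascape inference** — network metrics (strength, closeness,
  betweenness, transitivity) compressed by PCA into the OC block, PCNM
  spatial eigenvectors as the GD block, correspondence analysis of encoded
  habitat data as the EN block, Gower dissimilarity, Mantel tests, PCoA of
  linearized *F*<sub>ST</sub> as the GS response, and partial redundancy
  analysis with adjusted-*R*² variance partitioning of
  `GS ~ GD + OC + EN` (marginal and conditional effects, permutation
  *F*-tests, inclusion–exclusion shared fractions).
* **Synthetic data** — Balding–Nichols genotype simulation with inbreeding
  and clonality, analytic velocity-field presets, and grouped environmental
  covariates, all seeded and with truth records, so the whole chain is
  testable without field data or a hydrodynamic hindcast.

Everything user-facing takes and returns data frames (tibbles) so calls
chain with the pipe; site-by-site matrices are labelled base matrices, the
form `vegan` and `igraph` consume.

## Worked example

```r
library(seascaper)

# clone detection on the bundled synthetic example
gt <- read_genotypes(system.file("extdata", "synthetic_genotypes.csv",
                                 package = "seascaper"))
identify_mlgs(gt, missing_policy = "permissive")
#> # MLG partition (permissive): N = 30, G = 17, R = 0.552
#> # A tibble: 3 × 4
#>   site_id     N     G     R
#> 1 S01        10     6 0.556
#> 2 S02        10     7 0.667
#> 3 S03        10     4 0.333

# an end-to-end synthetic scenario: two genetic clusters interleaved in
# space, connectivity and environment aligned with the clusters
sites <- simulate_sites(12, "interleaved", seed = 11)
sim   <- simulate_genotypes(12, samples_per_site = 48, n_loci = 16,
                            theta = 0.05, groups = sites$region,
                            theta_between = 0.25, clonality = 0.3, f = 0.1,
                            seed = 12)
env   <- simulate_environment(sites, "grouped", seed = 13)
conn  <- simulate_connectivity(sites, seed = 14)

report <- run_full_analysis(sim$genotypes, sites, env, conn,
                            config = analysis_config(seed = 1, n_perm = 999))
report
#> # Seascape-genetics run report
#>   sites analysed: 12 (none dropped)
#>   global F_ST = 0.209 (p = 0.001)
#> # Variance partitioning (n = 12 sites, 999 permutations)
#>  block      effect adj_r2_pct df_model df_residual           F p_value
#>     GD    marginal     -35.97        3           8  0.03004838   1.000
#>     GD conditional      -4.00        3           2  0.50546925   0.885
#>     OC    marginal      88.50        3           8 29.20570117   0.001
#>     OC conditional      -2.11        3           2  0.73897763   0.704
#>     EN    marginal      90.33        3           8 35.23648011   0.003
#>     EN conditional       1.94        3           2  1.23981090   0.412
#>   residual (adjusted): 13.49%
```

The reading: oceanographic connectivity (OC) and environment (EN) each
explain most of the variance in genetic structure on their own (significant
marginal effects), geographic distance (GD) explains essentially none, and
no block retains a significant unique fraction once the others are
controlled — the drivers act jointly, not independently.  `tidy()`,
`glance()` and `autoplot()` methods expose the fitted objects for further
work, and `write_report()` serializes every table.

A command-line wrapper for the same pipeline is at
`inst/scripts/run_pipeline.R` (`--simulate` or CSV inputs).

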