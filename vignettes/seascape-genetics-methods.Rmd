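---
title: "Methods: clonal diversity, dispersal and variance partitioning in seascaper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal diversity, dispersal and variance partitioning in seascaper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`seascaper` estimates how geographic distance, oceanographic connectivity
and local habitat jointly shape the genetic structure of a partially
clonal, current-dispersed marine plant sampled at a set of sites and
genotyped at codominant microsatellite loci.  This vignette records the
models, the parameters that matter, the numerical choices, and what the
synthetic data generator does and does not emulate.

## Clone detection and clonal diversity

Samples sharing a multilocus genotype (MLG) are putative ramets of one
genet.  `identify_mlgs()` offers two missing-data policies.  Under
`strict`, two samples share an MLG only if they agree at every locus and
neither has missing data; incompletely genotyped samples become
singletons.  Under `permissive`, a missing locus is a wildcard and clone
groups are connected components of the pairwise-compatibility graph
(transitive closure, union–find).  Wildcarding can chain genuinely
different genotypes through an intermediate sample, which is why both
policies exist; `strict` never merges wrongly but over-splits whenever
missingness is present.  MLG labels follow first appearance in row order,
so output is deterministic.  Samples missing every locus are flagged
unassignable and excluded from *G*.

Clonal richness is *R* = (*G* − 1)/(*N* − 1): 0 for a monoclonal stand, 1
when every sample is distinct.  The power of the marker panel to
distinguish genets is summarised by the per-locus probability of identity
PID$_\ell = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2$, multiplied over loci
(the standard multi-allele form; the sib-corrected variant is deliberately
not the default because the panel-power question concerns unrelated
genets).  PID×N, the expected number of chance-duplicate genotypes among
*N* samples, is reported alongside.

Whether *n* copies of one MLG could instead be *n* independent sexual
events is tested with
$P_{sex} = P[X \ge n-1]$, $X \sim \mathrm{Binomial}(N-1, P_{gen})$, where
$P_{gen}$ is the genotype probability with round-robin inbreeding
correction ($p_i^2 + f p_i(1-p_i)$ for homozygotes,
$2 p_i p_j (1 - f)$ for heterozygotes, *f* clamped at 0).  The
conventional clone-mate call is $P_{sex} < 0.05$.

Per-site diversity uses observed heterozygosity, Nei's unbiased expected
heterozygosity $\frac{2n}{2n-1}(1 - \sum p_i^2)$, and the multi-locus
Weir–Cockerham $F_{IS}$ from within-population variance components, with a
two-sided permutation test that shuffles gene copies among individuals
within the site (default 999; the pipeline uses 199, which resolves
p-values to 0.005).  Allelic richness is hypergeometric rarefaction on
gene copies standardized to *g* diploid individuals (2*g* genes; default
*g* = 14, a typical minimum MLG count per site, with 20 as the common
alternative); private-allele richness follows Kalinowski's generalized
rarefaction across the site set.  Rarefaction on MLGs rather than raw
samples reflects that diversity statistics are computed after clone
correction — downstream statistics use one ramet per genet per site.

Null alleles are fitted per locus by an EM maximization of the
Kalinowski–Taper model: observed homozygotes are a mixture of true
homozygotes and visible×null heterozygotes, blanks a mixture of null
homozygotes and an amplification-failure rate β.  Convergence is declared
when the log-likelihood moves by less than 1e-8 (capped at 1000
iterations); non-convergence is flagged, never raised.  Significance of a
positive null frequency is a boundary-corrected likelihood-ratio test,
with a parametric bootstrap option (default 1000 replicates) for small
samples where the χ² approximation is doubtful.

Multilocus linkage disequilibrium uses the standardized index of
association $\bar r_d = \sum_{\ell<m} \mathrm{cov}(d_\ell, d_m) /
\sum_{\ell<m} \sqrt{\mathrm{var}(d_\ell)\,\mathrm{var}(d_m)}$ on per-locus
pairwise allele-mismatch counts (0/1/2).  Pairs with a missing locus take
that locus's mean distance; the permutation null shuffles each locus's
diploid genotypes among individuals independently, which preserves
single-locus structure while destroying inter-locus association.

## Differentiation

$F_{ST}$ is the Weir–Cockerham θ: variance components *a*, *b*, *c*
summed over alleles and loci, $\hat\theta = \sum a / \sum(a+b+c)$, with
$F_{IS}$ and $F_{IT}$ from the same components.  Pairwise values come from
two-site subsets.  The permutation unit is the individual MLG (site labels
shuffled), with the add-one correction
$p = (\mathrm{hits}+1)/(n_{perm}+1)$; permuting individuals rather than
alleles respects the non-independence of the two gene copies within an
individual under inbreeding.  Sites below a minimum genotype count
(default 2 for estimation; the pipeline excludes sites with fewer than 6
MLGs from all genetic stages, a generalization of excluding effectively
monoclonal stands) are dropped with a warning.  Negative pairwise
estimates are reported raw but clamped to 0 before Rousset linearization
$F/(1-F)$, which requires nonnegative input; $F = 1$ is an error.

The mutation-bias diagnostic correlates per-locus Nei $G_{ST}$ with
$H_S$; a significantly negative correlation warns that high-mutation loci
depress the differentiation estimate.  Because the resampling scheme of
the original program is not published, significance here is a two-sided
bootstrap over loci — the locus is the natural resampling unit for an
across-locus correlation.

Individual spatial autocorrelation follows Smouse–Peakall: per-locus
squared genetic distances from allele-count coding
($d^2 = \tfrac12\sum_a \Delta_a^2$, giving the canonical genotype-pair
values 0/1/2/3/4), summed over loci, Gower-centered into a codistance
matrix, and summarized per geographic distance class as
$r = c_{xy}/c_{xx}$ (off-diagonal over diagonal codistance sums of the
pairs in the class).  Distance classes are half-open $(\mathrm{lower},
\mathrm{upper}]$ intervals; the default endpoints (0.01, 0.025, 0.05, 5,
10, 15, 20, 25, 30, 35, 45, 60 km) resolve the within-meadow scale first.
The heterogeneity envelope permutes individual locations (default 999 in
tests; 9999 is the conventional publication setting) and the confidence
interval bootstraps pairs within each class.  Loci missing in a pair
contribute that locus's mean over complete pairs — a compromise that keeps
the codistance matrix complete without imputing genotypes.

The Evanno ΔK statistic,
$|\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / \mathrm{sd}(L(K))$, is
computed on a user-supplied runs-by-K log-likelihood table; the Bayesian
clustering runs themselves are outside this package's scope.  Zero
standard deviation at some K leaves ΔK undefined there (flagged `NA`, not
an error).

## Dispersal simulation

`advect()` integrates particle positions through gridded hourly surface
currents with a classical RK4 scheme, each hour split into `substeps`
(default 4) sub-intervals, velocities interpolated bilinearly in space and
linearly in time.  Masked (land) cells carry zero velocity, so speeds
taper toward the coast.  After each hour an isotropic random-walk kick
$\sqrt{2 K \Delta t}\, z$ per axis (default $K = 1$ m²/s) models
unresolved turbulence; applying it once per hour, not per RK4 substage,
keeps the noise process well defined (the integrated variance is
independent of the substep count).  The default land policy `freeze`
discards a sub-step or kick that would land on a masked cell — the
particle may move again later; `beach` removes it permanently.  The choice
matters in narrow channels; `freeze` is the default because permanent
beaching of a propagule that merely grazes the coast is biologically too
strict for a buoyant fruit.

A release schedule seeds 100 particles per site (default) every 3 days
within the fruiting season, each tracked for 168 h (the 2–7 day competency
window, taken at its upper end).  Detection uses a 500 m × 500 m
axis-aligned cell centred on each site, tested on hourly fixes only, and a
particle counts at most once per (release, target site).  Connectivity is
the per-release average count from site *i* detected at site *j* — a
directed matrix.  Both the once-per-release counting rule and the
diagonal (self-recruitment) policy are explicit flags, since either
convention is defensible.  With hourly fixes, a fast particle
(≳ 0.14 m/s) can cross a 500 m cell between fixes; detection is therefore
slightly conservative for strong flows, consistently so across site pairs.

Overwater distances are Dijkstra shortest paths on the graph of sea cells
(8- or 16-neighbour; 16 by default, whose worst-case discretization
overestimate is about 2.8%), edge weights the planar or great-circle
distance between cell centres.  Sites snap to the nearest sea cell within
2 cells; failure to snap is an error, and disconnected pairs return `Inf`
with a warning.

## The seascape inference

The response block GS is the principal-coordinate embedding of linearized
$F_{ST}$ (Gower double-centering of $-\tfrac12 D^2$; axes kept when their
eigenvalue exceeds 1e-8 of the largest — linearized $F_{ST}$ is generally
non-Euclidean and negative eigenvalues are expected and discarded).

The three predictor blocks:

* **GD** — PCNM spatial eigenvectors of the geographic distance matrix
  (distances beyond the truncation threshold replaced by 4× the threshold;
  default threshold the longest minimum-spanning-tree edge, via
  `vegan::pcnm`).  The first 3 axes are retained by default; a
  collinearity screen against GS (keeping axes whose maximum |r| with the
  response stays below a threshold) is available, since selecting spatial
  predictors already collinear with the response would make the spatial
  fraction circular.
* **OC** — strength, closeness, betweenness and local transitivity of the
  weighted directed connectivity graph, centred, scaled and compressed by
  PCA (3 axes by default).  Shortest-path metrics default to treating the
  raw weight as the edge cost (`cost_raw`), replicating the convention of
  the software lineage this analysis descends from, under which high
  closeness/betweenness flag isolated sites; `cost_inverse` (1/weight) is
  the semantically conventional alternative.  Transitivity is computed on
  the binarized undirected graph; zero weights are absent edges, because a
  zero-cost edge would collapse all shortest paths.
* **EN** — habitat covariates one-hot encoded (categoricals and booleans)
  with numeric columns range-scaled to [0, 1], then a correspondence
  analysis (SVD of standardized residuals of the profile matrix); 3 axes
  by default.  Range-scaling before CA is the package's resolution of an
  under-specified step: it puts numeric columns on the nonnegative,
  comparable footing CA requires without inventing pseudo-counts.

Variance partitioning fits redundancy analyses for all seven block
unions.  $R^2$ is the fraction of total response variance captured by the
fitted values; adjusted values use Ezekiel's formula
$1 - (1-R^2)(n-1)/(n-m-1)$ with *m* the QR rank of the predictors, and
conditional (unique) fractions are differences of adjusted $R^2$ of nested
models (the Peres-Neto convention).  Marginal tests permute response rows;
conditional tests permute reduced-model residuals — the standard scheme
where the conditioning structure must be preserved.  Negative adjusted
fractions are reported as computed, not floored, and the unadjusted
unique + shared + residual fractions sum to 1 to numerical precision (an
invariant under test).  Collinear predictor columns are dropped by QR
pivot with a warning.  Mantel tests of each raw driver matrix against
linearized $F_{ST}$ (via `vegan::mantel`) are reported alongside, for
continuity with the older inferential style; the partitioning is the
primary inference, being robust to the spurious-correlation failure modes
of Mantel tests on spatially structured data.  For the connectivity
driver, the Mantel matrix is the pairwise total ($C + C^T$, diagonal
excluded) by default, both conventions being available.

## The synthetic-data generator

`simulate_genotypes()` draws site allele frequencies from the
Balding–Nichols model — Dirichlet ancestral frequencies, site frequencies
$\mathrm{Beta}\!\big(p\tfrac{1-\theta}{\theta}, (1-p)\tfrac{1-\theta}{\theta}\big)$
per allele (generalized to the multi-allele Dirichlet) — so the expected
Weir–Cockerham θ equals the `theta` parameter.  Defaults mirror the
sampling design the package targets: 48 samples per site, 16 loci, θ = 0.2
(the study-scale global differentiation), inbreeding *f* = 0.1, and allele
states mapped to even sizes in locus-specific windows to resemble
dinucleotide repeats.  A two-level `groups` mode nests site-level θ within
group-level θ for hierarchical structure.  Clonality copies a previous
same-site sample's genotype with probability `clonality` and then re-draws
missingness independently, so MLG matching under discordant missing
patterns is exercised — the reason the pipeline defaults to `permissive`
matching.  Inbreeding is implemented as an autozygosity mixture
(probability *f* of a forced homozygote), which reproduces the target
$F_{IS}$ without distorting allele frequencies.

`simulate_velocity_field()` provides analytic presets — uniform flow,
solid rotation, and a tidal channel (residual plus sinusoid, default
amplitude 1 m/s, period 12 h, on a 2 km grid) — chosen because each has a
closed-form trajectory against which the integrator is verified.
`simulate_environment()` draws the five habitat covariates either
independently of site groups or with group-specific category supports
(sediment the strongest contrast).  `simulate_connectivity()` builds a
group-structured directed matrix with Gamma noise on the 0–7.5
particles-per-release scale, with one group optionally weakly
self-connected (an oceanographically isolated cluster) — the configuration
in which network metrics separate the clusters.

What the generators do **not** emulate: mutation (no stepwise-mutation
size homoplasy, so the $G_{ST}$–$H_S$ diagnostic is null-calibrated only),
linkage, realistic bathymetry or coastlines, seasonal and wind forcing
beyond one sinusoid, genotyping artefacts other than uniform missingness
and null alleles, and isolation-by-distance gradients within groups.
Passing tests therefore demonstrate estimator correctness and pipeline
integrity under the stated models, not robustness to every failure mode of
field data.

## Problem sizes and seeds

The test suite validates estimator recovery at the survey scale (12 sites
× 48 samples × 16 loci, 20 replicate seeds), permutation-test calibration
on 200 null datasets per statistic at 99 permutations, diffusion physics
on 10⁴ particles, and the variance-partitioning signature on 20 replicate
scenarios of 12 sites; unit tests use smaller fixtures with exact or
enumerated oracles.  Every stochastic function takes an explicit integer
seed and is bit-reproducible given it; the pipeline derives stage seeds
from one master seed recorded in the run report.

## Known limitations

With ~11–13 sites the RDA has 3 predictors per block against 10–12
response rows; conditional tests then run on 1–2 residual degrees of
freedom and have little power — a property of the design, visible in the
wide conditional p-values.  Adjusted $R^2$ can be strongly negative for
irrelevant blocks at this *n*.  The EM null-allele fit assumes one locus
at a time and a single panmictic site; Wahlund structure inflates its
estimates.  Permissive MLG matching can merge distinct genets through
heavily missing intermediates.  The dispersal model is two-dimensional
surface drift without behaviour, buoyancy loss or mortality.
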