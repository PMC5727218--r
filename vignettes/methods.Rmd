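---
title: "Models and methods behind peascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

peascape re-implements, as one tested toolchain, the analysis style used to
study crop wild relatives of pea (*Pisum sativum* subsp. *elatius* and
*P. fulvum*) across the Mediterranean: maximum-entropy niche models per taxon
or chloroplast haplotype, niche-overlap similarity testing against
background-randomized nulls, per-cell Shannon diversity of the resulting
suitability surfaces under current and alternative climates, and the
population-genetic statistics that describe the genotypic side — SNP QC,
heterozygosity, Ritland kinship over distance classes, Weir–Cockerham Fst,
and haplotype collapsing with a network. Because the germplasm genotypes,
archived sequences and global climate layers behind such a study are not
desk-reproducible, every stage here runs on synthetic inputs with known
ground truth; this vignette records the models, the defaults, and what the
synthetic conditions do and do not demonstrate.

## The maximum-entropy niche model

The core model is the Gibbs distribution over landscape cells,
$q(x) \propto \exp(w \cdot f(x))$, fitted from presence points against a
background sample by maximizing the penalized presence log-likelihood

$$\frac{1}{n}\sum_{i} w \cdot f(x_i) \;-\; \log \sum_{x \in B} e^{w \cdot f(x)}
\;-\; \sum_j \beta_j |w_j|.$$

Feature set: linear and quadratic terms per environmental layer. Layers are
standardized on the training background and the quadratic term is the square
of the standardized value (itself re-standardized). Building the quadratic
feature from the standardized layer — rather than standardizing the raw
square — is deliberate: it makes the feature basis, and therefore the L1
penalty, exactly invariant to positive affine rescaling of the inputs, so a
layer expressed in °C or in 0.1 °C yields identical fits. Hinge, threshold
and product features are intentionally absent: they break the small convex
core that makes the fit analytically checkable (a single binary feature with
presence mean 0.8 on a half/half background must fit $w = \ln 4$).

The L1 problem is solved exactly by the split $w = u - v$, $u, v \ge 0$,
under L-BFGS-B; convergence is declared only when the KKT moment conditions
$|\bar f_j^{pres} - E_q[f_j]| \le \beta_j + 10^{-6}$ hold for every feature,
and a fit that cannot reach that tolerance errors rather than returning
silently. Regularization defaults to
$\beta_j = \text{reg\_multiplier} \times \text{sd}(f_j)/\sqrt{n}$ with
reg_multiplier 1 — a simplified analogue of the tuned defaults in the
standard Maxent software. The background is a seeded uniform sample of
unmasked cells, default 10,000 (all cells when the grid is smaller).

Output is the raw distribution (sums to 1 over unmasked cells), which is
what the overlap metrics and the Shannon index consume. A cloglog/logistic
"probability of presence" transform is not provided; a min–max display
rescale exists and is labelled as exactly that, because downstream analyses
here only use relative suitability. AUC is the tie-aware Mann–Whitney
statistic of presences against the model's own background sample (training
AUC; no replicate scheme is implemented, since the choice of folds or
bootstraps would be arbitrary here). Permutation importance permutes one
layer's values jointly across the presence and background evaluation points,
recomputes AUC with the fixed model, floors negative mean drops at zero, and
normalizes to percentages summing to 100.

## Niche overlap and the background similarity test

On two raw-normalized maps, Schoener's
$D = 1 - \tfrac12\sum_c |q_A - q_B|$ and the Hellinger-based
$I = 1 - \tfrac12\sum_c (\sqrt{q_A} - \sqrt{q_B})^2$. The similarity test
replaces one taxon's occurrences with the same number of points drawn from
that taxon's Gaussian-filtered background density (kernel in great-circle
distance; bandwidth default 200 km, a free parameter recorded in the output
since the field convention leaves it unstated), refits, and recomputes D and
I against the other taxon's observed model — 100 iterations per direction,
both directions always run and reported separately. Verdicts are two-sided
at $\alpha = 0.05$: observed above the 97.5% null quantile is "similar",
below the 2.5% quantile "divergent", otherwise "ns". A refit failure inside
an iteration is retried up to three times with fresh draws, then recorded as
missing and counted, never silently dropped.

## Per-cell Shannon diversity

Given $K \ge 2$ suitability surfaces, each cell's values are normalized to
proportions $p_i$ and $H' = -\sum_i p_i \ln p_i$ (natural log, $0\ln 0 = 0$)
is mapped. The minus sign is part of the definition used here so that
$H' \in [0, \ln K]$; per-cell normalization is the default because
independently fitted suitability surfaces are not jointly normalized and
only their cell-wise proportions make $H'$ a true Shannon index. The
un-normalized mode is retained for sensitivity analysis and flagged in the
output metadata. Cells whose surfaces sum below `min_total` ($10^{-12}$)
carry no signal and are masked; the scenario-vs-current difference map
reports such newly signal-free cells in a separate "lost cells" tally rather
than as a numeric change.

## Genotype statistics

QC follows the order missingness-then-MAF: drop loci with more than 10%
missing calls, then loci with minor allele frequency at or below 0.05 (the
boundary value is dropped), MAF computed on non-missing calls only; the two
rules are reported separately and the filter is idempotent. Heterozygosity
is the percentage of non-missing calls with dosage 1, per individual.
Species-diagnostic SNPs come from a two-sided Fisher exact test on the 2×2
group-by-allele count table at the genome-wide threshold $5\times10^{-8}$,
with no additional multiple-testing correction (the threshold itself is the
genome-wide control).

Ritland kinship per biallelic locus with counted-allele frequency $p$ and
half-dosages $x_i$ is $x_i x_j/p + (1-x_i)(1-x_j)/(1-p) - 1$, averaged with
equal weights over usable loci; allele frequencies come from the whole
analyzed sample. The spatial profile bins all pairwise great-circle
distances into equal-count classes (the published design fixes both the
class count and the per-class pair count, which is only jointly satisfiable
for one sample size; equal-count binning generalizes it), with ties at bin
edges resolved by a stable sort on distance then pair id. The permutation
null shuffles coordinate assignments among individuals while keeping
genotypes — and hence the kinship matrix — fixed, which is the same null as
shuffling genotypes but cheaper; the envelope is the 2.5/97.5 percentile per
class, and the profile also reports the first class whose mean kinship is
non-positive (the "kinship reaches zero at distance d" summary).

Fst is the Weir–Cockerham (1984) estimator: variance components a, b, c per
locus for each pair of groups, combined as the ratio of sums
$\theta = \sum a / \sum(a+b+c)$, skipping loci monomorphic across the pair.
Centroids are coordinate-wise means of member lon/lat — a planar
approximation that is adequate at the sub-continental extents simulated
here and documented as such; member distances and centroid separations are
great-circle.

All great-circle distances use the haversine formula on a sphere of radius
6371.0 km; the 50-km georeferencing screen and the ~250-km kinship scale
these distances feed do not justify ellipsoidal precision.

## Haplotypes and the network

Character calling treats each alignment column with two or more observed
bases as a SNP character (N missing; a gap in a column is missing for
substitution calling) and each distinct maximal run of `-` as ONE binary
indel character, so a six-bp deletion is a single character and a single
mutational step, and two distinct overlapping runs are two characters.
Collapsing groups sequences identical across all characters, with missing
matching anything; a sequence compatible with several haplotypes joins the
largest and is flagged, never silently assigned. The network is the minimum
spanning network — every edge present in at least one minimum spanning tree
of the pairwise character-distance graph, found by the cut criterion (an
edge belongs to some MST exactly when its endpoints are not connected by
strictly shorter edges). Full median-joining with median vectors is a
documented stretch goal, not implemented: for the low-homoplasy data these
analyses describe, the MSN reproduces the topology and is exactly testable
against brute-force spanning-tree enumeration. Haplotypes carried by more
than one sequence are labelled "major", singletons "unique" — a reporting
label only.

## The synthetic data and what passing means

The generators are pure functions of their configuration; the seed fully
determines every output, and ground truth (true suitability surface, true
population labels and frequencies, true haplotype assignment) is always
returned beside the observable data.

* **Layers**: white noise convolved with a Gaussian kernel (radius
  `autocorr_range` cells, default 4), standardized per layer; the
  alternative-climate stack adds a configured shift (default 1 sd). The
  grids default to 40×40 cells at 0.25° in the eastern Mediterranean —
  large enough for spatial structure, small enough that a full similarity
  test (200 model refits) runs in about a second.
* **Occurrences**: cells drawn with probability proportional to a logistic
  function of the true linear+quadratic score, jittered within the cell.
* **Genotypes**: Balding–Nichols island model (per-locus ancestral
  frequency uniform on 0.1–0.9, Beta-distributed population frequencies at
  the target Fst, default 0.2 as a moderate between-species value), with
  individuals scattered around population centres ~3° apart. Isolation by
  distance is layered on as a per-locus, spatially smoothed perturbation of
  individual allele frequencies (Gaussian kernel over inter-individual
  distance with unit-variance rows), whose amplitude is `ibd_strength` in
  allele-frequency units and whose range defaults to 100 km so that kinship
  decays to zero within a couple hundred kilometres, the scale reported for
  wild pea. `ibd_strength = 0` — the default — switches the overlay off
  entirely and leaves the pure island model; an admixture-weight
  construction was rejected because it cannot express that limit (equal
  weights erase the island structure and the Fst target with it).
  Missingness is completely at random, and optional F1 hybrids draw one
  allele from each parental pool.
* **Alignment**: a stepwise chain of haplotypes over a random reference —
  each haplotype adds one new variant, first the substitutions, then one
  contiguous deletion — so 5 SNPs plus one 6-bp indel define exactly 7
  haplotypes with known membership (the composition of the published
  chloroplast *trnS-G* example).

These conditions are deliberately idealized: no sampling bias or spatial
clustering of collectors, no correlated layer structure like real bioclim
covariance, HWE within demes (so simulated heterozygosities are far above
the near-selfing values seen in real pea), no sequencing error and no
homoplasy. Passing the suite therefore demonstrates the estimators and
algorithms are correct and internally consistent, not that the pipeline is
robust to the biases of real occurrence and germplasm data.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: presences in a single cell, an empty score
set for AUC, a single surface for diversity, a pair with no polymorphic
locus. Quantities with exact contracts are enforced to tight tolerances
(raw maps sum to 1 within $10^{-9}$; KKT within $10^{-6}$). The test and
acceptance runs use scaled-down study sizes chosen to keep each simulated
check seconds-long while leaving the statistics well out of their noise
floors: 20–40 cell grids, 50–200 presences, panels of 300–1000 loci on
40–100 individuals, 50-seed replication for recovery rates. The analysis
scripts under `analysis/` run the same pipeline at slightly larger,
narrative-friendly sizes.

Known limitations: no projected coordinate systems or GeoTIFF I/O, no
hinge/product features or cross-validated AUC replicates, no median
vectors, standard pairwise Weir–Cockerham theta only, and the niche
identity (pooled-resplit) test variant is intentionally absent — only the
background similarity test is implemented.
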