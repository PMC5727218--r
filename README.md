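# peascape

An integrated macroecology + population-genetics toolkit for crop wild
relatives (CWR), built around the analysis style used for wild pea
(*Pisum sativum* subsp. *elatius*, *P. fulvum*) in the Mediterranean Basin.
It is aimed at researchers who want the whole chain — niche models, niche
overlap, diversity mapping and genotype statistics — as ordinary, tested R
functions instead of a constellation of GUI tools.

The package provides:

* **Maximum-entropy niche models** (`fit_maxent`, `project_model`,
  `auc_maxent`, `permutation_importance`): the Gibbs model
  q(x) ∝ exp(w·f(x)) over a background sample, with linear + quadratic
  features, exact L1 regularization and KKT-verified convergence; projection
  onto alternative (e.g. LGM or RCP-style) climate stacks.
* **Niche overlap** (`schoener_D`, `hellinger_I`,
  `background_similarity_test`): D = 1 − ½Σ|q_A − q_B|,
  I = 1 − ½Σ(√q_A − √q_B)², and the two-directional background-randomization
  similarity test (occurrences replaced by draws from a Gaussian-filtered
  background density, 100 refits per direction).
* **Per-cell Shannon diversity** (`shannon_map`, `diversity_difference`):
  H′ = −Σ p_i ln p_i across a stack of suitability surfaces, plus
  scenario-minus-current difference maps.
* **Population genetics** (`filter_snps`, `heterozygosity_percent`,
  `diagnostic_snps`, `ritland_kinship`, `spatial_autocorrelation`,
  `pairwise_fst`, `centroid_distances`): SNP QC (missingness > 10%,
  MAF ≤ 0.05), Fisher-exact diagnostic SNPs at 5×10⁻⁸, Ritland kinship over
  equal-count distance classes with a 100-permutation envelope, and
  Weir–Cockerham θ as the ratio of summed variance components.
* **Haplotypes** (`call_characters`, `collapse_haplotypes`,
  `build_network`): indel-aware character coding (one gap run = one
  character = one step), collapsing with missing-matches-anything, and the
  minimum spanning network (every edge in at least one MST).
* **Simulators** (`sim_config`, `gen_env_layers`, `gen_occurrences`,
  `gen_genotypes`, `gen_alignment`): every input above with known ground
  truth — smoothed-noise climate layers, occurrences from a parametric
  niche, Balding–Nichols genotypes with optional isolation by distance,
  and alignments with planted SNPs and one multi-base indel.

File formats are the field's plain-text standards: ESRI ASCII grids,
`taxon,lon,lat` occurrence CSVs, dosage-matrix CSVs (or VCF via vcfR),
aligned FASTA, GraphML/TSV networks, JSON models and manifests.

## Worked example

```r
library(peascape)

cfg  <- sim_config(seed = 1, grid_rows = 25, grid_cols = 25, n_layers = 2,
                   autocorr_range = 3)
env  <- gen_env_layers(cfg)$current
occ  <- gen_occurrences(env, c(2.5, -1), 200, seed = 2, taxon = "taxonA")
fit  <- fit_maxent(env, clean_occurrences(occ$occurrences)$occurrences, seed = 3)
fit
#> maxent_model: 2 layers, 4 features, 200 presences, 625 background cells
#>   3 non-zero weights, max KKT gap 1.56e-08
round(fit$weights, 3)
#> [1]  0.660 -0.287 -0.153  0.000
auc_maxent(fit, env, occ$occurrences)
#> [1] 0.72984
round(permutation_importance(fit, env, occ$occurrences, n_reps = 10, seed = 4), 1)
#> BIO1 BIO2
#> 75.4 24.6
```

The fitted weights recover the simulated niche: the positive linear weight
sits on the layer given true coefficient +2.5 and the negative one on the
layer given −1 (the fourth, L1-zeroed entry is an uninformative quadratic
term), the training AUC of 0.73 reflects a clearly non-uniform niche on a
small smooth landscape, and permutation importance attributes ~75% of the
discrimination to the dominant layer.

A complete run of the analysis — simulation, per-taxon models, overlap
tests, diversity maps, genotype statistics, haplotype network — is scripted
as numbered drivers:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_niche_models.R
Rscript analysis/03_overlap.R
Rscript analysis/04_diversity.R
Rscript analysis/05_popgen.R
Rscript analysis/06_haplotypes.R
```

Each stage prints what it found (e.g. "pairwise theta pop1-pop2: 0.226",
"kinship first reaches zero in class 9 (mean distance 213 km)", "haplotypes:
7 recovered vs 7 planted") and writes its tables under `results/`. The same
orchestration is available in-process as `run_pipeline()` with a YAML or
list config.

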