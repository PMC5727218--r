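#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds the synthetic counterparts of the field data: a bioclim-style
# raster stack (current + shifted climate scenario), presence points for two
# taxa drawn from known parametric niches, an island-model SNP panel with a
# target differentiation of 0.2, and an 855-bp alignment carrying 5 SNPs
# plus one 6-bp indel (7 haplotypes). Everything is written under
# results/inputs/ in the same plain-text formats the pipeline reads back
# (ESRI ASCII, CSV, FASTA), with the ground truth kept alongside.

library(peascape)

seed <- 20260926L
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed, grid_rows = 40, grid_cols = 40, n_layers = 5,
                  autocorr_range = 4, scenario_shift = 1,
                  n_occurrences = 150, n_populations = 2, n_individuals = 40,
                  n_loci = 1000, target_fst = 0.2, ibd_strength = 0.3,
                  missing_rate = 0.02, n_sequences = 60, seq_length = 855,
                  n_snp_sites = 5, indel_length = 6)

grids <- gen_env_layers(cfg)
for (l in names(grids$current$layers)) {
  write_ascii_grid(grids$current, l, file.path(out, paste0(l, "_current.asc")))
  write_ascii_grid(grids$scenario, l, file.path(out, paste0(l, "_scenario.asc")))
}

# two taxa: a warm-wet specialist and a broader generalist niche
truths <- list(taxonA = c(2.5, -1, 0.5, 0, 0),
               taxonB = c(-1, 1.5, 0, 0.5, 0))
occ_all <- NULL
for (nm in names(truths)) {
  o <- gen_occurrences(grids$current, truths[[nm]], cfg$n_occurrences,
                       seed = seed + match(nm, names(truths)), taxon = nm)
  occ_all <- rbind(occ_all, o$occurrences)
}
write_occurrences(occ_all, file.path(out, "occurrences.csv"))

g <- gen_genotypes(cfg)
write_genotypes_csv(g, file.path(out, "genotypes.csv"),
                    file.path(out, "samples.csv"))

al <- gen_alignment(cfg)
write_fasta(al$sequences, file.path(out, "alignment.fasta"))
utils::write.csv(data.frame(sequence = names(al$sequences),
                            true_haplotype = al$true_haplotype),
                 file.path(out, "alignment_truth.csv"), row.names = FALSE)

message(sprintf("simulated %d layers, %d occurrences, %d x %d genotypes, %d sequences (%d true haplotypes)",
                cfg$n_layers, nrow(occ_all), nrow(g$geno), ncol(g$geno),
                cfg$n_sequences, al$n_haplotypes))
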