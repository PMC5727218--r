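#!/usr/bin/env Rscript
# Stage 5 — population-genetic statistics on the simulated SNP panel.
#
# QC-filters the dosage matrix (missingness > 10%, MAF <= 0.05), reports
# per-individual heterozygosity, pairwise Weir-Cockerham Fst between the
# two populations, the Ritland-kinship distance-class profile with its
# permutation envelope, and the distance-to-centroid spatial summary.

library(peascape)

inp <- "results/inputs"; out <- "results/popgen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260929L

g <- read_genotypes_csv(file.path(inp, "genotypes.csv"),
                        file.path(inp, "samples.csv"))
filt <- filter_snps(g)
message(sprintf("QC: %d loci in, %d dropped for missingness, %d for MAF, %d retained",
                filt$report$n_input, filt$report$dropped_missing,
                filt$report$dropped_maf, filt$report$n_retained))
gq <- filt$genotypes

het <- heterozygosity_percent(gq)
utils::write.csv(data.frame(id = names(het), het_pct = het),
                 file.path(out, "heterozygosity.csv"), row.names = FALSE)
message(sprintf("heterozygosity: mean %.2f%%, range %.2f-%.2f%%",
                mean(het, na.rm = TRUE), min(het, na.rm = TRUE),
                max(het, na.rm = TRUE)))

fst <- pairwise_fst(gq)
utils::write.csv(as.data.frame(fst$theta), file.path(out, "fst.csv"))
message(sprintf("pairwise theta pop1-pop2: %.3f (target 0.2 + IBD overlay)",
                fst$theta["pop1", "pop2"]))

prof <- spatial_autocorrelation(gq, n_classes = 20, n_permutations = 100,
                                seed = seed)
utils::write.csv(prof$classes, file.path(out, "kinship_profile.csv"),
                 row.names = FALSE)
if (!is.na(prof$first_nonpositive_class))
  message(sprintf("kinship first reaches zero in class %d (mean distance %.0f km)",
                  prof$first_nonpositive_class,
                  prof$first_nonpositive_distance_km))

cd <- centroid_distances(gq)
utils::write.csv(cd$distances, file.path(out, "centroid_distances.csv"),
                 row.names = FALSE)
utils::write.csv(cd$overlap, file.path(out, "centroid_overlap.csv"),
                 row.names = FALSE)
message(sprintf("cluster centroid separations: %s km",
                paste(round(cd$separations[upper.tri(cd$separations)]),
                      collapse = ", ")))
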