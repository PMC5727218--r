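#!/usr/bin/env Rscript
# Stage 3 — niche overlap and the background similarity test.
#
# For the taxon pair, computes observed Schoener's D and Hellinger-based I
# from the fitted suitability maps and runs the two-directional
# background-randomization similarity test (100 iterations per direction).
# The full null distributions go into the output JSON for audit.

library(peascape)

inp <- "results/inputs"; out <- "results/overlap"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260928L

layer_files <- list.files(inp, pattern = "_current\\.asc$", full.names = TRUE)
layers <- list(); g0 <- NULL
for (f in layer_files) {
  g <- read_ascii_grid(f, sub("_current\\.asc$", "", basename(f)))
  layers[[names(g$layers)]] <- g$layers[[1]]
  g0 <- g
}
env <- env_grid(layers, xll = g0$xll, yll = g0$yll, cellsize = g0$cellsize,
                mask = g0$mask)
occ <- read_occurrences(file.path(inp, "occurrences.csv"))
taxa <- unique(occ$taxon)
prs <- utils::combn(taxa, 2)
for (c in seq_len(ncol(prs))) {
  a <- prs[1, c]; b <- prs[2, c]
  r <- background_similarity_test(
    clean_occurrences(occ[occ$taxon == a, ])$occurrences,
    clean_occurrences(occ[occ$taxon == b, ])$occurrences,
    env, n_iterations = 100, seed = seed + c)
  message(sprintf("%s vs %s: D = %.3f, I = %.3f", a, b, r$D, r$I))
  print(r$verdict)
  jsonlite::write_json(
    list(D = r$D, I = r$I, verdict = r$verdict, null = r$null,
         n_failed = as.list(r$n_failed), settings = r$settings),
    file.path(out, sprintf("overlap_%s_vs_%s.json", a, b)),
    auto_unbox = TRUE, digits = NA)
}
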