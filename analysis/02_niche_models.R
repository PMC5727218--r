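#!/usr/bin/env Rscript
# Stage 2 — niche models per taxon.
#
# Reads the simulated inputs from stage 1, cleans the occurrences, fits a
# maximum-entropy model per taxon, evaluates training AUC and permutation
# importance, and projects each model onto both the current and the
# scenario climate stacks. Writes models, suitability maps and evaluation
# tables under results/enm/.

library(peascape)

inp <- "results/inputs"; out <- "results/enm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260927L

layer_files <- list.files(inp, pattern = "_current\\.asc$", full.names = TRUE)
read_stack <- function(files, suffix) {
  layers <- list(); g0 <- NULL
  for (f in files) {
    g <- read_ascii_grid(f, sub(suffix, "", basename(f)))
    layers[[names(g$layers)]] <- g$layers[[1]]
    g0 <- g
  }
  env_grid(layers, xll = g0$xll, yll = g0$yll, cellsize = g0$cellsize,
           mask = g0$mask)
}
env_cur <- read_stack(layer_files, "_current\\.asc$")
env_scn <- read_stack(list.files(inp, pattern = "_scenario\\.asc$",
                                 full.names = TRUE), "_scenario\\.asc$")

occ <- read_occurrences(file.path(inp, "occurrences.csv"))
eval_rows <- NULL; imp_rows <- NULL
for (tx in unique(occ$taxon)) {
  cl <- clean_occurrences(occ[occ$taxon == tx, ])
  message(sprintf("%s: %d points kept, %d rejected", tx,
                  nrow(cl$occurrences), nrow(cl$report)))
  m <- fit_maxent(env_cur, cl$occurrences, seed = seed)
  write_maxent_model(m, file.path(out, paste0("model_", tx, ".json")))
  write_suitability(project_model(m, env_cur),
                    file.path(out, paste0("suitability_", tx, "_current.asc")))
  write_suitability(project_model(m, env_scn),
                    file.path(out, paste0("suitability_", tx, "_scenario.asc")))
  a <- auc_maxent(m, env_cur, cl$occurrences)
  imp <- permutation_importance(m, env_cur, cl$occurrences, n_reps = 10,
                                seed = seed)
  eval_rows <- rbind(eval_rows, data.frame(taxon = tx, auc = a))
  imp_rows <- rbind(imp_rows, data.frame(taxon = tx, layer = names(imp),
                                         importance_pct = as.numeric(imp)))
  top <- names(sort(imp, decreasing = TRUE))[1]
  message(sprintf("  training AUC %.3f; top layer by permutation importance: %s (%.1f%%)",
                  a, top, max(imp)))
}
utils::write.csv(eval_rows, file.path(out, "evaluation.csv"), row.names = FALSE)
utils::write.csv(imp_rows, file.path(out, "importance.csv"), row.names = FALSE)
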