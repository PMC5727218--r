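# deterministic per-stage seed derived from the global seed and stage name,
# kept below 2^31 so stage skipping never shifts downstream randomness
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "pipeline_out",
    simulate = list(grid_rows = 40L, grid_cols = 40L, n_layers = 5L,
                    autocorr_range = 4, scenario_shift = 1,
                    n_occurrences = 150L, n_taxa = 2L,
                    n_populations = 2L, n_individuals = 40L, n_loci = 500L,
                    target_fst = 0.2, ibd_strength = 0, missing_rate = 0.02,
                    n_sequences = 60L, seq_length = 400L, n_snp_sites = 5L,
                    indel_length = 6L),
    enm = list(background_size = 10000L, reg_multiplier = 1,
               importance_reps = 10L),
    overlap = list(n_iterations = 100L, alpha = 0.05, bandwidth_km = 200),
    diversity = list(normalize_per_cell = TRUE, min_total = 1e-12),
    popgen = list(max_missing = 0.10, min_maf = 0.05, n_classes = 20L,
                  n_permutations = 100L),
    haplotypes = list(),
    skip = character(0)
  )
}

# recursive merge of user config over defaults; unknown keys rejected
merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown config key: ", full)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) stop("config key ", full, " must be a mapping")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate and resolve a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, validates it against the known
#' schema (unknown keys are rejected before any work), and fills defaults.
#'
#' @param config list or path to a YAML file.
#' @return resolved configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  cfg <- merge_config(pipeline_defaults(), config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full synthetic-landscape analysis pipeline
#'
#' Orchestrates: simulation of all inputs; one niche model per taxon with
#' AUC, permutation importance and projection onto the scenario stack;
#' pairwise background similarity tests; current and scenario Shannon
#' diversity maps and their difference; SNP QC, heterozygosity, pairwise
#' Fst, kinship spatial autocorrelation and centroid distances; haplotype
#' calling, collapsing and network construction. Every stage writes
#' deterministic file names under `output_dir` and the manifest records
#' settings, per-stage seeds and status; listed stages can be skipped, and a
#' stage failure halts its dependents while keeping completed artifacts.
#'
#' @param config list or YAML path, see [pipeline_config()].
#' @return the manifest (also written as `manifest.json` in `output_dir`),
#'   invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("peascape")),
                   seed = cfg$seed, config = cfg, stages = list(),
                   artifacts = list())
  log_msg <- function(...) message(sprintf(...))
  add_stage <- function(name, status, seed = NULL, error = NULL) {
    manifest$stages[[name]] <<- list(status = status, seed = seed,
                                     error = error)
  }
  out <- function(...) file.path(cfg$output_dir, ...)
  state <- new.env()

  stages <- list(
    simulate = function() {
      sc <- cfg$simulate
      seed <- stage_seed(cfg$seed, "simulate")
      base <- sim_config(seed = seed, grid_rows = sc$grid_rows,
                         grid_cols = sc$grid_cols, n_layers = sc$n_layers,
                         autocorr_range = sc$autocorr_range,
                         scenario_shift = sc$scenario_shift,
                         n_occurrences = sc$n_occurrences,
                         n_populations = sc$n_populations,
                         n_individuals = sc$n_individuals,
                         n_loci = sc$n_loci, target_fst = sc$target_fst,
                         ibd_strength = sc$ibd_strength,
                         missing_rate = sc$missing_rate,
                         n_sequences = sc$n_sequences,
                         seq_length = sc$seq_length,
                         n_snp_sites = sc$n_snp_sites,
                         indel_length = sc$indel_length)
      grids <- gen_env_layers(base)
      state$env <- grids$current; state$scenario <- grids$scenario
      # one random (but seed-determined) niche per taxon
      occs <- list()
      for (t in seq_len(sc$n_taxa)) {
        set.seed(seed + 100L * t)
        beta <- stats::rnorm(sc$n_layers, 0, 1.5)
        o <- gen_occurrences(grids$current, beta, sc$n_occurrences,
                             seed = seed + t, taxon = paste0("taxon", t))
        occs[[paste0("taxon", t)]] <- o
      }
      state$occs <- occs
      state$genotypes <- gen_genotypes(base)
      state$alignment <- gen_alignment(base)
      for (l in names(state$env$layers))
        write_ascii_grid(state$env, l, out(paste0("env_", l, ".asc")))
      all_occ <- do.call(rbind, lapply(occs, function(o) o$occurrences))
      write_occurrences(all_occ, out("occurrences.csv"))
      write_genotypes_csv(state$genotypes, out("genotypes.csv"),
                          out("samples.csv"))
      write_fasta(state$alignment$sequences, out("alignment.fasta"))
      manifest$artifacts$simulate <<-
        c("occurrences.csv", "genotypes.csv", "samples.csv", "alignment.fasta",
          paste0("env_", names(state$env$layers), ".asc"))
      seed
    },
    enm = function() {
      seed <- stage_seed(cfg$seed, "enm")
      fits <- list(); arts <- character(0)
      for (nm in names(state$occs)) {
        occ <- clean_occurrences(state$occs[[nm]]$occurrences)$occurrences
        m <- fit_maxent(state$env, occ,
                        background_size = cfg$enm$background_size,
                        reg_multiplier = cfg$enm$reg_multiplier, seed = seed)
        cur <- project_model(m, state$env)
        fut <- project_model(m, state$scenario)
        fits[[nm]] <- list(model = m, occ = occ, current = cur,
                           scenario = fut,
                           auc = auc_maxent(m, state$env, occ),
                           importance = permutation_importance(
                             m, state$env, occ,
                             n_reps = cfg$enm$importance_reps, seed = seed))
        write_maxent_model(m, out(paste0("model_", nm, ".json")))
        write_suitability(cur, out(paste0("suitability_", nm, "_current.asc")))
        write_suitability(fut, out(paste0("suitability_", nm, "_scenario.asc")))
        arts <- c(arts, paste0("model_", nm, ".json"),
                  paste0("suitability_", nm, "_current.asc"),
                  paste0("suitability_", nm, "_scenario.asc"))
      }
      state$fits <- fits
      eval_df <- data.frame(
        taxon = names(fits),
        auc = vapply(fits, function(f) f$auc, numeric(1L)))
      utils::write.csv(eval_df, out("enm_evaluation.csv"), row.names = FALSE)
      imp <- do.call(rbind, lapply(names(fits), function(nm)
        data.frame(taxon = nm, layer = names(fits[[nm]]$importance),
                   importance_pct = as.numeric(fits[[nm]]$importance))))
      utils::write.csv(imp, out("enm_importance.csv"), row.names = FALSE)
      manifest$artifacts$enm <<- c(arts, "enm_evaluation.csv",
                                   "enm_importance.csv")
      seed
    },
    overlap = function() {
      seed <- stage_seed(cfg$seed, "overlap")
      nms <- names(state$fits)
      res <- list()
      if (length(nms) >= 2L) {
        prs <- utils::combn(nms, 2L)
        for (c in seq_len(ncol(prs))) {
          a <- prs[1L, c]; b <- prs[2L, c]
          r <- background_similarity_test(
            state$fits[[a]]$occ, state$fits[[b]]$occ, state$env,
            n_iterations = cfg$overlap$n_iterations,
            alpha = cfg$overlap$alpha, seed = seed + c,
            bandwidth_km = cfg$overlap$bandwidth_km,
            background_size = cfg$enm$background_size,
            reg_multiplier = cfg$enm$reg_multiplier)
          res[[paste(a, b, sep = "_vs_")]] <- r
          jsonlite::write_json(
            list(D = r$D, I = r$I, verdict = r$verdict, null = r$null,
                 n_failed = as.list(r$n_failed), settings = r$settings),
            out(paste0("overlap_", a, "_vs_", b, ".json")),
            auto_unbox = TRUE, digits = NA)
        }
      }
      state$overlap <- res
      manifest$artifacts$overlap <<- paste0("overlap_", names(res), ".json")
      seed
    },
    diversity = function() {
      seed <- stage_seed(cfg$seed, "diversity")
      cur <- lapply(state$fits, function(f) f$current)
      fut <- lapply(state$fits, function(f) f$scenario)
      dc <- shannon_map(cur, cfg$diversity$normalize_per_cell,
                        cfg$diversity$min_total)
      df <- shannon_map(fut, cfg$diversity$normalize_per_cell,
                        cfg$diversity$min_total)
      dd <- diversity_difference(dc, df)
      write_diversity(dc, out("shannon_current.asc"))
      write_diversity(df, out("shannon_scenario.asc"))
      jsonlite::write_json(
        dd[c("impoverished_fraction", "enriched_fraction", "lost_cells",
             "gained_cells")],
        out("diversity_difference.json"), auto_unbox = TRUE, digits = NA)
      state$diversity <- list(current = dc, scenario = df, difference = dd)
      manifest$artifacts$diversity <<-
        c("shannon_current.asc", "shannon_scenario.asc",
          "diversity_difference.json")
      seed
    },
    popgen = function() {
      seed <- stage_seed(cfg$seed, "popgen")
      filt <- filter_snps(state$genotypes, cfg$popgen$max_missing,
                          cfg$popgen$min_maf)
      het <- heterozygosity_percent(filt$genotypes)
      fst <- pairwise_fst(filt$genotypes)
      prof <- spatial_autocorrelation(filt$genotypes,
                                      n_classes = cfg$popgen$n_classes,
                                      n_permutations = cfg$popgen$n_permutations,
                                      seed = seed)
      cd <- centroid_distances(filt$genotypes)
      utils::write.csv(data.frame(id = names(het), het_pct = het),
                       out("heterozygosity.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(fst$theta), out("fst.csv"))
      utils::write.csv(prof$classes, out("kinship_profile.csv"),
                       row.names = FALSE)
      utils::write.csv(cd$distances, out("centroid_distances.csv"),
                       row.names = FALSE)
      jsonlite::write_json(filt$report, out("snp_filter_report.json"),
                           auto_unbox = TRUE)
      state$popgen <- list(filter = filt, het = het, fst = fst,
                           kinship = prof, centroids = cd)
      manifest$artifacts$popgen <<-
        c("heterozygosity.csv", "fst.csv", "kinship_profile.csv",
          "centroid_distances.csv", "snp_filter_report.json")
      seed
    },
    haplotypes = function() {
      seed <- stage_seed(cfg$seed, "haplotypes")
      ct <- call_characters(state$alignment$sequences)
      hs <- collapse_haplotypes(ct)
      net <- build_network(hs)
      utils::write.csv(haplotype_table(hs), out("haplotypes.csv"),
                       row.names = FALSE)
      write_network(net, tsv_path = out("network_edges.tsv"),
                    graphml_path = out("network.graphml"))
      state$haplotypes <- list(characters = ct, haplotypes = hs,
                               network = net)
      manifest$artifacts$haplotypes <<-
        c("haplotypes.csv", "network_edges.tsv", "network.graphml")
      seed
    }
  )

  deps <- list(simulate = character(0), enm = "simulate",
               overlap = "enm", diversity = "enm",
               popgen = "simulate", haplotypes = "simulate")
  done <- character(0)
  for (nm in names(stages)) {
    if (nm %in% cfg$skip) { add_stage(nm, "skipped"); next }
    if (!all(deps[[nm]] %in% done)) {
      add_stage(nm, "halted (dependency failed or skipped)")
      next
    }
    log_msg("pipeline: running stage '%s'", nm)
    res <- tryCatch(stages[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      add_stage(nm, "failed", error = conditionMessage(res))
      log_msg("pipeline: stage '%s' failed: %s", nm, conditionMessage(res))
    } else {
      add_stage(nm, "ok", seed = res)
      done <- c(done, nm)
    }
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest$results <- as.list(state)
  invisible(manifest)
}
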