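#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The generators are
#' pure functions of the configuration (the seed fully determines all
#' outputs), and each one returns the ground truth alongside the observable
#' data so downstream stages can be tested for recovery.
#'
#' Defaults emulate the shapes of a Mediterranean crop-wild-relative study:
#' a bioclim-style stack of 19 layers, a few hundred occurrences per taxon,
#' an island-model SNP panel with moderate differentiation, and a short
#' aligned locus carrying a handful of SNPs plus one multi-base indel.
#'
#' @param seed integer seed driving every random draw.
#' @param grid_rows,grid_cols grid dimensions (cells); must be >= 8.
#' @param n_layers number of environmental layers (BIO-style).
#' @param autocorr_range Gaussian smoothing radius in cells controlling the
#'   spatial autocorrelation of the layers.
#' @param scenario_shift numeric shift (in layer standard deviations) added to
#'   each layer to produce the alternative-climate stack; recycled over
#'   layers.
#' @param niche_coefficients list of per-taxon coefficient vectors on the
#'   linear+quadratic feature expansion (length `2 * n_layers` each, or
#'   `n_layers` for linear-only truths padded with zero quadratics).
#' @param n_occurrences presence points drawn per taxon.
#' @param n_populations,n_individuals,n_loci genotype panel dimensions
#'   (`n_individuals` is per population).
#' @param target_fst Balding-Nichols differentiation parameter, strictly in
#'   (0, 1).
#' @param ibd_strength amplitude (allele-frequency units) of the spatially
#'   smoothed within-population perturbation that creates isolation by
#'   distance; 0 disables it (pure island model).
#' @param ibd_range_km kernel range of the isolation-by-distance smoothing.
#' @param missing_rate fraction of genotype calls set missing, completely at
#'   random.
#' @param n_hybrids number of planted F1 individuals between populations 1
#'   and 2.
#' @param n_sequences,seq_length,n_snp_sites,indel_length alignment simulator
#'   dimensions: number of sequences, alignment length (bp), planted SNP
#'   sites, and the length of the single planted indel.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       grid_rows = 40L, grid_cols = 40L,
                       n_layers = 19L, autocorr_range = 4,
                       scenario_shift = 1,
                       niche_coefficients = NULL,
                       n_occurrences = 200L,
                       n_populations = 2L, n_individuals = 50L,
                       n_loci = 1000L, target_fst = 0.2,
                       ibd_strength = 0, ibd_range_km = 100,
                       missing_rate = 0.02, n_hybrids = 0L,
                       n_sequences = 60L, seq_length = 855L,
                       n_snp_sites = 5L, indel_length = 6L) {
  cfg <- list(seed = as.integer(seed), grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols), n_layers = as.integer(n_layers),
              autocorr_range = autocorr_range, scenario_shift = scenario_shift,
              niche_coefficients = niche_coefficients,
              n_occurrences = as.integer(n_occurrences),
              n_populations = as.integer(n_populations),
              n_individuals = as.integer(n_individuals),
              n_loci = as.integer(n_loci), target_fst = target_fst,
              ibd_strength = ibd_strength, ibd_range_km = ibd_range_km,
              missing_rate = missing_rate, n_hybrids = as.integer(n_hybrids),
              n_sequences = as.integer(n_sequences),
              seq_length = as.integer(seq_length),
              n_snp_sites = as.integer(n_snp_sites),
              indel_length = as.integer(indel_length))
  counts <- c(cfg$grid_rows, cfg$grid_cols, cfg$n_layers, cfg$n_populations,
              cfg$n_individuals, cfg$n_loci, cfg$n_sequences, cfg$seq_length)
  if (any(counts <= 0L)) stop("all counts must be > 0")
  if (cfg$target_fst <= 0 || cfg$target_fst >= 1)
    stop("target_fst must be strictly inside (0, 1)")
  if (cfg$ibd_strength < 0) stop("ibd_strength must be >= 0")
  if (cfg$indel_length < 1L) stop("indel_length must be >= 1")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

# separable Gaussian smoothing of a matrix, truncated kernel, renormalized at
# the edges so smoothing preserves a constant field exactly
gaussian_smooth_matrix <- function(m, range_cells) {
  if (range_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * range_cells))
  k <- exp(-(seq(-half, half))^2 / (2 * range_cells^2))
  smooth_vec <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      kk <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m <- apply(m, 2L, smooth_vec)
  t(apply(m, 1L, smooth_vec))
}

#' Generate spatially autocorrelated environmental layers
#'
#' Each layer is white noise convolved with a Gaussian kernel of radius
#' `autocorr_range` cells, then standardized to mean 0 and sd 1 over unmasked
#' cells. A matching "scenario" stack (emulating a past/future climate) is
#' produced by adding `scenario_shift` to each layer, re-expressed on the
#' same standardization so projection code sees genuinely shifted inputs.
#'
#' @param config a [sim_config()].
#' @return list with `current` and `scenario`, both `env_grid` objects with
#'   layers named `BIO1 ... BIOn`.
#' @export
gen_env_layers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$grid_rows < 8L || config$grid_cols < 8L)
    stop("grid dimensions must be >= 8 x 8")
  set.seed(config$seed)
  shift <- rep_len(config$scenario_shift, config$n_layers)
  cur <- vector("list", config$n_layers)
  scn <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    noise <- matrix(stats::rnorm(config$grid_rows * config$grid_cols),
                    config$grid_rows, config$grid_cols)
    sm <- gaussian_smooth_matrix(noise, config$autocorr_range)
    sm <- (sm - mean(sm)) / stats::sd(sm)
    cur[[l]] <- sm
    scn[[l]] <- sm + shift[l]
  }
  nm <- paste0("BIO", seq_len(config$n_layers))
  names(cur) <- nm; names(scn) <- nm
  # extent chosen to sit in the eastern Mediterranean at ~0.25 deg resolution
  cs <- 0.25
  list(current = env_grid(cur, xll = 20, yll = 30, cellsize = cs),
       scenario = env_grid(scn, xll = 20, yll = 30, cellsize = cs))
}

# linear + quadratic expansion of raw layer values (rows = cells/points)
feature_expand <- function(x) {
  cbind(x, x^2)
}

#' Sample occurrence points from a known parametric niche
#'
#' Presence cells are drawn with probability proportional to a logistic
#' function of the true linear+quadratic feature score, and each point is
#' jittered uniformly within its cell. The true suitability surface is
#' returned for recovery tests.
#'
#' @param env an `env_grid` (typically `gen_env_layers(config)$current`).
#' @param true_coefficients coefficient vector on the linear+quadratic
#'   expansion of the layers; a vector of length `n_layers` is padded with
#'   zero quadratic terms.
#' @param n number of presence points.
#' @param seed integer seed.
#' @param taxon taxon label attached to the points.
#' @return list with `occurrences` (data.frame `taxon,lon,lat`),
#'   `true_suitability` (matrix of per-cell presence weights, normalized to
#'   sum to 1 over unmasked cells) and `true_coefficients` (padded vector).
#' @export
gen_occurrences <- function(env, true_coefficients, n, seed = 1L,
                            taxon = "taxon1") {
  stopifnot(inherits(env, "env_grid"))
  n_lay <- length(env$layers)
  if (length(true_coefficients) == n_lay)
    true_coefficients <- c(true_coefficients, rep(0, n_lay))
  if (length(true_coefficients) != 2L * n_lay)
    stop("true_coefficients must have length n_layers or 2 * n_layers")
  land <- which(env$mask)
  if (n > length(land)) stop("n exceeds the number of unmasked cells")
  X <- vapply(env$layers, function(m) m[land], numeric(length(land)))
  if (length(land) == 1L) X <- matrix(X, nrow = 1L)
  score <- drop(feature_expand(X) %*% true_coefficients)
  w <- stats::plogis(score)
  prob <- w / sum(w)
  set.seed(as.integer(seed))
  cells <- sample(land, n, replace = TRUE, prob = prob)
  rc <- arrayInd(cells, dim(env$mask))
  # jitter within cell (half-open cells, so jitter in [0, cellsize))
  u <- stats::runif(n); v <- stats::runif(n)
  lon <- env$xll + (rc[, 2L] - 1L + u) * env$cellsize
  lat <- env$yll + (env$n_rows - rc[, 1L] + v) * env$cellsize
  lat <- pmin(lat, env$yll + env$n_rows * env$cellsize - 1e-9)
  truth <- matrix(0, env$n_rows, env$n_cols)
  truth[land] <- prob
  occ <- if (n > 0L)
    data.frame(taxon = taxon, lon = lon, lat = lat, stringsAsFactors = FALSE)
  else
    data.frame(taxon = character(0), lon = numeric(0), lat = numeric(0))
  list(occurrences = occ, true_suitability = truth,
       true_coefficients = true_coefficients)
}

#' Simulate an island-model SNP panel with known differentiation
#'
#' Per locus, an ancestral frequency is drawn uniformly on (0.1, 0.9) and
#' population frequencies follow the Balding-Nichols Beta construction with
#' parameter `target_fst`. Individuals are placed at coordinates around
#' spaced population centres; when `ibd_strength > 0`, a per-locus spatially
#' smoothed perturbation of individual allele frequencies makes genetic
#' similarity decay with distance at kernel range `ibd_range_km`. A fraction
#' of calls is set missing completely at random, and `n_hybrids` planted F1s
#' between populations 1 and 2 are appended.
#'
#' @param config a [sim_config()].
#' @return a `genotype_matrix`: list with `geno` (individuals x loci dosage
#'   matrix in \{0,1,2,NA\}), `samples` (data.frame `id,group,lon,lat`),
#'   `loci` (locus ids), and ground truth `true_pop_freqs` (populations x
#'   loci) and `true_labels`.
#' @export
gen_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  P <- config$n_populations; ni <- config$n_individuals; L <- config$n_loci
  Fst <- config$target_fst
  p_anc <- stats::runif(L, 0.1, 0.9)
  shape <- (1 - Fst) / Fst
  pop_freq <- matrix(0, P, L)
  for (k in seq_len(P))
    pop_freq[k, ] <- stats::rbeta(L, p_anc * shape, (1 - p_anc) * shape)
  # population centres spaced along the longitude axis, ~3 deg apart
  centers_lon <- 25 + 3 * (seq_len(P) - 1L)
  centers_lat <- rep(35, P)
  n_tot <- P * ni
  pop_of <- rep(seq_len(P), each = ni)
  lon <- centers_lon[pop_of] + stats::rnorm(n_tot, 0, 1.0)
  lat <- centers_lat[pop_of] + stats::rnorm(n_tot, 0, 1.0)
  p_ind <- pop_freq[pop_of, , drop = FALSE]  # individuals x loci
  if (config$ibd_strength > 0) {
    d <- haversine_matrix(lon, lat, lon, lat)
    S <- exp(-(d / config$ibd_range_km)^2 / 2)
    # unit-variance rows: each individual's perturbation has sd exactly
    # ibd_strength, and cor(pert_i, pert_j) decays with distance
    S <- S / sqrt(rowSums(S^2))
    Z <- matrix(stats::rnorm(n_tot * L), n_tot, L)
    p_ind <- p_ind + config$ibd_strength * (S %*% Z)
    p_ind <- pmin(pmax(p_ind, 0.01), 0.99)
  }
  geno <- matrix(stats::rbinom(n_tot * L, 2L, as.vector(p_ind)), n_tot, L)
  labels <- paste0("pop", pop_of)
  ids <- sprintf("ind%03d", seq_len(n_tot))
  if (config$n_hybrids > 0L) {
    if (P < 2L) stop("planting F1 hybrids requires >= 2 populations")
    hg <- matrix(0L, config$n_hybrids, L)
    for (h in seq_len(config$n_hybrids))
      hg[h, ] <- stats::rbinom(L, 1L, pop_freq[1L, ]) +
        stats::rbinom(L, 1L, pop_freq[2L, ])
    geno <- rbind(geno, hg)
    mid_lon <- mean(centers_lon[1:2]); mid_lat <- mean(centers_lat[1:2])
    lon <- c(lon, mid_lon + stats::rnorm(config$n_hybrids, 0, 0.5))
    lat <- c(lat, mid_lat + stats::rnorm(config$n_hybrids, 0, 0.5))
    labels <- c(labels, rep("hybrid", config$n_hybrids))
    ids <- c(ids, sprintf("hyb%03d", seq_len(config$n_hybrids)))
    pop_of <- c(pop_of, rep(NA_integer_, config$n_hybrids))
  }
  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(geno))
    if (nmiss > 0L) geno[sample(length(geno), nmiss)] <- NA_integer_
  }
  structure(
    list(geno = geno,
         samples = data.frame(id = ids, group = labels, lon = lon, lat = lat,
                              stringsAsFactors = FALSE),
         loci = sprintf("snp%05d", seq_len(L)),
         true_pop_freqs = pop_freq, true_labels = pop_of),
    class = "genotype_matrix")
}

#' Simulate an aligned sequence set with planted haplotypes
#'
#' Builds a random reference of `seq_length` bp, then a stepwise chain of
#' haplotypes: haplotype 1 is the reference, each subsequent haplotype adds
#' one new variant (first the `n_snp_sites` substitutions, then one
#' contiguous deletion of `indel_length` bp), so `n_snp_sites` SNPs plus the
#' indel define `n_snp_sites + 2` distinct haplotypes. Sequences are assigned
#' to haplotypes in a fixed near-equal split, giving known truth counts.
#'
#' @param config a [sim_config()].
#' @param indel_start 1-based alignment position of the indel run (default:
#'   centred; may be 1 to place it on the alignment edge).
#' @param include_indel set `FALSE` to plant substitutions only (with
#'   `n_snp_sites = 0` this yields a single invariant haplotype).
#' @return list with `sequences` (named character vector of aligned
#'   sequences over A,C,G,T,-), `true_haplotype` (integer assignment),
#'   `n_haplotypes`, `variant_positions` (SNP sites) and `indel_range`.
#' @export
gen_alignment <- function(config, indel_start = NULL, include_indel = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$seq_length; S <- config$n_snp_sites
  I <- if (include_indel) config$indel_length else 0L
  n_hap <- S + 1L + as.integer(include_indel)
  if (L < S + I + 2L)
    stop("seq_length too small to host the planted SNPs and indel")
  set.seed(config$seed + 2L)
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (is.null(indel_start)) indel_start <- max(1L, floor(L / 2) - max(I, 1L))
  if (include_indel && (indel_start < 1L || indel_start + I - 1L > L))
    stop("indel does not fit in the alignment")
  indel_pos <- if (include_indel) indel_start:(indel_start + I - 1L) else integer(0)
  snp_pool <- setdiff(seq_len(L), indel_pos)
  snp_pos <- if (S > 0L) sort(sample(snp_pool, S)) else integer(0)
  alt_of <- function(b) {
    cands <- setdiff(c("A", "C", "G", "T"), b)
    cands[1L]  # deterministic transversion-agnostic alternative
  }
  haps <- vector("list", n_hap)
  haps[[1L]] <- ref
  cur <- ref
  for (j in seq_len(S)) {
    cur[snp_pos[j]] <- alt_of(cur[snp_pos[j]])
    haps[[j + 1L]] <- cur
  }
  if (include_indel) {
    cur[indel_pos] <- "-"
    haps[[n_hap]] <- cur
  }
  # near-equal deterministic split of sequences over haplotypes
  assign <- rep(seq_len(n_hap), length.out = config$n_sequences)
  assign <- sort(assign)
  seqs <- vapply(assign, function(h) paste(haps[[h]], collapse = ""),
                 character(1L))
  names(seqs) <- sprintf("seq%03d", seq_len(config$n_sequences))
  list(sequences = seqs, true_haplotype = assign, n_haplotypes = n_hap,
       variant_positions = snp_pos,
       indel_range = if (include_indel) c(indel_start, indel_start + I - 1L)
       else NULL)
}

#' Write aligned sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(seqs[[i]], con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: no '>' headers")
  idx <- cumsum(hdr)
  nm <- sub("^>", "", lines[hdr])
  body <- tapply(lines[!hdr], idx[!hdr], paste, collapse = "")
  out <- as.character(body)
  names(out) <- nm
  toupper(out)
}
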