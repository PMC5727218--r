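#' Assemble a genotype matrix object
#'
#' @param geno individuals x loci matrix of diploid dosages in \{0,1,2,NA\}.
#' @param samples data.frame with `id`, `group` and optionally `lon`, `lat`.
#' @param loci locus id vector (default column names or snp#).
#' @return a `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, samples, loci = NULL) {
  geno <- as.matrix(geno)
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (nrow(geno) != nrow(samples)) stop("samples must have one row per individual")
  if (!all(c("id", "group") %in% names(samples)))
    stop("samples needs 'id' and 'group' columns")
  if (is.null(loci))
    loci <- if (!is.null(colnames(geno))) colnames(geno) else
      sprintf("snp%05d", seq_len(ncol(geno)))
  if (any(c("lon", "lat") %in% names(samples)) &&
      all(c("lon", "lat") %in% names(samples))) {
    cc <- stats::complete.cases(samples[, c("lon", "lat")])
    if (any(abs(samples$lon[cc]) > 180 | abs(samples$lat[cc]) > 90))
      stop("sample coordinates out of range")
  }
  structure(list(geno = geno, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d group(s), %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$samples$group)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

# per-locus frequency of the counted (dosage) allele over non-missing calls
locus_freq <- function(geno) {
  colSums(geno, na.rm = TRUE) / (2 * colSums(!is.na(geno)))
}

#' SNP quality-control filter: missingness then minor allele frequency
#'
#' Drops loci whose missing-call fraction exceeds `max_missing`, then loci
#' whose minor allele frequency (computed on non-missing calls) is at or
#' below `min_maf` (strict `<=`, so MAF exactly at the threshold is
#' removed). The filters are applied in that order and reported separately;
#' applying the filter twice is idempotent.
#'
#' @param g a `genotype_matrix`.
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param min_maf MAF threshold; loci with MAF <= this are dropped
#'   (default 0.05).
#' @return list with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (counts: input, dropped per rule, retained).
#' @export
filter_snps <- function(g, max_missing = 0.10, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_in <- ncol(g$geno)
  miss_frac <- colMeans(is.na(g$geno))
  keep1 <- miss_frac <= max_missing
  freq <- locus_freq(g$geno[, keep1, drop = FALSE])
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0  # loci with zero non-missing calls
  keep2 <- maf > min_maf
  kept_idx <- which(keep1)[keep2]
  out <- genotype_matrix(g$geno[, kept_idx, drop = FALSE], g$samples,
                         g$loci[kept_idx])
  if (length(kept_idx) == 0L)
    warning("no loci survive the filters")
  list(genotypes = out,
       report = list(n_input = n_in,
                     dropped_missing = sum(!keep1),
                     dropped_maf = sum(!keep2),
                     n_retained = length(kept_idx),
                     order = c("missingness", "maf")))
}

#' Per-individual heterozygosity percentage
#'
#' 100 times the number of heterozygous (dosage 1) calls over the number of
#' non-missing calls, per individual. Individuals with no non-missing call
#' get `NA`.
#'
#' @param g a `genotype_matrix`.
#' @return named numeric vector of percentages.
#' @export
heterozygosity_percent <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  het <- rowSums(g$geno == 1L, na.rm = TRUE)
  n_called <- rowSums(!is.na(g$geno))
  out <- ifelse(n_called > 0L, 100 * het / n_called, NA_real_)
  names(out) <- g$samples$id
  out
}

#' Species-diagnostic SNP selection by Fisher's exact test
#'
#' Per locus, a two-sided Fisher exact test on the 2x2 allele-count table
#' (group x allele) between two groups; loci with p below `p_threshold`
#' (default the genome-wide 5e-8) are retained. A locus monomorphic across
#' both groups has p = 1 and is never retained.
#'
#' @param g a `genotype_matrix`.
#' @param group_a,group_b group labels in `g$samples$group`.
#' @param p_threshold retention threshold (default 5e-8).
#' @return list with `loci` (retained locus ids), `index` (column indices)
#'   and `p_values` (all loci).
#' @export
diagnostic_snps <- function(g, group_a, group_b, p_threshold = 5e-8) {
  stopifnot(inherits(g, "genotype_matrix"))
  ia <- g$samples$group == group_a
  ib <- g$samples$group == group_b
  if (!any(ia) || !any(ib)) stop("both groups must be non-empty")
  ga <- g$geno[ia, , drop = FALSE]
  gb <- g$geno[ib, , drop = FALSE]
  a1 <- colSums(ga, na.rm = TRUE)
  a0 <- 2 * colSums(!is.na(ga)) - a1
  b1 <- colSums(gb, na.rm = TRUE)
  b0 <- 2 * colSums(!is.na(gb)) - b1
  p <- vapply(seq_len(ncol(g$geno)), function(l) {
    tab <- matrix(c(a1[l], a0[l], b1[l], b0[l]), 2L)
    if (sum(tab) == 0L || all(tab[1L, ] == 0L) || all(tab[2L, ] == 0L))
      return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1L))
  idx <- which(p < p_threshold)
  list(loci = g$loci[idx], index = idx, p_values = p)
}

#' Ritland kinship between two individuals
#'
#' Per biallelic locus with counted-allele frequency p (0 < p < 1) and
#' half-dosages x = dosage / 2, the locus estimate is
#' `x_i * x_j / p + (1 - x_i) * (1 - x_j) / (1 - p) - 1`; the multilocus
#' estimate is the unweighted mean over loci where both individuals are
#' called (all loci biallelic, so weights are equal). `NA` when no locus is
#' usable.
#'
#' @param gi,gj dosage vectors for the two individuals.
#' @param freqs counted-allele frequency per locus.
#' @return kinship estimate (a real; can be negative).
#' @export
ritland_kinship <- function(gi, gj, freqs) {
  use <- !is.na(gi) & !is.na(gj) & freqs > 0 & freqs < 1
  if (!any(use)) return(NA_real_)
  xi <- gi[use] / 2; xj <- gj[use] / 2; p <- freqs[use]
  mean(xi * xj / p + (1 - xi) * (1 - xj) / (1 - p) - 1)
}

# full pairwise Ritland kinship matrix, vectorized over loci with missing
# handled per pair; frequencies estimated from the whole analyzed sample
ritland_matrix <- function(geno, freqs = NULL) {
  if (is.null(freqs)) freqs <- locus_freq(geno)
  use_loc <- freqs > 0 & freqs < 1
  G <- geno[, use_loc, drop = FALSE]
  p <- freqs[use_loc]
  X <- G / 2
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  Yin <- (1 - X); Yin[!M] <- 0
  A <- (X0 %*% diag(1 / p, length(p))) %*% t(X0)
  B <- (Yin %*% diag(1 / (1 - p), length(p))) %*% t(Yin)
  n_use <- (M * 1) %*% t(M * 1)
  K <- (A + B - n_use) / n_use
  K[n_use == 0] <- NA_real_
  K
}

#' Distance-class spatial autocorrelation of Ritland kinship
#'
#' All pairwise great-circle distances are binned into `n_classes`
#' equal-count classes (ties at bin edges resolved by a stable sort on
#' distance then pair id). Per class, the mean pairwise Ritland kinship is
#' reported (allele frequencies from the whole sample). The permutation null
#' shuffles the coordinate assignment among individuals, keeping genotypes
#' fixed, and recomputes the class means; the envelope is the 2.5/97.5
#' percentile per class. The profile also reports the first class whose mean
#' kinship drops to or below zero (the "kinship reaches zero at distance d"
#' summary).
#'
#' @param g a `genotype_matrix` with coordinates for every individual.
#' @param n_classes number of distance classes (default 20).
#' @param n_permutations permutation replicates (default 100).
#' @param seed integer seed.
#' @return a `kinship_profile`: data.frame `classes` with columns
#'   `d_min,d_max,d_mean,n_pairs,kinship,env_lo,env_hi`, plus
#'   `first_nonpositive_class`, `first_nonpositive_distance_km` and settings.
#' @export
spatial_autocorrelation <- function(g, n_classes = 20L, n_permutations = 100L,
                                    seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!all(c("lon", "lat") %in% names(g$samples)) ||
      anyNA(g$samples$lon) || anyNA(g$samples$lat))
    stop("coordinates required for every individual")
  n <- nrow(g$geno)
  n_pairs <- n * (n - 1L) / 2L
  if (n_pairs < n_classes) stop("need at least as many pairs as classes")
  K <- ritland_matrix(g$geno)
  pr <- which(upper.tri(K), arr.ind = TRUE)
  kin <- K[upper.tri(K)]
  d <- haversine_km(g$samples$lon[pr[, 1L]], g$samples$lat[pr[, 1L]],
                    g$samples$lon[pr[, 2L]], g$samples$lat[pr[, 2L]])
  ord <- order(d, seq_along(d))  # stable: distance then pair id
  cls_sizes <- rep(n_pairs %/% n_classes, n_classes)
  rem <- n_pairs %% n_classes
  if (rem > 0L) cls_sizes[seq_len(rem)] <- cls_sizes[seq_len(rem)] + 1L
  cls <- integer(n_pairs)
  cls[ord] <- rep(seq_len(n_classes), times = cls_sizes)
  class_mean <- function(values, classes)
    vapply(seq_len(n_classes), function(c) mean(values[classes == c],
                                                na.rm = TRUE), numeric(1L))
  obs <- class_mean(kin, cls)
  set.seed(as.integer(seed))
  perm_means <- matrix(NA_real_, n_permutations, n_classes)
  for (pp in seq_len(n_permutations)) {
    relab <- sample.int(n)
    # permute coordinates: pair (i, j) keeps its kinship but is re-binned by
    # the distance between the permuted locations
    dp <- haversine_km(g$samples$lon[relab[pr[, 1L]]],
                       g$samples$lat[relab[pr[, 1L]]],
                       g$samples$lon[relab[pr[, 2L]]],
                       g$samples$lat[relab[pr[, 2L]]])
    ordp <- order(dp, seq_along(dp))
    clsp <- integer(n_pairs)
    clsp[ordp] <- rep(seq_len(n_classes), times = cls_sizes)
    perm_means[pp, ] <- class_mean(kin, clsp)
  }
  env_lo <- apply(perm_means, 2L, stats::quantile, probs = 0.025, na.rm = TRUE)
  env_hi <- apply(perm_means, 2L, stats::quantile, probs = 0.975, na.rm = TRUE)
  classes <- data.frame(
    class = seq_len(n_classes),
    d_min = vapply(seq_len(n_classes), function(c) min(d[cls == c]), numeric(1L)),
    d_max = vapply(seq_len(n_classes), function(c) max(d[cls == c]), numeric(1L)),
    d_mean = vapply(seq_len(n_classes), function(c) mean(d[cls == c]), numeric(1L)),
    n_pairs = as.integer(cls_sizes),
    kinship = obs, env_lo = env_lo, env_hi = env_hi)
  first_np <- which(obs <= 0)[1L]
  structure(
    list(classes = classes,
         first_nonpositive_class = if (length(first_np) && !is.na(first_np))
           first_np else NA_integer_,
         first_nonpositive_distance_km = if (length(first_np) && !is.na(first_np))
           classes$d_mean[first_np] else NA_real_,
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed)),
    class = "kinship_profile")
}

# Weir & Cockerham (1984) variance components for one locus and two groups;
# returns c(a, b, c) or NULL when the locus is unusable for the pair
wc84_components <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  n1 <- length(d1); n2 <- length(d2)
  if (n1 < 1L || n2 < 1L) return(NULL)
  p1 <- sum(d1) / (2 * n1); p2 <- sum(d2) / (2 * n2)
  if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) return(NULL)
  h1 <- mean(d1 == 1L); h2 <- mean(d2 == 1L)
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

#' Pairwise multi-locus Weir-Cockerham Fst
#'
#' For every pair of groups, the 1984 variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) are computed per locus and combined as the ratio of sums
#' `theta = sum(a) / sum(a + b + c)`. Loci monomorphic across a pair are
#' skipped; a pair with no usable locus gets `NA` and is reported.
#'
#' @param g a `genotype_matrix` with >= 2 groups of >= 2 individuals.
#' @return an `fst_matrix`: list with `theta` (symmetric matrix, NA
#'   diagonal), `n_loci_used` (matrix) and `groups`.
#' @export
pairwise_fst <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  groups <- sort(unique(g$samples$group))
  sizes <- table(g$samples$group)
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(sizes < 2L)) stop("every group needs >= 2 individuals")
  k <- length(groups)
  theta <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  used <- matrix(0L, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    gi <- g$geno[g$samples$group == groups[i], , drop = FALSE]
    gj <- g$geno[g$samples$group == groups[j], , drop = FALSE]
    A <- 0; TOT <- 0; n_used <- 0L
    for (l in seq_len(ncol(g$geno))) {
      comp <- wc84_components(gi[, l], gj[, l])
      if (is.null(comp)) next
      A <- A + comp[1L]; TOT <- TOT + sum(comp); n_used <- n_used + 1L
    }
    theta[i, j] <- theta[j, i] <- if (n_used > 0L && TOT != 0) A / TOT else NA_real_
    used[i, j] <- used[j, i] <- n_used
  }
  structure(list(theta = theta, n_loci_used = used, groups = groups),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise Weir-Cockerham theta:\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Distance-to-centroid summary of cluster spatial distributions
#'
#' Per cluster, the centroid is the coordinate-wise mean of member lon/lat
#' (a planar approximation, adequate at the sub-continental extents used
#' here) and each member's great-circle distance to it is reported.
#' Single-member clusters get distance 0 and are flagged. The overlap
#' summary compares pairwise centroid separations with the clusters' mean
#' radii: a pair whose separation is below the sum of mean radii is
#' spatially overlapping.
#'
#' @param g a `genotype_matrix` with coordinates.
#' @param cluster_labels vector of labels, one per individual (defaults to
#'   `g$samples$group`).
#' @return list with `distances` (data.frame `id,cluster,distance_km`),
#'   `centroids` (data.frame), `separations` (matrix of centroid-centroid
#'   km), `overlap` (data.frame per pair with `separation_km`,
#'   `sum_mean_radii_km`, `overlapping`), `singletons`.
#' @export
centroid_distances <- function(g, cluster_labels = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(cluster_labels)) cluster_labels <- g$samples$group
  if (!all(c("lon", "lat") %in% names(g$samples)))
    stop("coordinates required")
  labs <- sort(unique(cluster_labels))
  cents <- do.call(rbind, lapply(labs, function(l) {
    m <- cluster_labels == l
    data.frame(cluster = l, lon = mean(g$samples$lon[m]),
               lat = mean(g$samples$lat[m]), n = sum(m))
  }))
  dist_km <- numeric(nrow(g$samples))
  for (i in seq_len(nrow(g$samples))) {
    ci <- cents[cents$cluster == cluster_labels[i], ]
    dist_km[i] <- haversine_km(g$samples$lon[i], g$samples$lat[i],
                               ci$lon, ci$lat)
  }
  distances <- data.frame(id = g$samples$id, cluster = cluster_labels,
                          distance_km = dist_km)
  k <- length(labs)
  sep <- matrix(0, k, k, dimnames = list(labs, labs))
  if (k > 1L)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      sep[i, j] <- sep[j, i] <- haversine_km(cents$lon[i], cents$lat[i],
                                             cents$lon[j], cents$lat[j])
  radii <- vapply(labs, function(l)
    mean(dist_km[cluster_labels == l]), numeric(1L))
  ov <- NULL
  if (k > 1L) {
    pr <- utils::combn(seq_len(k), 2L)
    ov <- data.frame(
      cluster_a = labs[pr[1L, ]], cluster_b = labs[pr[2L, ]],
      separation_km = sep[t(pr)],
      sum_mean_radii_km = radii[pr[1L, ]] + radii[pr[2L, ]])
    ov$overlapping <- ov$separation_km < ov$sum_mean_radii_km
  }
  list(distances = distances, centroids = cents, separations = sep,
       overlap = ov, singletons = cents$cluster[cents$n == 1L])
}

#' Read genotypes from a CSV dosage matrix plus samples table
#'
#' The matrix CSV has one row per individual (first column `id`), one column
#' per locus, values 0/1/2 or empty/NA; the samples CSV has columns
#' `id,group,lon,lat` (coordinates optional).
#'
#' @param geno_path matrix CSV path.
#' @param samples_path samples CSV path.
#' @return a `genotype_matrix`.
#' @export
read_genotypes_csv <- function(geno_path, samples_path) {
  gm <- utils::read.csv(geno_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(gm)[1L] != "id") stop("genotype CSV must start with an 'id' column")
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  geno <- as.matrix(gm[, -1L, drop = FALSE])
  storage.mode(geno) <- "integer"
  m <- match(gm$id, samples$id)
  if (anyNA(m)) stop("genotype ids missing from samples table")
  genotype_matrix(geno, samples[m, , drop = FALSE],
                  loci = colnames(gm)[-1L])
}

#' Read genotypes from a VCF (biallelic SNPs, GT field)
#'
#' Dosages are counts of the ALT allele; any missing or partially missing GT
#' becomes `NA`. Requires the vcfR package.
#'
#' @param vcf_path VCF file path.
#' @param samples_path samples CSV (`id,group,lon,lat`).
#' @return a `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(vcf_path, samples_path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1L]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    sum(as.integer(al))
  })
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  geno <- t(dose)
  m <- match(rownames(geno), samples$id)
  if (anyNA(m)) stop("VCF sample ids missing from samples table")
  genotype_matrix(geno, samples[m, , drop = FALSE], loci = colnames(geno))
}

#' Write a genotype matrix to the CSV pair format
#'
#' @param g a `genotype_matrix`.
#' @param geno_path,samples_path output CSV paths.
#' @export
write_genotypes_csv <- function(g, geno_path, samples_path) {
  df <- data.frame(id = g$samples$id, g$geno, check.names = FALSE)
  colnames(df) <- c("id", g$loci)
  utils::write.csv(df, geno_path, row.names = FALSE, na = "")
  utils::write.csv(g$samples, samples_path, row.names = FALSE)
  invisible(geno_path)
}
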