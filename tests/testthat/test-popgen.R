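test_that("SNP filter matches the hand-enumerated fixture and reports per rule", {
  out <- filter_snps(qc_fixture())
  expect_equal(out$genotypes$loci, c("l1", "l4"))
  expect_equal(out$report$n_input, 5)
  expect_equal(out$report$dropped_missing, 1)
  expect_equal(out$report$dropped_maf, 2)
  expect_equal(out$report$n_retained, 2)
  expect_equal(out$report$order, c("missingness", "maf"))
  # idempotent: filtering the filtered matrix changes nothing
  again <- filter_snps(out$genotypes)
  expect_identical(again$genotypes$geno, out$genotypes$geno)
})

test_that("permissive thresholds drop only MAF-zero loci; all-monomorphic warns", {
  out <- filter_snps(qc_fixture(), max_missing = 1, min_maf = 0)
  expect_setequal(out$genotypes$loci, c("l1", "l2", "l3", "l4"))
  mono <- toy_genotypes(cbind(a = rep(0, 4), b = rep(2, 4)))
  expect_warning(res <- filter_snps(mono), "no loci")
  expect_equal(ncol(res$genotypes$geno), 0)
})

test_that("heterozygosity is per-individual percent of called loci", {
  g <- toy_genotypes(rbind(c(1, 1, rep(0, 48)),
                           rep(NA, 50),
                           c(1, rep(0, 48), NA)))
  het <- heterozygosity_percent(g)
  expect_equal(unname(het[1]), 4.0)       # 2 het of 50 called
  expect_true(is.na(het[2]))              # nothing called
  expect_equal(unname(het[3]), 100 / 49)  # 1 het of 49 called
})

test_that("a synthetic F1 between fixed lines shows 10% overall and 100% diagnostic heterozygosity", {
  # parents: 10 diploids per group (20 vs 20 alleles, so a fixed difference
  # is genome-wide significant), fixed 0 vs 2 at 100 diagnostic loci; 900
  # further loci monomorphic in everyone; one F1 het at all diagnostics
  nd <- 100; nm <- 900
  gA <- matrix(0L, 10, nd + nm)
  gB <- cbind(matrix(2L, 10, nd), matrix(0L, 10, nm))
  f1 <- c(rep(1L, nd), rep(0L, nm))
  geno <- rbind(gA, gB, f1)
  g <- toy_genotypes(geno, groups = c(rep("A", 10), rep("B", 10), "hyb"))
  g$loci <- sprintf("L%04d", seq_len(nd + nm))
  het <- heterozygosity_percent(g)
  expect_equal(unname(het[21]), 10.0)
  diag <- diagnostic_snps(g, "A", "B")
  expect_equal(length(diag$index), nd)
  sub <- genotype_matrix(g$geno[, diag$index, drop = FALSE], g$samples)
  expect_equal(unname(heterozygosity_percent(sub)[21]), 100)
})

test_that("diagnostic SNP Fisher p-values match the exact hypergeometric oracle", {
  # fixed difference, 10 diploid individuals per group = 20 vs 20 alleles:
  # one-sided point probability 1 / C(40,20), two-sided doubles it
  gA <- matrix(0L, 10, 1); gB <- matrix(2L, 10, 1)
  g <- toy_genotypes(rbind(gA, gB), groups = rep(c("A", "B"), each = 10))
  d <- diagnostic_snps(g, "A", "B")
  p_oracle <- 2 / choose(40, 20)
  expect_equal(d$p_values[1], p_oracle, tolerance = 1e-12)
  expect_lt(d$p_values[1], 5e-8)
  expect_equal(d$index, 1L)
  # small fixed difference (3 diploids per group = 6 vs 6 alleles): exact
  # two-sided p is 2 / C(12,6) ~ 2.2e-3, far above the genome-wide cut
  gs <- toy_genotypes(rbind(matrix(0L, 3, 1), matrix(2L, 3, 1)),
                      groups = rep(c("A", "B"), each = 3))
  ds <- diagnostic_snps(gs, "A", "B")
  expect_equal(ds$p_values[1], 2 / choose(12, 6), tolerance = 1e-12)
  expect_length(ds$index, 0)
  # identical frequencies: p = 1, excluded; monomorphic: p = 1
  gi <- toy_genotypes(cbind(c(1, 1, 1, 1), c(0, 0, 0, 0)),
                      groups = rep(c("A", "B"), each = 2))
  di <- diagnostic_snps(gi, "A", "B")
  expect_equal(di$p_values, c(1, 1))
  expect_length(di$index, 0)
})

test_that("Ritland kinship hits the closed-form two-individual cases", {
  expect_equal(ritland_kinship(2, 2, 0.5), 1.0)   # both hom reference
  expect_equal(ritland_kinship(2, 0, 0.5), -1.0)  # opposite homozygotes
  expect_equal(ritland_kinship(2, 1, 0.5), 0.0)   # hom vs het
  # unusable loci: fixed frequency or missing calls
  expect_true(is.na(ritland_kinship(c(2, NA), c(NA, 2), c(0.5, 0.5))))
  expect_true(is.na(ritland_kinship(2, 2, 1)))
  # multilocus mean is the unweighted mean of per-locus estimates
  expect_equal(ritland_kinship(c(2, 2), c(2, 0), c(0.5, 0.5)), 0.0)
})

test_that("Ritland estimator is unbiased for unrelated pairs at known frequencies", {
  set.seed(42)
  L <- 10000
  p <- runif(L, 0.1, 0.9)
  kins <- replicate(30, {
    gi <- rbinom(L, 2, p); gj <- rbinom(L, 2, p)
    ritland_kinship(gi, gj, p)
  })
  expect_lt(abs(mean(kins)), 0.01)
})

test_that("pairwise kinship matrix agrees with the per-pair estimator", {
  set.seed(7)
  geno <- matrix(rbinom(8 * 50, 2, 0.4), 8, 50)
  geno[sample(length(geno), 20)] <- NA
  K <- peascape:::ritland_matrix(geno)
  fr <- colSums(geno, na.rm = TRUE) / (2 * colSums(!is.na(geno)))
  for (pair in list(c(1, 2), c(3, 8), c(4, 5)))
    expect_equal(K[pair[1], pair[2]],
                 ritland_kinship(geno[pair[1], ], geno[pair[2], ], fr),
                 tolerance = 1e-12)
})

test_that("Fst is 1 for fixed alternate groups and ~0 under panmixia", {
  gA <- matrix(0L, 10, 50); gB <- matrix(2L, 10, 50)
  g <- toy_genotypes(rbind(gA, gB), groups = rep(c("A", "B"), each = 10))
  f <- pairwise_fst(g)
  expect_equal(f$theta["A", "B"], 1.0)
  expect_equal(f$theta, t(f$theta))
  expect_true(is.na(f$theta["A", "A"]))
  set.seed(11)
  p <- runif(1000, 0.1, 0.9)
  gen <- t(replicate(100, rbinom(1000, 2, p)))
  gp <- toy_genotypes(gen, groups = rep(c("A", "B"), each = 50))
  fp <- pairwise_fst(gp)
  expect_lt(abs(fp$theta["A", "B"]), 0.02)
})

test_that("theta matches the independent WC84 oracle and is allele-label invariant", {
  cfg <- sim_config(seed = 21, n_populations = 2, n_individuals = 30,
                    n_loci = 20, missing_rate = 0.05)
  g <- gen_genotypes(cfg)
  f <- pairwise_fst(g)
  g1 <- g$geno[g$samples$group == "pop1", ]
  g2 <- g$geno[g$samples$group == "pop2", ]
  expect_equal(f$theta["pop1", "pop2"], wc84_oracle(g1, g2),
               tolerance = 1e-12)
  # swap allele labels at every locus: dosage d -> 2 - d
  gs <- g
  gs$geno <- 2L - gs$geno
  fs <- pairwise_fst(gs)
  expect_equal(fs$theta, f$theta, tolerance = 1e-12)
})

test_that("Balding-Nichols panels recover the target Fst", {
  cfg <- sim_config(seed = 31, n_populations = 2, n_individuals = 50,
                    n_loci = 1000, target_fst = 0.2, missing_rate = 0)
  g <- gen_genotypes(cfg)
  f <- pairwise_fst(g)
  expect_equal(unname(f$theta["pop1", "pop2"]), 0.2, tolerance = 0.05)
})

test_that("distance classes hold equal pair counts with deterministic tie handling", {
  # 5 individuals -> 10 pairs; 2 classes of 5
  set.seed(3)
  g <- toy_genotypes(matrix(rbinom(5 * 100, 2, 0.5), 5, 100),
                     lon = c(20, 20.5, 21, 21.5, 22), lat = rep(35, 5))
  prof <- spatial_autocorrelation(g, n_classes = 2, n_permutations = 10,
                                  seed = 1)
  expect_equal(prof$classes$n_pairs, c(5L, 5L))
  expect_lte(max(prof$classes$d_min[2], 0), prof$classes$d_max[2])
  expect_true(all(diff(prof$classes$d_mean) > 0))
  prof2 <- spatial_autocorrelation(g, n_classes = 2, n_permutations = 10,
                                   seed = 1)
  expect_identical(prof$classes, prof2$classes)
})

test_that("location-independent genotypes stay inside the permutation envelope", {
  cov <- numeric(0)
  for (s in 1:15) {
    cfg <- sim_config(seed = s, n_populations = 1, n_individuals = 40,
                      n_loci = 300, missing_rate = 0)
    g <- gen_genotypes(cfg)
    prof <- spatial_autocorrelation(g, n_classes = 10, n_permutations = 100,
                                    seed = s + 500)
    cov <- c(cov, with(prof$classes, mean(kinship >= env_lo & kinship <= env_hi)))
  }
  expect_gt(mean(cov), 0.88)
  expect_lt(mean(cov), 1)
})

test_that("isolation by distance produces decreasing kinship over the first classes", {
  hits <- 0
  for (s in 1:20) {
    cfg <- sim_config(seed = s, n_populations = 1, n_individuals = 60,
                      n_loci = 1000, ibd_strength = 0.3, missing_rate = 0)
    g <- gen_genotypes(cfg)
    prof <- spatial_autocorrelation(g, n_classes = 10, n_permutations = 2,
                                    seed = s + 900)
    k <- prof$classes$kinship
    if (k[1] > k[2] && k[2] > k[3]) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of 20 seeds
})

test_that("centroid distances match hand calculations and flag singletons", {
  # 3-point toy: centroid of cluster A is the coordinate-wise mean
  lon <- c(20, 22, 21, 30); lat <- c(34, 34, 36, 40)
  g <- toy_genotypes(matrix(0L, 4, 3), groups = c("A", "A", "A", "B"),
                     lon = lon, lat = lat)
  # l5-style monomorphic payload is irrelevant here; dosages unused
  cd <- centroid_distances(g)
  cA <- cd$centroids[cd$centroids$cluster == "A", ]
  expect_equal(cA$lon, 21); expect_equal(cA$lat, mean(c(34, 34, 36)))
  for (i in 1:3)
    expect_equal(cd$distances$distance_km[i],
                 haversine_km(lon[i], lat[i], 21, cA$lat))
  expect_equal(cd$distances$distance_km[4], 0)
  expect_equal(cd$singletons, "B")
  expect_equal(cd$separations["A", "B"],
               haversine_km(21, cA$lat, 30, 40))
  # two points symmetric about the centroid: equal distances
  g2 <- toy_genotypes(matrix(0L, 2, 2), groups = c("A", "A"),
                      lon = c(20, 22), lat = c(35, 35))
  d2 <- centroid_distances(g2)$distances$distance_km
  expect_equal(d2[1], d2[2])
})

test_that("genotype CSV pair round-trips through the reader", {
  cfg <- sim_config(seed = 51, n_populations = 2, n_individuals = 5,
                    n_loci = 20, missing_rate = 0.1)
  g <- gen_genotypes(cfg)
  fg <- withr::local_tempfile(fileext = ".csv")
  fs <- withr::local_tempfile(fileext = ".csv")
  write_genotypes_csv(g, fg, fs)
  g2 <- read_genotypes_csv(fg, fs)
  expect_equal(unname(g2$geno), unname(g$geno))
  expect_equal(g2$samples$group, g$samples$group)
  expect_equal(g2$loci, g$loci)
})
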