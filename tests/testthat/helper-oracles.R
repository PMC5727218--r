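# Independent oracles and small constructors used across the suite. These
# deliberately re-derive quantities by a different route than the package
# code they check.

# hand-built raw suitability map on a 1 x n (or nr x nc) grid
toy_map <- function(v, nr = 1L, nc = length(v), mask = NULL, mode = "raw") {
  m <- matrix(v, nr, nc)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  structure(list(values = m, mode = mode, mask = mask, n_rows = nr,
                 n_cols = nc, xll = 0, yll = 0, cellsize = 1),
            class = "suitability_map")
}

# rook-neighbour (lag-1) Moran's I, direct double-loop definition
moran_I_direct <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  x <- as.vector(m) - mean(m)
  num <- 0; wsum <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- (c - 1L) * nr + r
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      rr <- r + d[1L]; cc <- c + d[2L]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        j <- (cc - 1L) * nr + rr
        num <- num + x[i] * x[j]
        wsum <- wsum + 1
      }
    }
  }
  (length(x) / wsum) * num / sum(x^2)
}

# Weir & Cockerham (1984) theta written independently from allele counts,
# explicit loops, ratio-of-sums over loci
wc84_oracle <- function(geno1, geno2) {
  sum_a <- 0; sum_all <- 0
  for (l in seq_len(ncol(geno1))) {
    d1 <- geno1[, l]; d1 <- d1[!is.na(d1)]
    d2 <- geno2[, l]; d2 <- d2[!is.na(d2)]
    n1 <- length(d1); n2 <- length(d2)
    if (n1 == 0 || n2 == 0) next
    p1 <- sum(d1) / (2 * n1); p2 <- sum(d2) / (2 * n2)
    if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) next
    h1 <- sum(d1 == 1) / n1; h2 <- sum(d2 == 1) / n2
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    r <- 2
    nc_ <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc_) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    sum_a <- sum_a + a
    sum_all <- sum_all + a + b + cc
  }
  sum_a / sum_all
}

# all edge sets of minimum-weight spanning trees of a complete weighted
# graph, by exhaustive enumeration (k <= 8)
msn_bruteforce <- function(dm) {
  k <- nrow(dm)
  if (k < 2L) return(list(edges = character(0), weight = 0))
  pr <- which(upper.tri(dm), arr.ind = TRUE)
  ne <- nrow(pr)
  combs <- utils::combn(ne, k - 1L)
  connected <- function(es) {
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in es) {
      ri <- find(pr[e, 1L]); rj <- find(pr[e, 2L])
      if (ri != rj) parent[ri] <- rj
    }
    length(unique(vapply(seq_len(k), find, integer(1L)))) == 1L
  }
  weights <- apply(combs, 2L, function(es) sum(dm[pr[es, , drop = FALSE]]))
  conn <- apply(combs, 2L, connected)
  if (!any(conn)) stop("no spanning tree")
  wmin <- min(weights[conn])
  in_mst <- unique(as.vector(combs[, conn & weights == wmin]))
  keys <- apply(pr, 1L, function(e)
    paste(sort(rownames(dm)[e]), collapse = "|"))
  list(edges = sort(keys[in_mst]), weight = wmin)
}

edge_keys <- function(edges_df) {
  if (nrow(edges_df) == 0L) return(character(0))
  sort(apply(edges_df[, c("from", "to")], 1L, function(e)
    paste(sort(e), collapse = "|")))
}

# hand genotype_matrix constructor
toy_genotypes <- function(geno, groups = NULL, lon = NULL, lat = NULL) {
  n <- nrow(geno)
  if (is.null(groups)) groups <- rep("g1", n)
  s <- data.frame(id = sprintf("i%02d", seq_len(n)), group = groups)
  if (!is.null(lon)) { s$lon <- lon; s$lat <- lat }
  genotype_matrix(geno, s)
}

# 10 individuals x 5 loci QC fixture, hand-enumerated:
#  l1: 1 missing call of 10 (10%) -> passes missingness (threshold is >10%),
#      9 called, alt count 5/18 -> MAF 5/18 ~ 0.278 -> kept
#  l2: 2 missing (20%) -> dropped by missingness
#  l3: complete, alt count 1/20 -> MAF 0.05 exactly -> dropped (<= rule)
#  l4: complete, alt count 2/20 -> MAF 0.10 -> kept
#  l5: complete, monomorphic -> MAF 0 -> dropped
qc_fixture <- function() {
  geno <- cbind(
    l1 = c(NA, 1, 1, 1, 1, 1, 0, 0, 0, 0),
    l2 = c(NA, NA, 2, 2, 0, 0, 1, 1, 0, 0),
    l3 = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    l4 = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    l5 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  toy_genotypes(geno)
}
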