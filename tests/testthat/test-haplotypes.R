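test_that("character calling finds one SNP and one indel in the toy alignment", {
  # 4 seqs x 8 bp: substitution at column 2; shared 3-bp gap run at 4-6
  seqs <- c(s1 = "AAGTTTGC",
            s2 = "ACGTTTGC",
            s3 = "ACG---GC",
            s4 = "ACG---GC")
  ct <- call_characters(seqs)
  expect_equal(nrow(ct$characters), 2)
  expect_setequal(ct$characters$type, c("snp", "indel"))
  ind <- ct$characters[ct$characters$type == "indel", ]
  expect_equal(ind$position, 4)
  expect_equal(ind$length, 3)
  expect_equal(unname(ct$states[, "snp_2"]), c("A", "C", "C", "C"))
  expect_equal(unname(ct$states[, "indel_4"]), c("0", "0", "1", "1"))
})

test_that("invariant alignments yield zero characters and one haplotype", {
  seqs <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  ct <- call_characters(seqs)
  expect_equal(nrow(ct$characters), 0)
  hs <- collapse_haplotypes(ct)
  expect_equal(length(hs$counts), 1)
  expect_equal(unname(hs$counts), 3)
})

test_that("two distinct overlapping gap runs become two indel characters", {
  seqs <- c(a = "ACGTACGT",
            b = "AC--ACGT",
            c = "AC---CGT",
            d = "ACGTACGT")
  ct <- call_characters(seqs)
  expect_equal(sum(ct$characters$type == "indel"), 2)
  # runs (3,4) and (3,5) are separate presence/absence characters
  ind <- ct$characters[ct$characters$type == "indel", ]
  expect_setequal(ind$length, c(2, 3))
})

test_that("ragged or invalid alignments are rejected", {
  expect_error(call_characters(c(a = "ACGT", b = "ACG")), "ragged")
  expect_error(call_characters(c(a = "ACXT", b = "ACGT")), "invalid symbol")
})

test_that("collapsing groups on characters with missing-matches-anything", {
  seqs <- c(a = "AAGT", b = "ANGT", c = "ATGT", d = "ATGT")
  ct <- call_characters(seqs)
  hs <- collapse_haplotypes(ct)
  # b (N at the SNP) is ambiguous between {a} and {c,d}: goes to the larger
  expect_equal(length(hs$counts), 2)
  expect_equal(sum(hs$counts), 4)
  expect_equal(nrow(hs$ambiguous), 1)
  expect_equal(hs$ambiguous$sequence, "b")
  expect_equal(hs$assignment[2], hs$assignment[3])
})

test_that("two sequences differing only at an N collapse with a flag", {
  seqs <- c(a = "AAGT", b = "ANGT", c = "ACGT")
  ct <- call_characters(seqs)
  hs <- collapse_haplotypes(ct)
  expect_equal(length(hs$counts), 2)
  expect_equal(hs$assignment[1], hs$assignment[2])
})

test_that("generator-planted alignments are recovered exactly", {
  cfg <- sim_config(seed = 17, n_sequences = 60, seq_length = 855,
                    n_snp_sites = 5, indel_length = 6)
  al <- gen_alignment(cfg)
  ct <- call_characters(al$sequences)
  expect_equal(nrow(ct$characters), 6)  # 5 SNPs + 1 indel
  hs <- collapse_haplotypes(ct)
  expect_equal(length(hs$counts), 7)
  expect_equal(sum(hs$counts), 60)
  # grouping matches the planted truth up to labelling
  expect_equal(length(unique(paste(al$true_haplotype, hs$assignment))), 7)
})

test_that("character coding is invariant to sequence input order", {
  cfg <- sim_config(seed = 19, n_sequences = 20, seq_length = 120,
                    n_snp_sites = 3, indel_length = 4)
  al <- gen_alignment(cfg)
  ct1 <- call_characters(al$sequences)
  perm <- c(7, 1, 20, 3:6, 2, 8:19)
  ct2 <- call_characters(al$sequences[perm])
  expect_equal(ct1$characters, ct2$characters)
  expect_equal(ct1$states[perm, ], ct2$states)
  hs1 <- collapse_haplotypes(ct1); hs2 <- collapse_haplotypes(ct2)
  expect_equal(sort(unname(hs1$counts)), sort(unname(hs2$counts)))
})

test_that("minimum spanning network matches brute-force enumeration", {
  # distances h1-h2 = 1, h1-h3 = 1, h2-h3 = 2: edges {h1-h2, h1-h3}
  st <- rbind(hap1 = c("A", "A"), hap2 = c("C", "A"), hap3 = c("A", "C"))
  colnames(st) <- c("snp_1", "snp_2")
  hs <- structure(list(assignment = 1:3, counts = c(hap1 = 1L, hap2 = 1L, hap3 = 1L),
                       states = st, members = list("a", "b", "c"),
                       ambiguous = data.frame(), n_sequences = 3L),
                  class = "haplotype_set")
  net <- build_network(hs)
  oracle <- msn_bruteforce(peascape:::hap_distances(st))
  expect_equal(edge_keys(net$edges), oracle$edges)
  expect_equal(edge_keys(net$edges), c("hap1|hap2", "hap1|hap3"))
  expect_equal(sum(net$edges$distance), oracle$weight)
})

test_that("three mutually equidistant haplotypes keep all tied edges", {
  st <- rbind(hap1 = c("A", "A", "A"), hap2 = c("C", "A", "A"),
              hap3 = c("A", "C", "C"))
  # make all pairwise distances equal to 1 by a one-character design instead
  st <- rbind(hap1 = "A", hap2 = "C", hap3 = "G")
  colnames(st) <- "snp_1"
  hs <- structure(list(assignment = 1:3, counts = c(hap1 = 2L, hap2 = 1L, hap3 = 1L),
                       states = st, members = list(c("a", "b"), "c", "d"),
                       ambiguous = data.frame(), n_sequences = 4L),
                  class = "haplotype_set")
  net <- build_network(hs)
  expect_equal(nrow(net$edges), 3)
  expect_equal(edge_keys(net$edges), msn_bruteforce(net$distances)$edges)
})

test_that("network edges equal brute force on random instances up to 8 haplotypes", {
  for (s in 1:5) {
    set.seed(s)
    k <- sample(4:8, 1)
    nchar_ <- 6
    st <- matrix(sample(c("A", "C", "G", "T"), k * nchar_, replace = TRUE),
                 k, nchar_, dimnames = list(sprintf("hap%d", 1:k), NULL))
    if (anyDuplicated(apply(st, 1, paste, collapse = ""))) next
    hs <- structure(list(assignment = seq_len(k),
                         counts = stats::setNames(rep(1L, k), rownames(st)),
                         states = st, members = as.list(rownames(st)),
                         ambiguous = data.frame(), n_sequences = k),
                    class = "haplotype_set")
    net <- build_network(hs)
    oracle <- msn_bruteforce(net$distances)
    expect_setequal(edge_keys(net$edges), oracle$edges)
    # connectivity: union-find over the reported edges joins every node
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in seq_len(nrow(net$edges))) {
      i <- match(net$edges$from[e], rownames(st))
      j <- match(net$edges$to[e], rownames(st))
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
    expect_equal(length(unique(vapply(seq_len(k), find, integer(1)))), 1)
    # total weight of any single MST equals the igraph oracle when available
    if (requireNamespace("igraph", quietly = TRUE)) {
      gr <- igraph::graph_from_adjacency_matrix(net$distances, mode = "undirected",
                                                weighted = TRUE)
      expect_equal(oracle$weight,
                   sum(igraph::E(igraph::mst(gr))$weight))
    }
  }
})

test_that("singleton haplotype sets give a single node and no edges", {
  seqs <- c(a = "ACGT", b = "ACGT")
  net <- build_network(collapse_haplotypes(call_characters(seqs)))
  expect_equal(nrow(net$nodes), 1)
  expect_equal(nrow(net$edges), 0)
})

test_that("haplotype labels and exports follow the major/unique convention", {
  cfg <- sim_config(seed = 23, n_sequences = 15, seq_length = 100,
                    n_snp_sites = 3, indel_length = 3)
  al <- gen_alignment(cfg)
  hs <- collapse_haplotypes(call_characters(al$sequences))
  tab <- haplotype_table(hs)
  expect_true(all(tab$label[tab$count > 1] == "major"))
  expect_true(all(tab$label[tab$count == 1] == "unique"))
  net <- build_network(hs)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, tsv, gml)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  expect_true(any(grepl("graphml", readLines(gml))))
})
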