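#' Call polymorphic characters from an aligned sequence set
#'
#' Substitution columns with at least two distinct non-missing base states
#' become SNP characters (states A/C/G/T; N is missing; '-' within a column
#' is treated as missing for substitution calling, because the gap itself is
#' captured separately). Each distinct maximal run of '-' observed in at
#' least one sequence becomes ONE binary indel character (present/absent),
#' so a six-bp gap is a single character and one mutational step; two
#' distinct overlapping runs are two characters.
#'
#' @param seqs named character vector of equal-length aligned sequences over
#'   A, C, G, T, N, -.
#' @return a `character_table`: list with `states` (sequences x characters
#'   character matrix, NA = missing), `characters` (data.frame describing
#'   each character: `type` "snp"/"indel", `position`, `length`).
#' @export
call_characters <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) stop("empty alignment")
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alignment contains invalid symbol(s): ", paste(bad, collapse = ", "))
  L <- ncol(mat)
  # maximal gap runs per sequence; a distinct (start, end) pair = one
  # candidate indel character
  runs <- list()
  for (i in seq_len(n)) {
    g <- mat[i, ] == "-"
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      runs[[length(runs) + 1L]] <- c(starts[k], ends[k])
  }
  runs <- unique(runs)
  states <- list(); chars <- list()
  # SNP characters: gap treated as missing
  sub <- mat
  sub[sub == "-"] <- NA
  sub[sub == "N"] <- NA
  for (j in seq_len(L)) {
    obs <- unique(sub[, j][!is.na(sub[, j])])
    if (length(obs) >= 2L) {
      states[[length(states) + 1L]] <- sub[, j]
      chars[[length(chars) + 1L]] <-
        data.frame(type = "snp", position = j, length = 1L)
    }
  }
  # indel characters: presence/absence of each exact maximal run
  for (r in runs) {
    has <- vapply(seq_len(n), function(i) {
      seg <- mat[i, r[1L]:r[2L]]
      before <- r[1L] == 1L || mat[i, r[1L] - 1L] != "-"
      after <- r[2L] == L || mat[i, r[2L] + 1L] != "-"
      all(seg == "-") && before && after
    }, logical(1L))
    st <- ifelse(has, "1", "0")
    # a sequence that is all-N across the run is uninformative
    allN <- vapply(seq_len(n), function(i)
      all(mat[i, r[1L]:r[2L]] == "N"), logical(1L))
    st[allN] <- NA
    if (length(unique(st[!is.na(st)])) >= 2L) {
      states[[length(states) + 1L]] <- st
      chars[[length(chars) + 1L]] <-
        data.frame(type = "indel", position = r[1L],
                   length = r[2L] - r[1L] + 1L)
    }
  }
  if (length(states)) {
    sm <- do.call(cbind, states)
    rownames(sm) <- names(seqs)
    ci <- do.call(rbind, chars)
    # deterministic order: by position, snp before indel at equal position
    o <- order(ci$position, ci$type != "snp")
    sm <- sm[, o, drop = FALSE]
    ci <- ci[o, , drop = FALSE]
    rownames(ci) <- NULL
    colnames(sm) <- sprintf("%s_%d", ci$type, ci$position)
  } else {
    sm <- matrix(NA_character_, n, 0L, dimnames = list(names(seqs), NULL))
    ci <- data.frame(type = character(0), position = integer(0),
                     length = integer(0))
  }
  structure(list(states = sm, characters = ci), class = "character_table")
}

#' Collapse sequences into haplotypes on the called characters
#'
#' Sequences identical across all characters are one haplotype; a missing
#' state (NA) matches anything. Sequences with complete character data are
#' grouped first by exact state; sequences carrying missing data are then
#' assigned to the compatible haplotype — when more than one is compatible
#' the largest group wins and the assignment is flagged as ambiguous in the
#' report. A sequence compatible with none founds a new haplotype.
#'
#' @param ct a `character_table` from [call_characters()].
#' @return a `haplotype_set`: list with `assignment` (integer per sequence),
#'   `counts`, `states` (haplotypes x characters representative states),
#'   `members` (list of sequence ids), `ambiguous` (data.frame of flagged
#'   assignments), `n_sequences`.
#' @export
collapse_haplotypes <- function(ct) {
  stopifnot(inherits(ct, "character_table"))
  sm <- ct$states
  n <- nrow(sm)
  if (ncol(sm) == 0L) {
    return(structure(list(
      assignment = rep(1L, n), counts = stats::setNames(n, "hap1"),
      states = matrix(character(0), 1L, 0L, dimnames = list("hap1", NULL)),
      members = list(hap1 = rownames(sm)),
      ambiguous = data.frame(sequence = character(0), haplotype = integer(0)),
      n_sequences = n), class = "haplotype_set"))
  }
  complete <- !apply(sm, 1L, anyNA)
  hap_states <- list(); hap_keys <- character(0); assignment <- integer(n)
  key <- unname(apply(sm, 1L, paste, collapse = "\r"))
  for (i in which(complete)) {
    hit <- match(key[i], hap_keys)
    if (!is.na(hit)) assignment[i] <- hit
    else {
      hap_states[[length(hap_states) + 1L]] <- sm[i, ]
      hap_keys <- c(hap_keys, key[i])
      assignment[i] <- length(hap_states)
    }
  }
  ambiguous <- list()
  # incomplete sequences, largest current groups first for deterministic ties
  for (i in which(!complete)) {
    compat <- which(vapply(hap_states, function(h) {
      ok <- is.na(sm[i, ]) | is.na(h) | sm[i, ] == h
      all(ok)
    }, logical(1L)))
    if (length(compat) == 0L) {
      hap_states[[length(hap_states) + 1L]] <- sm[i, ]
      assignment[i] <- length(hap_states)
    } else if (length(compat) == 1L) {
      assignment[i] <- compat
    } else {
      sizes <- tabulate(assignment, nbins = length(hap_states))[compat]
      pick <- compat[order(-sizes, compat)][1L]
      assignment[i] <- pick
      ambiguous[[length(ambiguous) + 1L]] <-
        data.frame(sequence = rownames(sm)[i], haplotype = pick,
                   n_compatible = length(compat))
    }
  }
  k <- length(hap_states)
  hnames <- sprintf("hap%d", seq_len(k))
  counts <- stats::setNames(tabulate(assignment, nbins = k), hnames)
  states <- do.call(rbind, hap_states)
  rownames(states) <- hnames
  colnames(states) <- colnames(sm)
  members <- lapply(seq_len(k), function(h) rownames(sm)[assignment == h])
  names(members) <- hnames
  amb <- if (length(ambiguous)) do.call(rbind, ambiguous) else
    data.frame(sequence = character(0), haplotype = integer(0),
               n_compatible = integer(0))
  structure(list(assignment = assignment, counts = counts, states = states,
                 members = members, ambiguous = amb, n_sequences = n),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotype(s) from %d sequence(s), %d character(s)\n",
              length(x$counts), x$n_sequences, ncol(x$states)))
  print(x$counts)
  invisible(x)
}

# pairwise character distance between haplotype state rows; an indel
# character is one step like any other; characters missing in either
# haplotype are skipped
hap_distances <- function(states) {
  k <- nrow(states)
  d <- matrix(0L, k, k, dimnames = list(rownames(states), rownames(states)))
  if (k < 2L) return(d)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    use <- !is.na(states[i, ]) & !is.na(states[j, ])
    d[i, j] <- d[j, i] <- sum(states[i, use] != states[j, use])
  }
  d
}

# union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

#' Build a minimum-spanning haplotype network
#'
#' Nodes are haplotypes weighted by their counts; the edge set is the
#' minimum spanning network: every edge that appears in at least one minimum
#' spanning tree of the pairwise character-distance graph (ties retained).
#' An edge (u, v) belongs to some MST exactly when u and v are not already
#' connected by edges strictly shorter than d(u, v) (the cut criterion), and
#' the network is connected by construction. Indel characters count one
#' mutational step. Haplotypes carried by more than one sequence are
#' labelled "major", singletons "unique".
#'
#' @param h a `haplotype_set`.
#' @return a `haplo_network`: list with `nodes` (data.frame
#'   `haplotype,count,label`), `edges` (data.frame `from,to,distance`),
#'   `distances` (matrix).
#' @export
build_network <- function(h) {
  stopifnot(inherits(h, "haplotype_set"))
  k <- length(h$counts)
  dm <- hap_distances(h$states)
  nodes <- data.frame(haplotype = names(h$counts),
                      count = as.integer(h$counts),
                      label = ifelse(h$counts > 1L, "major", "unique"),
                      stringsAsFactors = FALSE)
  if (k < 2L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             distance = integer(0)),
                          distances = dm), class = "haplo_network"))
  }
  pr <- which(upper.tri(dm), arr.ind = TRUE)
  w <- dm[upper.tri(dm)]
  edges <- list()
  for (lev in sort(unique(w))) {
    # components under edges strictly shorter than this level
    parent <- uf_new(k)
    shorter <- which(w < lev)
    for (e in shorter) {
      ri <- uf_find(parent, pr[e, 1L]); rj <- uf_find(parent, pr[e, 2L])
      if (ri != rj) parent[ri] <- rj
    }
    for (e in which(w == lev)) {
      ri <- uf_find(parent, pr[e, 1L]); rj <- uf_find(parent, pr[e, 2L])
      if (ri != rj)
        edges[[length(edges) + 1L]] <-
          data.frame(from = rownames(dm)[pr[e, 1L]],
                     to = rownames(dm)[pr[e, 2L]],
                     distance = w[e], stringsAsFactors = FALSE)
    }
  }
  ed <- do.call(rbind, edges)
  ed <- ed[order(ed$distance, ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = nodes, edges = ed, distances = dm),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a haplotype network as an edge-list TSV and a GraphML file
#'
#' @param net a `haplo_network`.
#' @param tsv_path edge-list TSV output path (NULL to skip).
#' @param graphml_path GraphML output path (NULL to skip).
#' @export
write_network <- function(net, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(net$edges, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(graphml_path)) {
    n <- net$nodes; e <- net$edges
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="count" for="node" attr.name="count" attr.type="int"/>',
      '  <key id="label" for="node" attr.name="label" attr.type="string"/>',
      '  <key id="distance" for="edge" attr.name="distance" attr.type="int"/>',
      '  <graph edgedefault="undirected">',
      sprintf('    <node id="%s"><data key="count">%d</data><data key="label">%s</data></node>',
              n$haplotype, n$count, n$label),
      if (nrow(e))
        sprintf('    <edge source="%s" target="%s"><data key="distance">%d</data></edge>',
                e$from, e$to, e$distance),
      '  </graph>', '</graphml>')
    writeLines(lines, graphml_path)
  }
  invisible(net)
}

#' Haplotype table as a data.frame (for CSV export)
#'
#' @param h a `haplotype_set`.
#' @return data.frame with haplotype id, count, label and character states.
#' @export
haplotype_table <- function(h) {
  df <- data.frame(haplotype = names(h$counts), count = as.integer(h$counts),
                   label = ifelse(h$counts > 1L, "major", "unique"),
                   stringsAsFactors = FALSE)
  if (ncol(h$states))
    df <- cbind(df, as.data.frame(h$states, stringsAsFactors = FALSE))
  df
}
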