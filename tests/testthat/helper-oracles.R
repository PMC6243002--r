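# Shared fixtures and independent oracles used across test files.

small_truth <- function(seed = 42, ...) {
  generate_community(n_cellular = 10L, n_ncldv = 8L, seed = seed, ...)
}

# Independent connected-components oracle (igraph).
oracle_components <- function(nodes, edge_a, edge_b) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edge_a, to = edge_b),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  unname(igraph::components(g)$membership[nodes])
}

# dimension-name-free co-membership matrix for partition comparison
co_membership <- function(labels) {
  m <- outer(labels, labels, "==")
  dimnames(m) <- NULL
  m
}

# Independent PD oracle for a pruned leaf set: total length of the minimal
# subtree spanning the kept leaves. An edge contributes iff kept leaves lie
# on both sides of it.
oracle_spanning_pd <- function(tree, keep_leaves) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  keep_idx <- match(keep_leaves, tree$tip.label)
  total <- 0
  for (k in seq_len(nrow(tree$edge))) {
    below <- tips_under(tree$edge[k, 2])
    n_below <- length(intersect(below, keep_idx))
    if (n_below >= 1 && n_below < length(keep_idx))
      total <- total + tree$edge.length[k]
  }
  total
}

# Independent all-pairs edge-weight recomputation with explicit loops.
oracle_edge_weights <- function(og) {
  genomes <- sort(names(og$totals))
  out <- list()
  for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
    if (i >= j) next
    a <- genomes[i]; b <- genomes[j]
    cnt <- og$counts
    ogs_a <- cnt$og_id[cnt$genome_id == a]
    ogs_b <- cnt$og_id[cnt$genome_id == b]
    shared <- intersect(ogs_a, ogs_b)
    pa <- 100 * sum(cnt$n_proteins[cnt$genome_id == a &
                                     cnt$og_id %in% shared]) /
      og$totals[[a]]
    pb <- 100 * sum(cnt$n_proteins[cnt$genome_id == b &
                                     cnt$og_id %in% shared]) /
      og$totals[[b]]
    out[[paste(a, b)]] <- (pa + pb) / 2
  }
  out
}

# Random orthogroup table for property tests.
random_og_table <- function(n_genomes, n_og, seed) {
  withr::local_seed(seed)
  genomes <- sprintf("g%02d", seq_len(n_genomes))
  rows <- list()
  for (k in seq_len(n_og)) {
    members <- genomes[runif(n_genomes) < 0.5]
    if (!length(members)) next
    rows[[length(rows) + 1L]] <- data.frame(
      og_id = sprintf("OG%04d", k), genome_id = members,
      n_proteins = sample(1:3, length(members), replace = TRUE))
  }
  counts <- do.call(rbind, rows)
  sums <- tapply(counts$n_proteins, counts$genome_id, sum)
  totals <- setNames(rep(2, n_genomes), genomes)
  totals[names(sums)] <- as.numeric(sums)
  orthogroup_table(counts, totals + 5)
}
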