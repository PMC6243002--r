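#' Gene-sharing weight between two genomes
#'
#' For a pair of genomes, the shared orthogroups are those with at least
#' one protein from each. Each genome's directed percentage is 100 times
#' its number of proteins in shared orthogroups (paralogs included) over
#' its total protein count; the edge weight is the arithmetic mean of the
#' two directed percentages. A union-based alternative reading — shared
#' proteins over the pair's combined totals — is available via
#' \code{mode = "union"}.
#'
#' @param table a \code{gv_orthogroups} from [read_orthogroups()] or
#'   [orthogroup_table()].
#' @param a,b genome ids.
#' @param mode \code{"mean"} (default) or \code{"union"}.
#' @return edge weight in percent, in [0, 100].
#' @examples
#' og <- orthogroup_table(data.frame(
#'   og_id = c("OG1", "OG1"), genome_id = c("gA", "gB"),
#'   n_proteins = c(4L, 5L)), totals = c(gA = 10, gB = 20))
#' edge_weight(og, "gA", "gB")  # mean of 40% and 25% = 32.5
#' @export
edge_weight <- function(table, a, b, mode = c("mean", "union")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "gv_orthogroups"))
  if (a == b) stopf("edge weight undefined for a genome with itself")
  for (g in c(a, b)) {
    if (!g %in% names(table$totals))
      stopf("genome '%s' not in orthogroup table", g)
    if (table$totals[[g]] <= 0) stopf("genome '%s' has zero total proteins", g)
  }
  cnt <- table$counts
  in_a <- cnt[cnt$genome_id == a, ]
  in_b <- cnt[cnt$genome_id == b, ]
  shared <- intersect(in_a$og_id, in_b$og_id)
  shared_a <- sum(in_a$n_proteins[in_a$og_id %in% shared])
  shared_b <- sum(in_b$n_proteins[in_b$og_id %in% shared])
  if (mode == "mean") {
    (100 * shared_a / table$totals[[a]] +
     100 * shared_b / table$totals[[b]]) / 2
  } else {
    100 * (shared_a + shared_b) / (table$totals[[a]] + table$totals[[b]])
  }
}

#' Build the gene-sharing network
#'
#' Scores every unordered genome pair with [edge_weight()] and keeps edges
#' with weight at least \code{min_weight} percent (default 18%, inclusive).
#' Genomes whose every pair falls below the threshold remain in the node
#' set as isolated nodes — a completely disconnected genome is itself a
#' finding.
#'
#' @param table a \code{gv_orthogroups}.
#' @param min_weight minimum edge weight, percent.
#' @param exclude character vector of genome ids to drop before scoring
#'   (e.g. an over-represented clade such as a block of poxviruses).
#' @param mode passed to [edge_weight()].
#' @return A \code{gv_network}: list with \code{edges} (data frame
#'   \code{genome_a}, \code{genome_b}, \code{weight}; canonical a < b) and
#'   \code{nodes} (character vector including isolated genomes).
#' @export
build_network <- function(table, min_weight = 18, exclude = character(0),
                          mode = c("mean", "union")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "gv_orthogroups"))
  nodes <- sort(setdiff(names(table$totals), exclude))
  if (length(nodes) < 2) stopf("need at least two genomes to build a network")
  pairs <- utils::combn(nodes, 2)
  weights <- vapply(seq_len(ncol(pairs)), function(k)
    edge_weight(table, pairs[1, k], pairs[2, k], mode = mode), numeric(1))
  keep <- weights >= min_weight
  edges <- data.frame(genome_a = pairs[1, keep], genome_b = pairs[2, keep],
                      weight = weights[keep], stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, min_weight = min_weight),
            class = "gv_network")
}

#' @export
print.gv_network <- function(x, ...) {
  cat(sprintf("gv_network: %d nodes, %d edges (weight >= %.1f%%)\n",
              length(x$nodes), nrow(x$edges), x$min_weight))
  invisible(x)
}

#' Connectivity report for a gene-sharing network
#'
#' @param network a \code{gv_network} from [build_network()].
#' @return list with \code{degree} (named integer over nodes),
#'   \code{components} (data frame \code{genome_id}, \code{component}),
#'   \code{n_components}, and \code{isolated} (ids with degree 0).
#' @export
connectivity_report <- function(network) {
  stopifnot(inherits(network, "gv_network"))
  nodes <- network$nodes
  edges <- network$edges
  deg <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(c(edges$genome_a, edges$genome_b))
    deg[names(tab)] <- as.integer(tab)
  }
  comp <- components_single(nodes, edges)
  list(degree = deg,
       components = data.frame(genome_id = nodes, component = comp,
                               stringsAsFactors = FALSE),
       n_components = length(unique(comp)),
       isolated = names(deg)[deg == 0])
}
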