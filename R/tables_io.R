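#' Read a newick tree with branch lengths
#'
#' Wraps \code{ape::read.tree} and enforces the presence of branch lengths,
#' without which phylogenetic diversity is undefined.
#'
#' @param path path to a newick file.
#' @return an \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("newick file not found: %s", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stopf("could not parse newick in %s", path)
  if (is.null(tr$edge.length))
    stopf("tree in %s has no branch lengths; phylogenetic diversity undefined",
          path)
  tr
}

#' @rdname read_newick
#' @param tree a \code{phylo} object.
#' @return \code{write_newick} returns \code{path} invisibly. Branch lengths
#'   are serialized to 10 significant digits.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path, digits = 10)
  invisible(path)
}

#' Read a pairwise ANI table
#'
#' Accepts a headered TSV with columns \code{genome_a}, \code{genome_b},
#' \code{ani} (percent) and \code{aligned_bp}, or a headerless 4-column
#' whitespace-separated table in that order (the shape of fastANI output with
#' fragment counts pre-converted to aligned bases). Pairs may appear in both
#' orientations with different values (asymmetric estimator); self-pairs are
#' skipped with a warning.
#'
#' @param path path to the table.
#' @return data frame with columns \code{genome_a}, \code{genome_b},
#'   \code{ani}, \code{aligned_bp}.
#' @export
read_ani_table <- function(path) {
  if (!file.exists(path)) stopf("ANI table not found: %s", path)
  first <- readLines(path, n = 1L)
  header <- grepl("genome_a", first)
  tab <- read.table(path, header = header, stringsAsFactors = FALSE)
  if (!header) {
    if (ncol(tab) < 4L) stopf("ANI table needs 4 columns")
    tab <- tab[, 1:4]
    names(tab) <- c("genome_a", "genome_b", "ani", "aligned_bp")
  }
  tab$ani <- as.numeric(tab$ani)
  tab$aligned_bp <- as.numeric(tab$aligned_bp)
  if (any(is.na(tab$ani)) || any(tab$ani < 0 | tab$ani > 100))
    stopf("ANI values must lie in [0, 100]")
  self <- tab$genome_a == tab$genome_b
  if (any(self)) {
    warnf("dropping %d self-pair(s) from ANI table (e.g. %s)",
          sum(self), tab$genome_a[self][1])
    tab <- tab[!self, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Orthogroup tables: construction and I/O
#'
#' An orthogroup table records, for each orthogroup and each genome, how many
#' of that genome's proteins belong to the group, together with each genome's
#' total protein count (singleton and unassigned proteins make the totals
#' exceed the per-genome sums). It is the substrate of the gene-sharing
#' network.
#'
#' \code{read_orthogroups} accepts the OrthoFinder text layout, one group per
#' row: \code{"OG0000001: genomeA|p1 genomeA|p2 genomeB|p7"}. Totals default
#' to the per-genome sums over groups and can be overridden with an explicit
#' named vector (e.g. total gene calls per genome).
#'
#' @param path path to an orthogroups text file.
#' @param totals optional named numeric vector of total proteins per genome.
#' @return A \code{gv_orthogroups}: list with \code{counts} (data frame
#'   \code{og_id}, \code{genome_id}, \code{n_proteins}) and \code{totals}
#'   (named numeric).
#' @export
read_orthogroups <- function(path, totals = NULL) {
  if (!file.exists(path)) stopf("orthogroup file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(ln) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stopf("unparsable orthogroup row: '%s'", ln)
    og <- trimws(parts[1])
    members <- strsplit(trimws(paste(parts[-1], collapse = ":")), "\\s+")[[1]]
    genome <- sub("\\|.*$", "", members)
    cnt <- table(genome)
    data.frame(og_id = og, genome_id = names(cnt),
               n_proteins = as.integer(cnt), stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, recs)
  orthogroup_table(counts, totals)
}

#' @rdname read_orthogroups
#' @param counts data frame with columns \code{og_id}, \code{genome_id},
#'   \code{n_proteins}.
#' @export
orthogroup_table <- function(counts, totals = NULL) {
  need <- c("og_id", "genome_id", "n_proteins")
  if (!all(need %in% names(counts)))
    stopf("orthogroup counts need columns %s", paste(need, collapse = ", "))
  if (any(counts$n_proteins < 0)) stopf("orthogroup counts must be >= 0")
  counts <- counts[counts$n_proteins > 0, , drop = FALSE]
  sums <- tapply(counts$n_proteins, counts$genome_id, sum)
  sums <- setNames(as.numeric(sums), names(sums))
  if (is.null(totals)) totals <- sums
  else {
    miss <- setdiff(names(sums), names(totals))
    if (length(miss))
      stopf("totals missing for genome(s): %s", paste(miss, collapse = ", "))
    low <- names(sums)[totals[names(sums)] < sums]
    if (length(low))
      stopf("totals below in-group protein sum for: %s",
            paste(low, collapse = ", "))
  }
  structure(list(counts = counts, totals = totals),
            class = "gv_orthogroups")
}

#' @export
print.gv_orthogroups <- function(x, ...) {
  cat(sprintf("gv_orthogroups: %d orthogroups x %d genomes\n",
              length(unique(x$counts$og_id)), length(x$totals)))
  invisible(x)
}

#' @rdname read_orthogroups
#' @param og a \code{gv_orthogroups} object.
#' @export
write_orthogroups <- function(og, path) {
  stopifnot(inherits(og, "gv_orthogroups"))
  rows <- split(og$counts, og$counts$og_id)
  lines <- vapply(names(rows), function(id) {
    r <- rows[[id]]
    members <- unlist(Map(function(g, n) paste0(g, "|p", seq_len(n)),
                          r$genome_id, r$n_proteins))
    paste0(id, ": ", paste(members, collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write contig depth tables
#'
#' @param path path to a TSV with columns \code{contig_id}, \code{length_bp},
#'   \code{mean_depth} and optionally \code{bin_id} (missing values mean
#'   unbinned).
#' @return data frame with those four columns.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stopf("depth table not found: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("contig_id", "length_bp", "mean_depth")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("depth table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"bin_id" %in% names(tab)) tab$bin_id <- "unbinned"
  tab$bin_id[is.na(tab$bin_id) | !nzchar(tab$bin_id)] <- "unbinned"
  if (anyDuplicated(tab$contig_id)) stopf("duplicate contig_id in depth table")
  if (any(tab$length_bp < 1)) stopf("contig lengths must be >= 1 bp")
  if (any(tab$mean_depth < 0)) stopf("mean depth must be >= 0")
  tab[, c("contig_id", "length_bp", "mean_depth", "bin_id")]
}

#' @rdname read_depth_table
#' @param depth a depth-table data frame.
#' @export
write_depth_table <- function(depth, path) {
  write.table(depth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network edge list as TSV (node_a, node_b, weight_percent)
#'
#' @param edges data frame with columns \code{genome_a}, \code{genome_b},
#'   \code{weight} as produced by [build_network()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  out <- data.frame(node_a = edges$genome_a, node_b = edges$genome_b,
                    weight_percent = edges$weight)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
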