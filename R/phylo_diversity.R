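#' Trim gapped alignment columns
#'
#' Removes columns with less than \code{min_info_fraction} sequence
#' information, i.e. columns where the fraction of non-gap characters falls
#' below the threshold (default 10%, the rule applied to the marker
#' alignments before tree building). An optional secondary low-information
#' rule drops columns whose most frequent non-gap residue has a frequency
#' (among non-gap characters) below \code{low_info_min_freq}; it is off by
#' default because the published procedure names no parameter for it.
#'
#' @param aln a \code{gv_msa} from [read_alignment()] or [as_msa()].
#' @param min_info_fraction minimum fraction of non-gap characters per
#'   column, in (0, 1].
#' @param low_info_min_freq optional minimum modal-residue frequency;
#'   \code{NULL} disables the secondary rule.
#' @return the trimmed \code{gv_msa}; attribute \code{aligned_residues}
#'   holds the per-sequence non-gap residue counts after trimming, and
#'   attribute \code{kept_columns} the indices of retained columns.
#' @examples
#' aln <- as_msa(c(s1 = "MK-", s2 = "M--", s3 = "M--"))
#' ncol_kept <- nchar(trim_columns(aln, 0.10)[[1]])
#' @export
trim_columns <- function(aln, min_info_fraction = 0.10,
                         low_info_min_freq = NULL) {
  stopifnot(inherits(aln, "gv_msa"))
  if (min_info_fraction <= 0 || min_info_fraction > 1)
    stopf("min_info_fraction must lie in (0, 1]")
  mat <- msa_matrix(aln)
  is_gap <- mat == "-" | mat == "."
  info <- colMeans(!is_gap)
  keep <- info >= min_info_fraction
  if (!is.null(low_info_min_freq)) {
    modal <- vapply(seq_len(ncol(mat)), function(j) {
      res <- mat[!is_gap[, j], j]
      if (!length(res)) return(0)
      max(table(res)) / length(res)
    }, numeric(1))
    keep <- keep & modal >= low_info_min_freq
  }
  if (!any(keep)) stopf("trimming removed every alignment column")
  trimmed <- mat[, keep, drop = FALSE]
  out <- as_msa(setNames(apply(trimmed, 1L, paste, collapse = ""),
                         names(aln)))
  attr(out, "aligned_residues") <-
    setNames(rowSums(!(trimmed == "-" | trimmed == ".")), names(aln))
  attr(out, "kept_columns") <- which(keep)
  out
}

#' Concatenate marker alignments into a partitioned super-alignment
#'
#' Joins per-marker alignments over a common genome universe; a genome
#' missing from a partition is filled with gaps across that partition.
#' Partition boundaries are recorded for downstream use.
#'
#' @param alignments list of \code{gv_msa} objects (named for the partition
#'   map, e.g. by marker id).
#' @param id_universe optional character vector of genome ids; defaults to
#'   the union of all partition ids.
#' @return a \code{gv_msa} over \code{id_universe} with attribute
#'   \code{partitions}: data frame \code{partition}, \code{start},
#'   \code{end} (1-based inclusive).
#' @export
concatenate_alignments <- function(alignments, id_universe = NULL) {
  stopifnot(length(alignments) >= 1)
  for (aln in alignments) stopifnot(inherits(aln, "gv_msa"))
  ids <- unique(unlist(lapply(alignments, names)))
  if (is.null(id_universe)) id_universe <- sort(ids)
  extra <- setdiff(ids, id_universe)
  if (length(extra))
    stopf("alignment id(s) outside the id universe: %s",
          paste(extra, collapse = ", "))
  if (is.null(names(alignments)))
    names(alignments) <- sprintf("partition_%d", seq_along(alignments))
  widths <- vapply(alignments, function(a) nchar(a[[1]]), numeric(1))
  starts <- cumsum(c(1, widths[-length(widths)]))
  rows <- vapply(id_universe, function(g) {
    paste(vapply(seq_along(alignments), function(k) {
      a <- alignments[[k]]
      if (g %in% names(a)) a[[g]]
      else strrep("-", widths[k])
    }, character(1)), collapse = "")
  }, character(1))
  out <- as_msa(rows)
  attr(out, "partitions") <- data.frame(
    partition = names(alignments), start = as.integer(starts),
    end = as.integer(starts + widths - 1), stringsAsFactors = FALSE)
  out
}

#' Phylogenetic diversity: the sum of branch lengths
#'
#' PD of a tree is the sum of all its branch lengths; it does not depend on
#' the root position.
#'
#' @param tree a \code{phylo} object with branch lengths.
#' @return a single number, in units of the branch lengths
#'   (substitutions/site for the marker trees).
#' @export
phylogenetic_diversity <- function(tree) {
  if (is.null(tree$edge.length))
    stopf("tree has no branch lengths; PD undefined")
  sum(tree$edge.length)
}

#' Gain in phylogenetic diversity contributed by novel taxa
#'
#' Measures how much a set of novel leaves expands a tree's total PD:
#' \code{increase_percent = 100 * (pd_with - pd_without) / pd_without}.
#' Two modes are supported. In pruning mode (default) the "without" tree is
#' obtained by dropping the novel leaves from \code{tree_with}, collapsing
#' unifurcations and summing branch lengths through collapsed nodes. In
#' two-tree mode an independently inferred \code{tree_without} is supplied
#' and used as-is.
#'
#' @param tree_with tree containing the novel leaves.
#' @param novel_ids leaf labels of the novel taxa (pruning mode).
#' @param tree_without optional independently inferred tree without the
#'   novel taxa (two-tree mode; \code{novel_ids} then only documents which
#'   taxa are novel).
#' @return list of class \code{gv_pd}: \code{pd_with}, \code{pd_without},
#'   \code{increase_percent}, \code{mode}.
#' @examples
#' tr <- ape::read.tree(text = "(A:0.1,(B:0.2,C:0.3):0.4);")
#' pd_increase(tr, "C")
#' @export
pd_increase <- function(tree_with, novel_ids, tree_without = NULL) {
  pd_with <- phylogenetic_diversity(tree_with)
  if (is.null(tree_without)) {
    if (length(novel_ids) == 0) {
      warnf("no novel leaves supplied; PD increase is 0")
      return(structure(list(pd_with = pd_with, pd_without = pd_with,
                            increase_percent = 0, mode = "prune"),
                       class = "gv_pd"))
    }
    missing_ids <- setdiff(novel_ids, tree_with$tip.label)
    if (length(missing_ids))
      stopf("novel id(s) not in tree: %s", paste(missing_ids, collapse = ", "))
    if (length(tree_with$tip.label) - length(novel_ids) < 2L)
      stopf("pruning would leave fewer than two leaves")
    pruned <- ape::drop.tip(tree_with, novel_ids, collapse.singles = TRUE)
    pd_without <- phylogenetic_diversity(pruned)
    mode <- "prune"
  } else {
    pd_without <- phylogenetic_diversity(tree_without)
    mode <- "two_tree"
  }
  structure(list(pd_with = pd_with, pd_without = pd_without,
                 increase_percent = 100 * (pd_with - pd_without) / pd_without,
                 mode = mode),
            class = "gv_pd")
}

#' @export
print.gv_pd <- function(x, ...) {
  cat(sprintf(
    "PD with novel taxa %.6g, without %.6g: +%.1f%% (%s mode)\n",
    x$pd_with, x$pd_without, x$increase_percent, x$mode))
  invisible(x)
}

#' Assign taxonomy to query leaves from labeled reference leaves
#'
#' For each query leaf, walks from the leaf toward the root to the smallest
#' clade that contains at least one reference leaf. If every reference leaf
#' in that clade carries the same taxonomy label the query is assigned that
#' label; if the clade mixes labels the query stays unassigned — mirroring
#' how MCP sequences are classified by their nearest labeled neighbors in
#' the protein tree.
#'
#' @param tree a \code{phylo} object.
#' @param reference_labels named character vector: leaf label ->
#'   taxonomy label. Must cover at least one leaf and no query.
#' @param query_ids leaf labels to classify.
#' @return named character vector over \code{query_ids}; unassignable
#'   queries get \code{NA}.
#' @export
assign_taxonomy_by_tree <- function(tree, reference_labels, query_ids) {
  ref_ids <- names(reference_labels)
  bad <- setdiff(ref_ids, tree$tip.label)
  if (length(bad))
    stopf("reference leaf(s) not in tree: %s", paste(bad, collapse = ", "))
  if (!length(ref_ids)) stopf("no reference leaves supplied")
  missing_q <- setdiff(query_ids, tree$tip.label)
  if (length(missing_q))
    stopf("query leaf(s) not in tree: %s", paste(missing_q, collapse = ", "))
  overlap <- intersect(query_ids, ref_ids)
  if (length(overlap))
    stopf("query leaf(s) also labeled as reference: %s",
          paste(overlap, collapse = ", "))
  n_tip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    stack <- node; tips <- integer(0)
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v <= n_tip) tips <- c(tips, v)
      else stack <- c(stack, kids[[as.character(v)]])
    }
    tips
  }
  ref_idx <- match(ref_ids, tree$tip.label)
  out <- setNames(rep(NA_character_, length(query_ids)), query_ids)
  for (q in query_ids) {
    node <- match(q, tree$tip.label)
    repeat {
      node <- parent[node]
      if (node == 0) break
      tips <- tips_under(node)
      refs_here <- intersect(tips, ref_idx)
      if (length(refs_here)) {
        labels <- unique(reference_labels[tree$tip.label[refs_here]])
        if (length(labels) == 1L) out[q] <- labels
        break
      }
    }
  }
  out
}
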