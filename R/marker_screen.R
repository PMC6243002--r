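#' Profile metagenome bins by NCLDV marker content
#'
#' Applies the giant-virus discovery rule to a marker hit table: a bin is a
#' candidate when it carries more than five distinct ancestral NCVOG markers
#' and/or the major capsid protein (MCP, NCVOG0022). Completeness is the
#' fraction of the 20 ancestral markers present. A bin is eligible for
#' phylogenomic placement when it carries at least three of the five core
#' markers (bins with fewer are excluded from tree building).
#'
#' "More than five different hits" is counted by default as more than five
#' distinct marker identities, not raw hit rows; set
#' \code{count_mode = "rows"} for the alternative reading (total retained
#' hit rows).
#'
#' @param hits hit table data frame as returned by [read_hit_table()].
#' @param markers a \code{gv_markers} from [marker_definition()].
#' @param evalue_cutoff retain hits with e-value at or below this cutoff.
#' @param all_bins optional character vector of bin ids that must appear in
#'   the output even with zero hits (completeness 0), e.g. every bin in the
#'   contig-to-bin map.
#' @param count_mode \code{"distinct"} (default) or \code{"rows"}.
#' @return data frame with one row per bin: \code{bin_id},
#'   \code{n_distinct_markers}, \code{n_hit_rows}, \code{has_mcp},
#'   \code{distinct_core5}, \code{completeness}, \code{is_candidate},
#'   \code{phylogeny_eligible}, plus a \code{copy_numbers} attribute (bin x
#'   marker count matrix for qualitative comparison with reference genomes).
#' @examples
#' md <- marker_definition()
#' hits <- data.frame(query_id = paste0("c1_", 1:6), bin_id = "bin1",
#'                    marker_id = md$marker_ids[2:7], evalue = 1e-10,
#'                    bitscore = 100, aligned_len = 200L)
#' profile_bins(hits, md)$is_candidate
#' @export
profile_bins <- function(hits, markers, evalue_cutoff = 1e-6,
                         all_bins = NULL,
                         count_mode = c("distinct", "rows")) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(markers, "gv_markers"))
  if (evalue_cutoff <= 0) stopf("evalue_cutoff must be > 0")
  known <- markers$marker_ids
  if (is.null(hits))
    hits <- data.frame(query_id = character(), bin_id = character(),
                       marker_id = character(), evalue = numeric(),
                       bitscore = numeric(), aligned_len = integer(),
                       stringsAsFactors = FALSE)
  if (nrow(hits)) {
    alien <- !(hits$marker_id %in% known)
    if (any(alien)) {
      warnf("excluding %d hit(s) with marker id(s) outside the definition: %s",
            sum(alien), paste(unique(hits$marker_id[alien]), collapse = ", "))
      hits <- hits[!alien, , drop = FALSE]
    }
    hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  }
  bins <- sort(unique(c(hits$bin_id, all_bins)))
  n20 <- length(known)
  copy_mat <- matrix(0L, nrow = length(bins), ncol = n20,
                     dimnames = list(bins, known))
  rows <- lapply(bins, function(b) {
    h <- hits[hits$bin_id == b, , drop = FALSE]
    distinct <- unique(h$marker_id)
    if (nrow(h)) {
      cnt <- table(h$marker_id)
      copy_mat[b, names(cnt)] <<- as.integer(cnt)
    }
    n_distinct <- length(distinct)
    n_rows <- nrow(h)
    has_mcp <- markers$mcp_id %in% distinct
    n_for_rule <- if (count_mode == "distinct") n_distinct else n_rows
    data.frame(
      bin_id = b,
      n_distinct_markers = n_distinct,
      n_hit_rows = n_rows,
      has_mcp = has_mcp,
      distinct_core5 = length(intersect(distinct, markers$core5_ids)),
      completeness = n_distinct / n20,
      is_candidate = (n_for_rule > 5L) || has_mcp,
      phylogeny_eligible =
        length(intersect(distinct, markers$core5_ids)) >= 3L,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(bin_id = character(), n_distinct_markers = integer(),
               n_hit_rows = integer(), has_mcp = logical(),
               distinct_core5 = integer(), completeness = numeric(),
               is_candidate = logical(), phylogeny_eligible = logical(),
               stringsAsFactors = FALSE)
  attr(out, "copy_numbers") <- copy_mat
  out
}

#' Partition bin profiles by eligibility for phylogenomic placement
#'
#' Bins carrying fewer than three of the five core NCLDV markers are
#' excluded from tree construction; the rest are eligible.
#'
#' @param profiles data frame from [profile_bins()].
#' @return list with character vectors \code{eligible} and \code{excluded};
#'   the two partition the input bin ids.
#' @export
phylogeny_gate <- function(profiles) {
  list(eligible = profiles$bin_id[profiles$phylogeny_eligible],
       excluded = profiles$bin_id[!profiles$phylogeny_eligible])
}

#' Score screening results against a synthetic truth
#'
#' Compares candidate calls with the generator's ground truth. The positive
#' reference set is the NCLDV genomes whose \emph{true} marker complement
#' passes the candidate rule ("detectable" positives); NCLDV genomes whose
#' complement is below the rule cannot be found by any screen of this form
#' and are reported separately in \code{undetectable}.
#'
#' @param profiles data frame from [profile_bins()].
#' @param truth a \code{gv_truth} from [generate_community()].
#' @return list with counts \code{tp}, \code{fp}, \code{fn},
#'   \code{undetectable} and rates \code{precision}, \code{recall}
#'   (\code{NA} when the denominator is zero).
#' @export
score_recovery <- function(profiles, truth) {
  stopifnot(inherits(truth, "gv_truth"))
  unknown <- setdiff(profiles$bin_id, truth$genomes$genome_id)
  if (length(unknown))
    stopf("bin id(s) not present in truth: %s",
          paste(unknown, collapse = ", "))
  called <- profiles$bin_id[profiles$is_candidate]
  pos <- truth_detectable(truth)
  ncldv <- truth$genomes$genome_id[truth$genomes$class == "ncldv"]
  tp <- length(intersect(called, pos))
  fp <- length(setdiff(called, ncldv))
  fn <- length(setdiff(pos, called))
  list(tp = tp, fp = fp, fn = fn,
       undetectable = setdiff(ncldv, pos),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# NCLDV genomes whose true complement satisfies the candidate rule
truth_detectable <- function(truth) {
  md <- truth$markers
  comp <- truth$marker_complement
  ncldv <- truth$genomes$genome_id[truth$genomes$class == "ncldv"]
  keep <- vapply(ncldv, function(g) {
    m <- comp$marker_id[comp$genome_id == g]
    length(unique(m)) > 5L || md$mcp_id %in% m
  }, logical(1))
  ncldv[keep]
}
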