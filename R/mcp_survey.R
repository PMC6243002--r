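# The MCP survey filter cascade. Each stage only annotates: records failing
# a stage get dropped_at set to the stage name and are never removed from
# the catalog, so survivor sets are nested and the cascade is idempotent.

new_candidates <- function(cand) {
  need <- c("protein_id", "contig_id", "source", "evalue")
  miss <- setdiff(need, names(cand))
  if (length(miss))
    stopf("candidate table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(cand$protein_id)) stopf("duplicate protein_id in catalog")
  if (any(cand$evalue <= 0)) stopf("e-values must be > 0")
  n <- nrow(cand)
  if (!"dropped_at" %in% names(cand)) cand$dropped_at <- rep("none", n)
  if (!"cluster_rep" %in% names(cand)) cand$cluster_rep <- rep(NA, n)
  if (!"top10_rescued" %in% names(cand)) cand$top10_rescued <- rep(NA, n)
  if (!"aligned_aa_after_trim" %in% names(cand))
    cand$aligned_aa_after_trim <- rep(NA_integer_, n)
  cand
}

surviving <- function(cand) cand$dropped_at == "none"

#' MCP cascade stage 1: e-value filter
#'
#' Keeps candidates with search e-value at or below the cutoff (default
#' 1e-6, a cutoff validated against ~60,000 non-NCLDV genomes in the
#' original survey). Dropped records stay in the catalog with
#' \code{dropped_at = "evalue"}.
#'
#' @param candidates MCP candidate data frame (columns \code{protein_id},
#'   \code{contig_id}, \code{source}, \code{evalue}, ...).
#' @param cutoff e-value cutoff.
#' @return the annotated candidate data frame.
#' @export
filter_evalue <- function(candidates, cutoff = 1e-6) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  cand <- new_candidates(candidates)
  fail <- surviving(cand) & cand$evalue > cutoff
  cand$dropped_at[fail] <- "evalue"
  cand
}

#' MCP cascade stage 2: redundancy clustering at 95% identity
#'
#' Greedy longest-first clustering (the semantics of cd-hit without its
#' word-filter heuristics): sequences are visited by decreasing length;
#' each joins the first existing representative it matches at or above
#' \code{identity_min}, otherwise it founds a new cluster. Representatives
#' survive; other members get \code{dropped_at = "cluster"}.
#'
#' @param candidates annotated candidate data frame.
#' @param pairwise_identity either a symmetric matrix of identities in
#'   [0, 1] with protein ids as dimnames, or a function
#'   \code{f(id_a, id_b)} returning the identity.
#' @param lengths named numeric vector of protein lengths; defaults to the
#'   \code{protein_len} column.
#' @param identity_min clustering identity threshold.
#' @return the annotated candidate data frame with \code{cluster_rep} and a
#'   \code{cluster_of} column naming each survivor's representative.
#' @export
cluster_95 <- function(candidates, pairwise_identity, lengths = NULL,
                       identity_min = 0.95) {
  cand <- new_candidates(candidates)
  ident <- if (is.function(pairwise_identity)) pairwise_identity
           else function(a, b) pairwise_identity[a, b]
  alive <- cand$protein_id[surviving(cand)]
  if (is.null(lengths)) {
    if (!"protein_len" %in% names(cand))
      stopf("need protein lengths (protein_len column or lengths=)")
    lengths <- setNames(cand$protein_len, cand$protein_id)
  }
  alive <- alive[order(-lengths[alive], alive)]
  reps <- character(0)
  assign_to <- setNames(character(length(alive)), alive)
  for (p in alive) {
    hit <- NA_character_
    for (r in reps) {
      if (ident(p, r) >= identity_min) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, p); assign_to[p] <- p }
    else assign_to[p] <- hit
  }
  cand$cluster_of <- NA_character_
  idx <- match(names(assign_to), cand$protein_id)
  cand$cluster_of[idx] <- assign_to
  cand$cluster_rep <- !is.na(cand$cluster_of) &
    cand$cluster_of == cand$protein_id
  member <- surviving(cand) & !cand$cluster_rep
  cand$dropped_at[member] <- "cluster"
  cand
}

#' MCP cascade stage 3: top-10 database-hit rescue
#'
#' Candidates whose database search returned hits but no NCLDV MCP within
#' the top 10 are discarded as likely false positives. Candidates with no
#' hits at all are kept (only "proteins which had hits" can be excluded),
#' as are candidates with an NCLDV MCP anywhere in the top 10.
#'
#' @param candidates annotated candidate data frame.
#' @param nr_hits data frame of ranked database hits: \code{protein_id},
#'   \code{label}, \code{bitscore}, \code{evalue}, \code{is_ncldv_mcp}
#'   (logical).
#' @param rank_by \code{"bitscore"} (descending, default) or
#'   \code{"evalue"} (ascending); ties broken by the other key, then by
#'   label.
#' @param top_n rescue window size.
#' @return the annotated candidate data frame with \code{top10_rescued}.
#' @export
top10_rescue <- function(candidates, nr_hits,
                         rank_by = c("bitscore", "evalue"), top_n = 10L) {
  rank_by <- match.arg(rank_by)
  cand <- new_candidates(candidates)
  need <- c("protein_id", "label", "bitscore", "evalue", "is_ncldv_mcp")
  miss <- setdiff(need, names(nr_hits))
  if (length(miss))
    stopf("nr_hits lacks column(s): %s", paste(miss, collapse = ", "))
  by_prot <- split(nr_hits, nr_hits$protein_id)
  keep_one <- function(p) {
    h <- by_prot[[p]]
    if (is.null(h) || nrow(h) == 0) return(TRUE)  # no hits: kept
    ord <- if (rank_by == "bitscore")
      order(-h$bitscore, h$evalue, h$label) else
      order(h$evalue, -h$bitscore, h$label)
    any(h$is_ncldv_mcp[ord][seq_len(min(top_n, nrow(h)))])
  }
  alive <- which(surviving(cand))
  rescued <- vapply(cand$protein_id[alive], keep_one, logical(1))
  cand$top10_rescued[alive] <- rescued
  cand$dropped_at[alive[!rescued]] <- "top10"
  cand
}

#' MCP cascade stage 4: aligned-length filter
#'
#' After alignment and column trimming, proteins with fewer than
#' \code{min_aa} aligned (non-gap) amino acids are removed; exactly
#' \code{min_aa} residues is kept.
#'
#' @param candidates annotated candidate data frame.
#' @param trimmed_alignment a \code{gv_msa} of the trimmed alignment; every
#'   surviving candidate must have a row.
#' @param min_aa minimum aligned residues.
#' @return the annotated candidate data frame with
#'   \code{aligned_aa_after_trim} filled for survivors of stage 3.
#' @export
filter_aligned_length <- function(candidates, trimmed_alignment,
                                  min_aa = 50L) {
  cand <- new_candidates(candidates)
  stopifnot(inherits(trimmed_alignment, "gv_msa"))
  alive <- which(surviving(cand))
  miss <- setdiff(cand$protein_id[alive], names(trimmed_alignment))
  if (length(miss))
    stopf("candidate(s) missing from trimmed alignment: %s",
          paste(miss, collapse = ", "))
  n_res <- vapply(cand$protein_id[alive], function(p)
    nchar(gsub("[-.]", "", trimmed_alignment[[p]])), numeric(1))
  cand$aligned_aa_after_trim[alive] <- as.integer(n_res)
  cand$dropped_at[alive[n_res < min_aa]] <- "aligned_len"
  cand
}

#' Run the whole MCP filter cascade
#'
#' Applies the four stages in their published order — e-value cutoff,
#' 95% identity clustering, top-10 database rescue, aligned-length floor —
#' and records per-stage provenance in \code{dropped_at}.
#'
#' @param candidates raw candidate data frame.
#' @param pairwise_identity see [cluster_95()]; \code{NULL} skips the
#'   clustering stage (every survivor its own representative).
#' @param nr_hits see [top10_rescue()].
#' @param trimmed_alignment see [filter_aligned_length()]; \code{NULL}
#'   skips the stage.
#' @param config a \code{gv_config} supplying the thresholds.
#' @return the fully annotated candidate data frame.
#' @export
run_mcp_cascade <- function(candidates, pairwise_identity = NULL,
                            nr_hits = NULL, trimmed_alignment = NULL,
                            config = gv_config()) {
  cand <- filter_evalue(candidates, cutoff = config$mcp_evalue_cutoff)
  if (!is.null(pairwise_identity))
    cand <- cluster_95(cand, pairwise_identity,
                       identity_min = config$mcp_cluster_identity)
  if (!is.null(nr_hits))
    cand <- top10_rescue(cand, nr_hits)
  if (!is.null(trimmed_alignment))
    cand <- filter_aligned_length(cand, trimmed_alignment,
                                  min_aa = config$mcp_min_aligned_aa)
  cand
}

#' Fraction accounting for the MCP survey
#'
#' Summarizes cascade survivors the way the survey reports them: counts by
#' source (reference genomes, MAGs, unbinned bulk fraction), bulk contigs
#' split at 1 kb (strictly greater than 1,000 bp counts as ">1 kb"; the
#' equal case falls in the short class and is flagged), the share of
#' survivors in the unbinned fraction, and how many sit on contigs with
#' read coverage below 2 — the signature of extremely low-abundance
#' viruses. Length/coverage pairs are returned for plotting.
#'
#' @param candidates annotated candidate data frame after the cascade.
#' @param depth contig depth table (see [read_depth_table()]); every
#'   survivor's contig must be present.
#' @return list with \code{counts_by_source}, \code{bulk_length_classes},
#'   \code{unbinned_percent} (one decimal), \code{low_cov_count} (bulk
#'   survivors with coverage < 2), \code{boundary_1kb_count}, and
#'   \code{scatter} (data frame \code{protein_id}, \code{source},
#'   \code{length_bp}, \code{mean_depth}).
#' @export
fraction_report <- function(candidates, depth) {
  cand <- new_candidates(candidates)
  surv <- cand[surviving(cand), , drop = FALSE]
  if (nrow(surv) == 0)
    return(list(counts_by_source = c(reference = 0L, mag = 0L,
                                     bulk_unbinned = 0L),
                bulk_length_classes = c(over_1kb = 0L, under_1kb = 0L),
                unbinned_percent = 0, low_cov_count = 0L,
                boundary_1kb_count = 0L,
                scatter = data.frame()))
  miss <- setdiff(surv$contig_id, depth$contig_id)
  if (length(miss))
    stopf("contig(s) missing from depth table: %s",
          paste(miss, collapse = ", "))
  idx <- match(surv$contig_id, depth$contig_id)
  surv$length_bp <- depth$length_bp[idx]
  surv$mean_depth <- depth$mean_depth[idx]
  counts <- table(factor(surv$source,
                         levels = c("reference", "mag", "bulk_unbinned")))
  bulk <- surv[surv$source == "bulk_unbinned", , drop = FALSE]
  over <- sum(bulk$length_bp > 1000)
  under <- sum(bulk$length_bp <= 1000)
  meta <- surv$source %in% c("mag", "bulk_unbinned")  # metagenome-derived
  n_meta <- sum(meta)
  unb_pct <- if (n_meta > 0)
    round(100 * sum(surv$source[meta] == "bulk_unbinned") / n_meta, 1) else 0
  list(counts_by_source = setNames(as.integer(counts), names(counts)),
       bulk_length_classes = c(over_1kb = over, under_1kb = under),
       unbinned_percent = unb_pct,
       low_cov_count = sum(bulk$mean_depth < 2),
       boundary_1kb_count = sum(bulk$length_bp == 1000),
       scatter = surv[, c("protein_id", "source", "length_bp",
                          "mean_depth")])
}
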