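#' Generate a synthetic soil community with planted giant viruses
#'
#' Builds the ground truth every downstream stage is tested against: a
#' community of abundant cellular genomes plus rare NCLDV genomes. The
#' abundance regime emulates the study system — rare viruses sit below 1x
#' expected bulk coverage while one designated "abundant" virus reaches
#' about 9x, the contrast that makes bulk metagenomics blind to most soil
#' giant viruses. Viral marker complements are drawn from the 20-marker
#' ancestral NCVOG set as a mixture of complete (20/20), partial, and
#' sub-threshold genomes (fewer than three core markers, at most five
#' distinct markers, no MCP). Orthogroup sharing probability decays with
#' lineage distance so that gene-sharing networks built on the table show
#' stronger within-lineage than cross-lineage connectivity. A random
#' phylogeny with branch lengths is attached for the PD statistics.
#'
#' @param n_cellular number of cellular (bacterial/archaeal) genomes.
#' @param n_ncldv number of NCLDV genomes.
#' @param viral_abundance_ceiling upper bound for the relative abundance of
#'   any rare NCLDV genome.
#' @param lineage_count number of NCLDV lineages.
#' @param seed integer RNG seed; the whole truth object is reproducible.
#' @param complement_mix mixture weights for complete / partial /
#'   sub-threshold marker complements.
#' @param copy_mean mean marker copy number (truncated geometric, mimicking
#'   paralog expansions).
#' @param bulk_yield_bp total bulk sequencing yield used to convert
#'   abundances to expected bulk coverage.
#' @param abundant_cov target expected bulk coverage of the one abundant
#'   virus.
#' @param markers a \code{gv_markers} definition.
#'
#' @return A \code{gv_truth} list: \code{genomes} (data frame with
#'   \code{genome_id}, \code{class}, \code{lineage}, \code{length_bp},
#'   \code{abundance}, \code{complement_class}, \code{expected_bulk_cov}),
#'   \code{marker_complement} (long data frame \code{genome_id},
#'   \code{marker_id}, \code{copies}), \code{tree} (phylo over NCLDV),
#'   \code{orthogroups} (\code{gv_orthogroups} over NCLDV), \code{markers},
#'   \code{seed}.
#' @examples
#' truth <- generate_community(n_cellular = 20, n_ncldv = 6, seed = 7)
#' sum(truth$genomes$abundance)
#' @export
generate_community <- function(n_cellular = 60L, n_ncldv = 12L,
                               viral_abundance_ceiling = 5e-5,
                               lineage_count = 4L, seed = 1L,
                               complement_mix = c(complete = 0.3,
                                                  partial = 0.5,
                                                  subthreshold = 0.2),
                               copy_mean = 1.3,
                               bulk_yield_bp = 5e10,
                               abundant_cov = 9,
                               markers = marker_definition()) {
  if (n_cellular < 1 || n_ncldv < 1) stopf("genome counts must be >= 1")
  if (viral_abundance_ceiling <= 0 || viral_abundance_ceiling >= 1)
    stopf("viral_abundance_ceiling must lie in (0,1)")
  complement_mix <- complement_mix / sum(complement_mix)

  cell_ids <- sprintf("cell_%03d", seq_len(n_cellular))
  gv_ids <- sprintf("gv_%03d", seq_len(n_ncldv))
  lineages <- sprintf("lineage_%d", 1 + (seq_len(n_ncldv) - 1L) %% lineage_count)

  abund <- with_seed(sub_seed(seed, "abundance"), {
    cell_len <- round(runif(n_cellular, 2e6, 8e6))
    gv_len <- round(runif(n_ncldv, 1e5, 2.5e6))
    # rare viruses: draw target bulk coverage < 1x, convert to abundance
    rare_cov <- runif(n_ncldv, 0.05, 0.9)
    gv_ab <- pmin(rare_cov * gv_len / bulk_yield_bp,
                  viral_abundance_ceiling * 0.99)
    abundant_idx <- sample.int(n_ncldv, 1L)
    gv_ab[abundant_idx] <- abundant_cov * gv_len[abundant_idx] / bulk_yield_bp
    cell_raw <- rlnorm(n_cellular, 0, 1)
    cell_ab <- cell_raw / sum(cell_raw) * (1 - sum(gv_ab))
    list(cell_len = cell_len, gv_len = gv_len, cell_ab = cell_ab,
         gv_ab = gv_ab, abundant_idx = abundant_idx)
  })
  if (viral_abundance_ceiling >= max(abund$cell_ab))
    warnf("viral abundance ceiling exceeds the largest cellular abundance; %s",
          "this is not a rare-virus regime")

  comp <- with_seed(sub_seed(seed, "complement"), {
    cls <- sample(names(complement_mix), n_ncldv, replace = TRUE,
                  prob = complement_mix)
    # the bulk-abundant virus mirrors the one bulk-recovered MAG: a
    # near-complete genome, discoverable by the marker screen
    cls[abund$abundant_idx] <- "complete"
    rows <- lapply(seq_len(n_ncldv), function(i) {
      ids <- draw_complement(cls[i], markers)
      data.frame(genome_id = gv_ids[i], marker_id = ids,
                 copies = draw_copies(length(ids), copy_mean),
                 stringsAsFactors = FALSE)
    })
    list(cls = cls, table = do.call(rbind, rows))
  })

  tree <- with_seed(sub_seed(seed, "tree"), {
    tr <- ape::rtree(n_ncldv, tip.label = gv_ids)
    tr$edge.length <- round(rexp(nrow(tr$edge), rate = 4) + 0.01, 6)
    tr
  })

  og <- with_seed(sub_seed(seed, "orthogroups"),
                  draw_orthogroups(gv_ids, lineages))

  genomes <- data.frame(
    genome_id = c(cell_ids, gv_ids),
    class = rep(c("cellular", "ncldv"), c(n_cellular, n_ncldv)),
    lineage = c(rep("cellular", n_cellular), lineages),
    length_bp = c(abund$cell_len, abund$gv_len),
    abundance = c(abund$cell_ab, abund$gv_ab),
    complement_class = c(rep(NA_character_, n_cellular), comp$cls),
    stringsAsFactors = FALSE)
  genomes$expected_bulk_cov <-
    genomes$abundance * bulk_yield_bp / genomes$length_bp

  structure(list(genomes = genomes, marker_complement = comp$table,
                 tree = tree, orthogroups = og, markers = markers,
                 abundant_virus = gv_ids[abund$abundant_idx],
                 bulk_yield_bp = bulk_yield_bp, seed = as.integer(seed)),
            class = "gv_truth")
}

#' @export
print.gv_truth <- function(x, ...) {
  g <- x$genomes
  cat(sprintf(
    "gv_truth: %d cellular + %d NCLDV genomes (seed %d)\n",
    sum(g$class == "cellular"), sum(g$class == "ncldv"), x$seed))
  cat(sprintf("  abundant virus: %s (expected bulk coverage %.1fx)\n",
              x$abundant_virus,
              g$expected_bulk_cov[g$genome_id == x$abundant_virus]))
  invisible(x)
}

# marker complement for one genome by complement class
draw_complement <- function(class, markers) {
  all20 <- markers$marker_ids
  core <- markers$core5_ids
  switch(class,
    complete = all20,
    partial = {
      k <- sample(8:19, 1L)
      sample(all20, k)
    },
    subthreshold = {
      # < 3 core markers, <= 5 distinct, never the MCP: invisible to the rule
      pool <- setdiff(all20, markers$mcp_id)
      repeat {
        ids <- sample(pool, sample(1:5, 1L))
        if (length(intersect(ids, core)) < 3L) return(ids)
      }
    },
    stopf("unknown complement class '%s'", class))
}

# 1 + geometric, truncated at 6 copies; mean ~ copy_mean for small excess
draw_copies <- function(n, copy_mean) {
  p <- 1 / copy_mean
  pmin(1L + stats::rgeom(n, p), 6L)
}

# lineage-structured orthogroup table: sharing decays with lineage distance
draw_orthogroups <- function(gv_ids, lineages, n_core = 10L,
                             n_accessory = 140L, p_within = 0.8,
                             decay = 0.35) {
  lin_idx <- as.integer(factor(lineages, levels = unique(lineages)))
  rows <- list()
  add <- function(og, members) {
    if (length(members) == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      og_id = og, genome_id = members,
      n_proteins = draw_copies(length(members), 1.3),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_core))
    add(sprintf("OG%07d", i), gv_ids)
  for (i in seq_len(n_accessory)) {
    home <- sample(unique(lin_idx), 1L)
    p <- p_within * decay ^ abs(lin_idx - home)
    members <- gv_ids[runif(length(gv_ids)) < p]
    add(sprintf("OG%07d", n_core + i), members)
  }
  counts <- do.call(rbind, rows)
  # singletons so totals exceed in-group sums, as with real gene calls
  sums <- tapply(counts$n_proteins, counts$genome_id, sum)
  totals <- setNames(rep(0, length(gv_ids)), gv_ids)
  totals[names(sums)] <- as.numeric(sums)
  totals <- totals + stats::rpois(length(gv_ids), 40) + 1
  orthogroup_table(counts, totals)
}

#' Emit a synthetic marker hit table from a community truth
#'
#' Simulates the hit table an HMM search over the binned assembly would
#' yield: every marker copy of every NCLDV genome produces one hit with an
#' e-value log-uniform below the screening cutoff; false negatives drop
#' hits at the given rate; false positives inject spurious marker hits into
#' cellular bins. Bin ids equal genome ids (one bin per genome).
#'
#' @param truth a \code{gv_truth}.
#' @param false_pos_rate per cellular-genome-per-marker probability of an
#'   injected spurious hit.
#' @param false_neg_rate per true-hit probability of being dropped.
#' @param seed RNG seed.
#' @param evalue_range log10 e-value range for emitted hits (below the
#'   default screening cutoff of 1e-6).
#' @return hit table data frame as from [read_hit_table()].
#' @export
emit_hit_table <- function(truth, false_pos_rate = 0, false_neg_rate = 0,
                           seed = truth$seed,
                           evalue_range = c(-30, -8)) {
  stopifnot(inherits(truth, "gv_truth"))
  if (false_pos_rate < 0 || false_pos_rate >= 1 ||
      false_neg_rate < 0 || false_neg_rate > 1)
    stopf("noise rates must lie in [0,1)")
  with_seed(sub_seed(seed, "hit_table"), {
    comp <- truth$marker_complement
    true_rows <- comp[rep(seq_len(nrow(comp)), comp$copies), , drop = FALSE]
    keep <- runif(nrow(true_rows)) >= false_neg_rate
    true_rows <- true_rows[keep, , drop = FALSE]
    cell <- truth$genomes$genome_id[truth$genomes$class == "cellular"]
    fp <- expand.grid(genome_id = cell,
                      marker_id = truth$markers$marker_ids,
                      stringsAsFactors = FALSE)
    fp <- fp[runif(nrow(fp)) < false_pos_rate, , drop = FALSE]
    all_rows <- rbind(true_rows[, c("genome_id", "marker_id")],
                      fp[, c("genome_id", "marker_id")])
    n <- nrow(all_rows)
    if (n == 0)
      return(data.frame(query_id = character(), bin_id = character(),
                        marker_id = character(), evalue = numeric(),
                        bitscore = numeric(), aligned_len = integer(),
                        stringsAsFactors = FALSE))
    data.frame(
      query_id = sprintf("%s_c1_%d", all_rows$genome_id, seq_len(n)),
      bin_id = all_rows$genome_id,
      marker_id = all_rows$marker_id,
      evalue = 10 ^ runif(n, evalue_range[1], evalue_range[2]),
      bitscore = round(runif(n, 60, 500), 1),
      aligned_len = as.integer(round(runif(n, 100, 400))),
      stringsAsFactors = FALSE)
  })
}

#' Emit trees with and without a set of novel leaves
#'
#' Returns the truth tree and the tree obtained by pruning the novel leaves
#' (unifurcations collapsed, branch lengths summed through collapsed
#' nodes), together with the true phylogenetic diversity of both — the
#' oracle for [pd_increase()].
#'
#' @param truth a \code{gv_truth}.
#' @param novel_ids leaves to prune; must be a subset of the NCLDV genome
#'   ids and must leave at least two leaves standing.
#' @return list with \code{tree_with}, \code{tree_without}, \code{pd_with},
#'   \code{pd_without}.
#' @export
emit_tree <- function(truth, novel_ids) {
  stopifnot(inherits(truth, "gv_truth"))
  tree <- truth$tree
  bad <- setdiff(novel_ids, tree$tip.label)
  if (length(bad))
    stopf("novel id(s) not in tree: %s", paste(bad, collapse = ", "))
  if (length(novel_ids) >= length(tree$tip.label))
    stopf("pruning would remove all leaves")
  without <- if (length(novel_ids) == 0) tree
             else ape::drop.tip(tree, novel_ids, collapse.singles = TRUE)
  list(tree_with = tree, tree_without = without,
       pd_with = sum(tree$edge.length),
       pd_without = sum(without$edge.length))
}

#' Emit a synthetic pairwise ANI table
#'
#' Adds synthetic reference genomes that form known ANI clusters and pairs
#' every community NCLDV genome with the references and each other at ANI
#' below the dereplication threshold, reproducing the observation that
#' newly discovered viruses cluster with nothing.
#'
#' @param truth a \code{gv_truth}.
#' @param n_ref number of synthetic reference genomes.
#' @param n_ref_clusters number of ANI clusters the references form.
#' @param seed RNG seed.
#' @return list with \code{pairs} (ANI table data frame), \code{lengths}
#'   (named genome lengths) and \code{ref_cluster} (named truth cluster
#'   assignment of the references).
#' @export
emit_ani_table <- function(truth, n_ref = 20L, n_ref_clusters = 8L,
                           seed = truth$seed) {
  stopifnot(inherits(truth, "gv_truth"))
  with_seed(sub_seed(seed, "ani"), {
    ref_ids <- sprintf("ref_%03d", seq_len(n_ref))
    cluster <- sort(rep_len(seq_len(n_ref_clusters), n_ref))
    gv <- truth$genomes[truth$genomes$class == "ncldv", ]
    ids <- c(ref_ids, gv$genome_id)
    lens <- setNames(c(round(runif(n_ref, 2e5, 2e6)), gv$length_bp), ids)
    rows <- list()
    pair <- function(a, b, ani, bp) {
      rows[[length(rows) + 1L]] <<- data.frame(
        genome_a = a, genome_b = b, ani = ani, aligned_bp = bp,
        stringsAsFactors = FALSE)
    }
    n_all <- length(ids)
    for (i in seq_len(n_all - 1L)) for (j in (i + 1L):n_all) {
      a <- ids[i]; b <- ids[j]
      same_cluster <- i <= n_ref && j <= n_ref && cluster[i] == cluster[j]
      if (same_cluster) {
        ani <- runif(1, 96, 99.9)
        bp <- round(runif(1, 1.2e5, min(lens[a], lens[b])))
      } else {
        ani <- runif(1, 75, 88)   # always below the 95% threshold
        bp <- round(runif(1, 2e4, 3e5))
      }
      # asymmetric estimator: both orientations, slightly different values
      pair(a, b, min(100, round(ani + runif(1, 0, 0.4), 2)), bp)
      pair(b, a, max(0, round(ani - runif(1, 0, 0.4), 2)), bp)
    }
    list(pairs = do.call(rbind, rows), lengths = lens,
         ref_cluster = setNames(cluster, ref_ids))
  })
}

#' Emit a synthetic MCP survey catalog
#'
#' Builds the inputs of the MCP filter cascade with known ground truth:
#' true MCP candidates from reference genomes, MAGs and the unbinned bulk
#' fraction (most bulk MCPs on short, low-coverage contigs and a
#' configurable fraction unbinned), plus injected false positives whose nr
#' top-10 hit lists contain no NCLDV MCP — the records the rescue stage
#' must remove.
#'
#' @param truth a \code{gv_truth}.
#' @param n_bulk number of true bulk-metagenome MCPs.
#' @param n_ref number of reference-genome MCPs.
#' @param unbinned_frac fraction of bulk MCPs on unbinned contigs.
#' @param n_false_pos number of injected false positives.
#' @param seed RNG seed.
#' @param n_duplicate_pairs number of near-duplicate (98% identity) bulk
#'   MCP pairs, the records the 95% clustering stage must collapse.
#' @return list with \code{candidates}, \code{nr_hits}, \code{alignment}
#'   (a \code{gv_msa} of trimmed rows), \code{depth} (contig depth table),
#'   \code{identity} (pairwise identity function for [cluster_95()]),
#'   \code{duplicate_of} (named vector over duplicated proteins),
#'   and \code{truth_labels} (named vector: "true_mcp" / "false_positive").
#' @export
emit_mcp_catalog <- function(truth, n_bulk = 60L, n_ref = 25L,
                             unbinned_frac = 0.99, n_false_pos = 6L,
                             n_duplicate_pairs = 4L,
                             seed = truth$seed) {
  stopifnot(inherits(truth, "gv_truth"))
  with_seed(sub_seed(seed, "mcp"), {
    mcp_genomes <- unique(truth$marker_complement$genome_id[
      truth$marker_complement$marker_id == truth$markers$mcp_id])
    mag <- data.frame(protein_id = sprintf("%s_mcp", mcp_genomes),
                      source = "mag",
                      bin_id = mcp_genomes, stringsAsFactors = FALSE)
    ref <- data.frame(protein_id = sprintf("refmcp_%03d", seq_len(n_ref)),
                      source = "reference",
                      bin_id = sprintf("refg_%03d", seq_len(n_ref)),
                      stringsAsFactors = FALSE)
    n_unb <- round(n_bulk * unbinned_frac)
    bulk <- data.frame(
      protein_id = sprintf("bulkmcp_%03d", seq_len(n_bulk)),
      source = "bulk_unbinned",
      bin_id = "unbinned", stringsAsFactors = FALSE)
    if (n_bulk > n_unb) {
      binned_idx <- seq_len(n_bulk - n_unb)
      bulk$source[binned_idx] <- "mag"
      bulk$bin_id[binned_idx] <- sprintf("bulkbin_%02d", binned_idx)
    }
    fp <- data.frame(protein_id = sprintf("fp_%02d", seq_len(n_false_pos)),
                     source = "bulk_unbinned",
                     bin_id = "unbinned", stringsAsFactors = FALSE)
    cand <- rbind(ref, mag, bulk, fp)
    n <- nrow(cand)
    cand$contig_id <- paste0("ctg_", cand$protein_id)
    cand$evalue <- 10 ^ runif(n, -40, -8)        # all pass the 1e-6 cutoff
    # bulk contigs: mostly short and below 2x coverage (the Fig 4b regime)
    is_bulk <- cand$source == "bulk_unbinned" |
      grepl("^bulkmcp", cand$protein_id)
    cand$contig_len_bp <- ifelse(is_bulk,
                                 round(10 ^ runif(n, 2.3, 3.3)),
                                 round(10 ^ runif(n, 3.5, 5)))
    cand$contig_cov <- ifelse(is_bulk, runif(n, 0.2, 1.9), runif(n, 2, 40))
    cand$protein_len <- as.integer(round(runif(n, 180, 600)))
    truth_labels <- setNames(
      ifelse(grepl("^fp_", cand$protein_id), "false_positive", "true_mcp"),
      cand$protein_id)
    # nr top-10 hit lists: true MCPs get an NCLDV MCP inside the top 10,
    # false positives get 10 cellular hits and no MCP
    nr <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- 10L
      lab <- rep("cellular_protein", k)
      is_mcp <- rep(FALSE, k)
      if (truth_labels[i] == "true_mcp") {
        pos <- sample.int(k, 1L)
        lab[pos] <- "NCLDV_major_capsid_protein"
        is_mcp[pos] <- TRUE
      }
      data.frame(protein_id = cand$protein_id[i], label = lab,
                 bitscore = sort(runif(k, 50, 400), decreasing = TRUE),
                 evalue = sort(10 ^ runif(k, -60, -5)),
                 is_ncldv_mcp = is_mcp, stringsAsFactors = FALSE)
    }))
    # trimmed alignment rows: true MCPs align well; the aligned length
    # filter is exercised downstream by construction, not here
    width <- 220L
    aln_rows <- vapply(seq_len(n), function(i) {
      n_res <- sample(60:width, 1L)
      paste(c(rep("M", n_res), rep("-", width - n_res)), collapse = "")
    }, character(1))
    aln <- as_msa(setNames(aln_rows, cand$protein_id))
    depth <- data.frame(contig_id = cand$contig_id,
                        length_bp = cand$contig_len_bp,
                        mean_depth = cand$contig_cov,
                        bin_id = cand$bin_id, stringsAsFactors = FALSE)
    # near-duplicate bulk MCPs: the redundancy the 95% clustering removes
    bulk_true <- cand$protein_id[grepl("^bulkmcp", cand$protein_id)]
    n_dup <- min(n_duplicate_pairs, floor(length(bulk_true) / 2))
    duplicate_of <- character(0)
    if (n_dup > 0) {
      picked <- sample(bulk_true, 2L * n_dup)
      duplicate_of <- setNames(picked[seq_len(n_dup) + n_dup],
                               picked[seq_len(n_dup)])
    }
    dup_key <- paste(pmin(names(duplicate_of), duplicate_of),
                     pmax(names(duplicate_of), duplicate_of))
    identity_fn <- function(a, b) {
      if (a == b) return(1)
      if (paste(min(a, b), max(a, b)) %in% dup_key) 0.98 else 0.40
    }
    list(candidates = cand[, c("protein_id", "contig_id", "source",
                               "evalue", "contig_len_bp", "contig_cov",
                               "protein_len")],
         nr_hits = nr, alignment = aln, depth = depth,
         identity = identity_fn, duplicate_of = duplicate_of,
         truth_labels = truth_labels)
  })
}
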