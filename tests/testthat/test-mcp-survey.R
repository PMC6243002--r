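mk_catalog <- function(evalues, prefix = "p") {
  n <- length(evalues)
  data.frame(protein_id = sprintf("%s%02d", prefix, seq_len(n)),
             contig_id = sprintf("ctg%02d", seq_len(n)),
             source = rep("bulk_unbinned", n), evalue = evalues,
             protein_len = as.integer(400 - seq_len(n) + 1L),
             stringsAsFactors = FALSE)
}

test_that("e-value stage keeps 1e-7, drops 1e-5, at the 1e-6 cutoff", {
  cand <- filter_evalue(mk_catalog(c(1e-7, 1e-5, 1e-6)))
  expect_equal(cand$dropped_at, c("none", "evalue", "none"))
  expect_equal(nrow(filter_evalue(mk_catalog(numeric(0)))), 0L)
})

test_that("greedy 95% clustering keeps one representative per cluster", {
  cand <- mk_catalog(rep(1e-10, 2))
  ident_same <- function(a, b) 1
  out <- cluster_95(cand, ident_same)
  expect_equal(sum(out$cluster_rep), 1L)
  expect_equal(out$dropped_at[!out$cluster_rep], "cluster")
  ident_none <- function(a, b) if (a == b) 1 else 0.5
  out2 <- cluster_95(mk_catalog(rep(1e-10, 5)), ident_none)
  expect_true(all(out2$cluster_rep))
})

test_that("greedy clustering matches an explicit longest-first replay", {
  withr::local_seed(14)
  for (rep in 1:6) {
    n <- sample(5:20, 1)
    cand <- mk_catalog(rep(1e-10, n))
    cand$protein_len <- sample.int(500, n)
    m <- matrix(runif(n * n, 0.5, 1), n, n,
                dimnames = list(cand$protein_id, cand$protein_id))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    out <- cluster_95(cand, m)
    # oracle: independent explicit loop over lengths in decreasing order
    ord <- cand$protein_id[order(-cand$protein_len, cand$protein_id)]
    reps <- character(0)
    for (p in ord) {
      match_rep <- NA_character_
      for (r in reps) if (m[p, r] >= 0.95) { match_rep <- r; break }
      if (is.na(match_rep)) reps <- c(reps, p)
    }
    expect_setequal(out$protein_id[out$cluster_rep], reps)
  }
})

test_that("top-10 rescue: hitless kept, no-MCP-in-top-10 dropped, rank 10 kept", {
  cand <- mk_catalog(rep(1e-10, 3), prefix = "q")
  hits <- function(prot, mcp_rank) {
    k <- 10L
    data.frame(protein_id = prot, label = sprintf("hit%02d", 1:k),
               bitscore = seq(300, 300 - k + 1), evalue = 10^-(30:21),
               is_ncldv_mcp = seq_len(k) %in% mcp_rank)
  }
  nr <- rbind(hits("q02", NA), hits("q03", 10L))  # q01 has no hits at all
  out <- top10_rescue(cand, nr)
  expect_equal(out$dropped_at[out$protein_id == "q01"], "none")
  expect_equal(out$dropped_at[out$protein_id == "q02"], "top10")
  expect_equal(out$dropped_at[out$protein_id == "q03"], "none")
  # an MCP at rank 11 does not rescue
  h11 <- data.frame(protein_id = "q03", label = sprintf("h%02d", 1:11),
                    bitscore = seq(300, 290), evalue = 10^-(40:30),
                    is_ncldv_mcp = c(rep(FALSE, 10), TRUE))
  out11 <- top10_rescue(cand[3, ], h11)
  expect_equal(out11$dropped_at, "top10")
})

test_that("aligned-length stage: 49 aa dropped, 50 kept, all-gap dropped", {
  cand <- mk_catalog(rep(1e-10, 3), prefix = "a")
  aln <- as_msa(c(a01 = paste0(strrep("M", 49), strrep("-", 51)),
                  a02 = paste0(strrep("M", 50), strrep("-", 50)),
                  a03 = strrep("-", 100)))
  out <- filter_aligned_length(cand, aln)
  expect_equal(out$dropped_at, c("aligned_len", "none", "aligned_len"))
  expect_equal(out$aligned_aa_after_trim, c(49L, 50L, 0L))
  expect_error(filter_aligned_length(cand, as_msa(c(a01 = "MMM"))),
               "missing")
})

test_that("cascade survivor sets are nested and the cascade is idempotent", {
  truth <- small_truth(seed = 61)
  cat_mcp <- emit_mcp_catalog(truth, seed = 61)
  cfg <- gv_config()
  s1 <- filter_evalue(cat_mcp$candidates, cfg$mcp_evalue_cutoff)
  s2 <- cluster_95(s1, cat_mcp$identity)
  s3 <- top10_rescue(s2, cat_mcp$nr_hits)
  s4 <- filter_aligned_length(s3, cat_mcp$alignment, cfg$mcp_min_aligned_aa)
  alive <- function(x) x$protein_id[x$dropped_at == "none"]
  expect_true(all(alive(s2) %in% alive(s1)))
  expect_true(all(alive(s3) %in% alive(s2)))
  expect_true(all(alive(s4) %in% alive(s3)))
  # records are annotated, never removed
  expect_equal(nrow(s4), nrow(cat_mcp$candidates))
  # idempotence: re-running the cascade on its own output changes nothing
  again <- run_mcp_cascade(s4, cat_mcp$identity, cat_mcp$nr_hits,
                           cat_mcp$alignment, cfg)
  expect_equal(again$dropped_at, s4$dropped_at)
  expect_equal(alive(again), alive(s4))
})

test_that("injected false positives all fall at the top10 stage", {
  truth <- small_truth(seed = 62)
  cat_mcp <- emit_mcp_catalog(truth, n_false_pos = 8L, seed = 62)
  out <- run_mcp_cascade(cat_mcp$candidates, cat_mcp$identity,
                         cat_mcp$nr_hits, cat_mcp$alignment)
  fp <- names(cat_mcp$truth_labels)[cat_mcp$truth_labels == "false_positive"]
  expect_equal(unique(out$dropped_at[out$protein_id %in% fp]), "top10")
  # near-duplicates collapse at the clustering stage
  dup <- names(cat_mcp$duplicate_of)
  dropped_cluster <- out$protein_id[out$dropped_at == "cluster"]
  expect_equal(length(dropped_cluster), length(dup))
})

test_that("fraction report reproduces the unbinned-share arithmetic", {
  n <- 100
  cand <- data.frame(protein_id = sprintf("m%03d", 1:n),
                     contig_id = sprintf("c%03d", 1:n),
                     source = c(rep("bulk_unbinned", 99), "mag"),
                     evalue = 1e-10, dropped_at = "none",
                     stringsAsFactors = FALSE)
  depth <- data.frame(contig_id = cand$contig_id,
                      length_bp = c(rep(800L, 60), rep(1001L, 39), 5000L),
                      mean_depth = c(rep(1.5, 70), rep(3, 30)),
                      bin_id = "unbinned")
  rep <- fraction_report(cand, depth)
  expect_equal(rep$unbinned_percent, 99.0)
  expect_equal(unname(rep$bulk_length_classes["under_1kb"]), 60L)
  expect_equal(unname(rep$bulk_length_classes["over_1kb"]), 39L)
  expect_equal(rep$low_cov_count, 70L)   # bulk contigs with coverage < 2
  empty <- fraction_report(cand[0, ], depth)
  expect_equal(sum(empty$counts_by_source), 0L)
  expect_error(fraction_report(cand, depth[-1, ]), "missing")
})

test_that("synthetic catalog counts agree with the truth manifest", {
  truth <- small_truth(seed = 63)
  cat_mcp <- emit_mcp_catalog(truth, n_bulk = 50, unbinned_frac = 0.98,
                              seed = 63)
  out <- run_mcp_cascade(cat_mcp$candidates, cat_mcp$identity,
                         cat_mcp$nr_hits, cat_mcp$alignment)
  rep <- fraction_report(out, cat_mcp$depth)
  surv <- out[out$dropped_at == "none", ]
  expect_equal(unname(rep$counts_by_source["reference"]),
               sum(surv$source == "reference"))
  expect_equal(unname(rep$counts_by_source["bulk_unbinned"]),
               sum(surv$source == "bulk_unbinned"))
  # every surviving record is a true MCP
  expect_true(all(cat_mcp$truth_labels[surv$protein_id] == "true_mcp"))
})
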