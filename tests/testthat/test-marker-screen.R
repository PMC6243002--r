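md <- marker_definition()

# hit rows for one bin: n distinct markers, optionally including the MCP
bin_hits <- function(bin, n_markers, with_mcp) {
  ids <- if (with_mcp) c(md$mcp_id,
                         setdiff(md$marker_ids, md$mcp_id)[seq_len(max(0, n_markers - 1))])
         else setdiff(md$marker_ids, md$mcp_id)[seq_len(n_markers)]
  if (!length(ids)) return(NULL)
  data.frame(query_id = sprintf("%s_c1_%d", bin, seq_along(ids)),
             bin_id = bin, marker_id = ids, evalue = 1e-10,
             bitscore = 100, aligned_len = 200L)
}

test_that("candidate rule boundaries: 6 markers pass, 5 fail, MCP alone passes", {
  h6 <- bin_hits("b6", 6, FALSE)
  h5 <- bin_hits("b5", 5, FALSE)
  h1 <- bin_hits("bmcp", 1, TRUE)
  prof <- profile_bins(rbind(h6, h5, h1), md)
  expect_true(prof$is_candidate[prof$bin_id == "b6"])
  expect_false(prof$is_candidate[prof$bin_id == "b5"])
  expect_true(prof$is_candidate[prof$bin_id == "bmcp"])
  expect_equal(prof$completeness[prof$bin_id == "bmcp"], 1 / 20)
})

test_that("completeness is the distinct ancestral marker fraction of 20", {
  prof <- profile_bins(bin_hits("b10", 10, FALSE), md)
  expect_equal(prof$completeness, 0.5)
  # duplicate hits on one marker do not raise completeness
  dup <- bin_hits("bd", 3, FALSE)
  dup2 <- dup; dup2$query_id <- paste0(dup2$query_id, "x")
  prof2 <- profile_bins(rbind(dup, dup2), md)
  expect_equal(prof2$completeness, 3 / 20)
  expect_equal(prof2$n_hit_rows, 6L)
})

test_that("exhaustive decision table matches the brute-force rule", {
  for (n in 0:20) for (mcp in c(TRUE, FALSE)) {
    if (mcp && n == 0) next        # MCP present implies >= 1 marker
    if (!mcp && n == 20) next      # all 20 markers necessarily include MCP
    h <- bin_hits("b", n, mcp)
    prof <- profile_bins(h, md, all_bins = "b")
    expected <- (n > 5) || mcp     # the rule, restated
    expect_identical(prof$is_candidate, expected,
                     label = sprintf("n=%d mcp=%s", n, mcp))
    expect_equal(prof$completeness, n / 20)
    expect_identical(prof$has_mcp, mcp && n > 0)
  }
})

test_that("hits above the e-value cutoff and unknown markers are ignored", {
  h <- bin_hits("b", 8, FALSE)
  h$evalue[1:4] <- 1e-3            # above the 1e-6 default cutoff
  prof <- profile_bins(h, md)
  expect_equal(prof$n_distinct_markers, 4L)
  alien <- data.frame(query_id = "b_c1_99", bin_id = "b",
                      marker_id = "PF00001", evalue = 1e-30,
                      bitscore = 500, aligned_len = 300L)
  expect_warning(prof2 <- profile_bins(rbind(h, alien), md), "outside")
  expect_equal(prof2$n_distinct_markers, 4L)
})

test_that("zero-hit bins listed in the bin universe get completeness 0", {
  prof <- profile_bins(bin_hits("b1", 7, FALSE), md,
                       all_bins = c("b1", "b_empty"))
  empty <- prof[prof$bin_id == "b_empty", ]
  expect_equal(empty$completeness, 0)
  expect_false(empty$is_candidate)
})

test_that("count_mode = rows counts total retained hit rows", {
  h <- bin_hits("b", 3, FALSE)
  h2 <- h; h2$query_id <- paste0(h2$query_id, "y")
  both <- rbind(h, h2)             # 6 rows, 3 distinct markers
  expect_false(profile_bins(both, md)$is_candidate)
  expect_true(profile_bins(both, md, count_mode = "rows")$is_candidate)
})

test_that("phylogeny gate: three core markers pass, two are excluded", {
  mk <- function(bin, core_ids) data.frame(
    query_id = sprintf("%s_c1_%d", bin, seq_along(core_ids)),
    bin_id = bin, marker_id = core_ids, evalue = 1e-9, bitscore = 80,
    aligned_len = 150L)
  h <- rbind(mk("b3", md$core5_ids[1:3]), mk("b2", md$core5_ids[1:2]))
  gate <- phylogeny_gate(profile_bins(h, md))
  expect_setequal(gate$eligible, "b3")
  expect_setequal(gate$excluded, "b2")
  empty <- phylogeny_gate(profile_bins(h[0, ], md))
  expect_length(empty$eligible, 0)
  expect_length(empty$excluded, 0)
})

test_that("adding a hit row never revokes candidacy nor lowers completeness", {
  withr::local_seed(8)
  for (rep in 1:25) {
    n <- sample(0:12, 1)
    h <- bin_hits("b", n, sample(c(TRUE, FALSE), 1))
    extra <- data.frame(query_id = sprintf("b_c9_%d", rep), bin_id = "b",
                        marker_id = sample(md$marker_ids, 1),
                        evalue = 10^runif(1, -20, -7), bitscore = 100,
                        aligned_len = 100L)
    before <- profile_bins(h, md, all_bins = "b")
    after <- profile_bins(rbind(h, extra), md, all_bins = "b")
    expect_gte(after$completeness, before$completeness)
    expect_false(before$is_candidate && !after$is_candidate)
  }
})

test_that("recovery scoring is undefined-safe and rejects alien bins", {
  truth <- small_truth(seed = 31)
  prof <- profile_bins(emit_hit_table(truth, 0, 1), truth$markers,
                       all_bins = truth$genomes$genome_id)
  rec <- score_recovery(prof, truth)
  expect_equal(rec$tp, 0)
  expect_true(is.na(rec$precision))
  alien <- profile_bins(bin_hits("not_in_truth", 7, FALSE), md)
  expect_error(score_recovery(alien, truth), "not_in_truth")
})

test_that("recall under noise matches the analytic complement model", {
  # with zero false positives and per-hit drop rate f, a genome whose
  # complement passes the rule is recovered unless enough distinct markers
  # vanish; enumerate the exact recovery probability per genome from its
  # copy numbers and compare pooled recall over replicates
  truth <- generate_community(n_cellular = 5, n_ncldv = 120, seed = 17)
  md_t <- truth$markers
  fnr <- 0.3
  comp <- truth$marker_complement
  detectable <- gvpipe:::truth_detectable(truth)
  p_detect <- vapply(detectable, function(g) {
    rows <- comp[comp$genome_id == g, ]
    # marker survives if any of its copies survives
    p_marker <- 1 - fnr^rows$copies
    has_mcp <- md_t$mcp_id %in% rows$marker_id
    p_mcp <- if (has_mcp) p_marker[match(md_t$mcp_id, rows$marker_id)] else 0
    # P(>5 distinct survive or MCP survives): Monte Carlo over the exact
    # per-marker survival probabilities (independent Bernoulli)
    mean(replicate(400, {
      s <- runif(length(p_marker)) < p_marker
      sum(s) > 5 || (has_mcp && s[match(md_t$mcp_id, rows$marker_id)])
    }))
  }, numeric(1))
  n_rep <- 20
  hitsets <- lapply(seq_len(n_rep), function(r)
    emit_hit_table(truth, 0, fnr, seed = 500 + r))
  recovered <- vapply(hitsets, function(h) {
    prof <- profile_bins(h, md_t, all_bins = truth$genomes$genome_id)
    sum(prof$bin_id[prof$is_candidate] %in% detectable)
  }, numeric(1))
  expected <- sum(p_detect)
  se <- sqrt(sum(p_detect * (1 - p_detect)) / n_rep)
  expect_lt(abs(mean(recovered) - expected), 4 * se + 1)
})
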