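test_that("FASTA read/write round-trips ids and residues", {
  tf <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">a", "ACGT"), tf)
  ss <- read_fasta(tf)
  expect_equal(nrow(ss), 1L)
  expect_equal(nchar(ss$residues), 4L)
  expect_equal(attr(ss, "alphabet"), "nucleotide")

  prot <- data.frame(id = c("p1", "p2", "p3"),
                     description = c("capsid", "", "atpase"),
                     residues = c("MKVLI", "MAGT", strrep("MKWQERT", 30)))
  out <- withr::local_tempfile(fileext = ".faa")
  write_fasta(prot, out)
  back <- read_fasta(out)
  expect_equal(back$id, prot$id)
  expect_equal(back$residues, prot$residues)
  expect_equal(back$description, prot$description)
})

test_that("FASTA reader accepts wrapped and unwrapped dialects equally", {
  seq60 <- strrep("ACGT", 30)
  wrapped <- withr::local_tempfile(); unwrapped <- withr::local_tempfile()
  writeLines(c(">x", substr(seq60, 1, 60), substr(seq60, 61, 120)), wrapped)
  writeLines(c(">x", seq60), unwrapped)
  expect_equal(read_fasta(wrapped)$residues, read_fasta(unwrapped)$residues)
})

test_that("FASTA invariant violations are hard errors naming the culprit", {
  dup <- withr::local_tempfile()
  writeLines(c(">x", "ACGT", ">x", "ACGA"), dup)
  expect_error(read_fasta(dup), "x")
  empty_rec <- withr::local_tempfile()
  writeLines(c(">ok", "ACGT", ">bad", ""), empty_rec)
  expect_error(read_fasta(empty_rec), "bad")
})

test_that("domtblout parsing collapses to the best hit per (query, marker)", {
  row <- function(prot, marker, ieval, score, from, to) {
    paste(prot, "-", "500", marker, "-", "300", "1e-20", "80", "0.1",
          "1", "2", "1e-9", ieval, score, "0.1", "5", "120", from, to,
          "1", "200", "0.9", "desc", sep = " ")
  }
  tf <- withr::local_tempfile()
  writeLines(c("# comment line",
               row("binA_c1_1", "NCVOG0022", "1e-8", "55", "10", "150"),
               row("binA_c1_1", "NCVOG0022", "1e-3", "20", "160", "200"),
               row("binA_c1_2", "NCVOG0038", "1e-12", "90", "1", "230")),
             tf)
  hits <- read_hit_table(tf, dialect = "hmmer_domtbl")
  expect_equal(nrow(hits), 2L)
  best <- hits[hits$query_id == "binA_c1_1", ]
  expect_equal(best$evalue, 1e-8)
  expect_equal(best$aligned_len, 141L)  # 150 - 10 + 1, 1-based inclusive
})

test_that("bin ids come from the contig map; unmapped contigs are unbinned", {
  tf <- withr::local_tempfile()
  writeLines(c("query_id\tmarker_id\tevalue\tbitscore\taligned_len",
               "ctg1_1\tNCVOG0022\t1e-10\t100\t200",
               "ctg2_9\tNCVOG0038\t1e-12\t120\t210",
               "ctg9_1\tNCVOG0023\t1e-9\t90\t150"), tf)
  map <- data.frame(contig_id = c("ctg1", "ctg2"),
                    bin_id = c("bin1", "bin2"))
  hits <- read_hit_table(tf, dialect = "plain_tsv", contig_bin_map = map)
  expect_equal(sort(unique(hits$bin_id)), c("bin1", "bin2", "unbinned"))
})

test_that("plain TSV hit tables round-trip through write_hit_table", {
  md <- marker_definition()
  hits <- data.frame(query_id = sprintf("b%d_c1_%d", c(1, 1, 2, 3, 3), 1:5),
                     bin_id = sprintf("bin%d", c(1, 1, 2, 3, 3)),
                     marker_id = md$marker_ids[1:5],
                     evalue = 10^-(8:12), bitscore = as.numeric(51:55),
                     aligned_len = 101:105)
  tf <- withr::local_tempfile()
  write_hit_table(hits, tf)
  back <- read_hit_table(tf, dialect = "plain_tsv")
  back <- back[order(back$query_id), names(hits)]
  rownames(back) <- NULL
  expect_equal(back, hits)
  expect_equal(length(unique(back$bin_id)), 3L)
})

test_that("empty and malformed hit tables behave as specified", {
  tf <- withr::local_tempfile()
  writeLines(character(0), tf)
  expect_equal(nrow(read_hit_table(tf, dialect = "hmmer_domtbl")), 0L)
  bad <- withr::local_tempfile()
  writeLines(c("query_id\tmarker_id\tevalue\tbitscore\taligned_len",
               "p1\tNCVOG0022\tnot_a_number\t10\t100"), bad)
  expect_error(read_hit_table(bad, dialect = "plain_tsv"), "line")
})

test_that("newick round-trip preserves branch lengths; PD needs lengths", {
  tf <- withr::local_tempfile()
  writeLines("(A:0.1,B:0.2):0;", tf)
  tr <- read_newick(tf)
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(sum(tr$edge.length), 0.3)
  tr2 <- ape::rtree(20)
  tr2$edge.length <- tr2$edge.length * 1.234567891
  out <- withr::local_tempfile()
  write_newick(tr2, out)
  back <- read_newick(out)
  expect_equal(back$edge.length[order(back$edge.length)],
               tr2$edge.length[order(tr2$edge.length)],
               tolerance = 1e-9)
  nolen <- withr::local_tempfile()
  writeLines("(A,B);", nolen)
  expect_error(read_newick(nolen), "branch length")
})

test_that("ANI reader keeps asymmetric pairs and skips self-pairs", {
  tf <- withr::local_tempfile()
  writeLines(c("g1\tg2\t96.5\t200000",
               "g2\tg1\t95.9\t210000",
               "g1\tg1\t100\t500000"), tf)
  expect_warning(tab <- read_ani_table(tf), "self-pair")
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$genome_a != tab$genome_b))
})

test_that("orthogroup reader counts proteins per genome from member lists", {
  tf <- withr::local_tempfile()
  writeLines(c("OG0000001: gA|p1 gA|p2 gB|p1",
               "OG0000002: gB|p2 gC|p1"), tf)
  og <- read_orthogroups(tf)
  cnt <- og$counts
  expect_equal(cnt$n_proteins[cnt$og_id == "OG0000001" &
                                cnt$genome_id == "gA"], 2L)
  expect_equal(sort(names(og$totals)), c("gA", "gB", "gC"))
  expect_equal(unname(og$totals[c("gA", "gB", "gC")]), c(2, 2, 1))
  out <- withr::local_tempfile()
  write_orthogroups(og, out)
  back <- read_orthogroups(out, totals = og$totals)
  expect_equal(back$counts[order(back$counts$og_id, back$counts$genome_id), ],
               cnt[order(cnt$og_id, cnt$genome_id), ],
               ignore_attr = TRUE)
})

test_that("config defaults reproduce the published thresholds", {
  cfg <- gv_config()
  expect_identical(cfg$marker_min_distinct, 5L)
  expect_identical(cfg$mcp_marker_id, "NCVOG0022")
  expect_identical(cfg$ancestral_marker_count, 20L)
  expect_equal(cfg$ani_threshold, 95.0)
  expect_identical(cfg$aligned_fraction_min, 100000L)
  expect_equal(cfg$column_info_min, 0.10)
  expect_equal(cfg$mcp_evalue_cutoff, 1e-6)
  expect_equal(cfg$mcp_cluster_identity, 0.95)
  expect_identical(cfg$mcp_min_aligned_aa, 50L)
  expect_equal(cfg$edge_weight_min, 18.0)
  expect_identical(cfg$pool_size, 100L)
  expect_identical(cfg$contig_min_len, 2000L)
  expect_equal(cfg$contig_min_cov, 2.0)
  expect_identical(cfg$contig_end_trim, 200L)
})

test_that("config files round-trip through the key-value format", {
  cfg <- gv_config(mcp_evalue_cutoff = 1e-5, pool_size = 50L)
  tf <- withr::local_tempfile()
  write_config(cfg, tf)
  expect_equal(read_config(tf), cfg)
})
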