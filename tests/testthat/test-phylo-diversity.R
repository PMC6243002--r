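test_that("column trimming drops columns below 10% information", {
  # 100 rows; first column 9% non-gap (removed), second 10% (kept)
  rows <- vapply(1:100, function(i) {
    paste0(if (i <= 9) "A" else "-", if (i <= 10) "C" else "-", "G")
  }, character(1))
  aln <- as_msa(setNames(rows, sprintf("s%03d", 1:100)))
  out <- trim_columns(aln, 0.10)
  expect_equal(nchar(out[[1]]), 2L)
  expect_equal(attr(out, "kept_columns"), c(2L, 3L))
})

test_that("trimming a gap-free alignment is the identity", {
  aln <- as_msa(c(a = "MKVL", b = "MKIL", c = "MRVL"))
  out <- trim_columns(aln, 0.10)
  expect_equal(unclass(out), unclass(aln), ignore_attr = TRUE)
  # threshold smaller than 1/rows keeps every column with >= 1 residue
  gappy <- as_msa(c(a = "M-V", b = "-AV", c = "M-L"))
  out2 <- trim_columns(gappy, 1e-6)
  expect_equal(nchar(out2[[1]]), 3L)
})

test_that("trimming matches a brute-force per-column scan", {
  withr::local_seed(41)
  for (rep in 1:10) {
    n_row <- sample(5:30, 1); n_col <- sample(10:60, 1)
    mat <- matrix(sample(c("A", "C", "D", "-"), n_row * n_col, TRUE,
                         prob = c(0.2, 0.2, 0.2, 0.4)),
                  n_row, n_col)
    # guarantee one dense column so trimming never empties the alignment
    mat[, 1] <- "A"
    aln <- as_msa(setNames(apply(mat, 1, paste, collapse = ""),
                           sprintf("r%02d", 1:n_row)))
    thr <- runif(1, 0.05, 0.6)
    keep_oracle <- vapply(seq_len(n_col), function(j)
      mean(mat[, j] != "-") >= thr, logical(1))
    out <- trim_columns(aln, thr)
    expect_equal(nchar(out[[1]]), sum(keep_oracle))
    expect_equal(attr(out, "kept_columns"), which(keep_oracle))
  }
})

test_that("the optional low-information rule drops near-random columns", {
  # column 2: modal non-gap residue frequency 2/4 = 0.5
  aln <- as_msa(c(a = "MA", b = "MA", c = "MC", d = "MG"))
  out <- trim_columns(aln, 0.1, low_info_min_freq = 0.6)
  expect_equal(nchar(out[[1]]), 1L)
  expect_error(trim_columns(as_msa(c(a = "-", b = "-")), 0.5), "every")
})

test_that("concatenation fills missing genomes with gaps per partition", {
  p1 <- as_msa(c(g1 = strrep("A", 10), g2 = strrep("C", 10)))
  p2 <- as_msa(c(g2 = strrep("D", 15), g3 = strrep("E", 15)))
  cat2 <- concatenate_alignments(list(m1 = p1, m2 = p2))
  expect_equal(nchar(cat2[[1]]), 25L)
  expect_setequal(names(cat2), c("g1", "g2", "g3"))
  expect_equal(cat2[["g1"]], paste0(strrep("A", 10), strrep("-", 15)))
  expect_equal(cat2[["g3"]], paste0(strrep("-", 10), strrep("E", 15)))
  parts <- attr(cat2, "partitions")
  expect_equal(parts$start, c(1L, 11L))
  expect_equal(parts$end, c(10L, 25L))
})

test_that("concatenating five marker alignments spans the id union", {
  withr::local_seed(6)
  ids <- sprintf("g%02d", 1:12)
  alns <- lapply(1:5, function(k) {
    members <- sample(ids, sample(4:12, 1))
    w <- sample(8:20, 1)
    as_msa(setNames(vapply(members, function(m)
      paste(sample(c("A", "C", "-"), w, TRUE), collapse = ""), ""),
      members))
  })
  names(alns) <- sprintf("NCVOG%04d", 1:5)
  out <- concatenate_alignments(alns)
  expect_setequal(names(out), unique(unlist(lapply(alns, names))))
  expect_equal(nchar(out[[1]]),
               sum(vapply(alns, function(a) nchar(a[[1]]), 1)))
})

test_that("PD is the branch-length sum and survives re-rooting", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2):0;")
  expect_equal(phylogenetic_diversity(tr), 0.3)
  tr2 <- ape::rtree(15)
  pd0 <- phylogenetic_diversity(tr2)
  rerooted <- ape::root(tr2, outgroup = tr2$tip.label[1],
                        resolve.root = TRUE)
  expect_equal(phylogenetic_diversity(rerooted), pd0, tolerance = 1e-12)
  unrooted <- ape::unroot(tr2)
  expect_equal(phylogenetic_diversity(unrooted), pd0, tolerance = 1e-12)
})

test_that("pd_increase formula: 21% larger PD reports a 21% gain", {
  res <- structure(list(), class = "gv_pd")   # formula check via two trees
  t_small <- ape::rtree(10)
  t_small$edge.length <- t_small$edge.length /
    sum(t_small$edge.length)            # pd_without = 1
  t_big <- t_small
  t_big$edge.length <- t_big$edge.length * 1.21
  out <- pd_increase(t_big, novel_ids = NULL, tree_without = t_small)
  expect_equal(out$increase_percent, 21, tolerance = 1e-9)
})

test_that("pruned-tree PD equals the independent spanning-subtree oracle", {
  withr::local_seed(77)
  for (rep in 1:8) {
    tr <- ape::rtree(30)
    novel <- sample(tr$tip.label, 7)
    keep <- setdiff(tr$tip.label, novel)
    res <- pd_increase(tr, novel)
    expect_equal(res$pd_without, oracle_spanning_pd(tr, keep),
                 tolerance = 1e-10)
    expect_gte(res$pd_with, res$pd_without)
    expect_equal(res$increase_percent,
                 100 * (res$pd_with - res$pd_without) / res$pd_without)
  }
})

test_that("pd_increase recovers the generator-recorded PD exactly", {
  truth <- generate_community(n_cellular = 2, n_ncldv = 20, seed = 19)
  novel <- truth$tree$tip.label[1:6]
  emitted <- emit_tree(truth, novel)
  res <- pd_increase(emitted$tree_with, novel)
  expect_identical(res$pd_with, emitted$pd_with)
  expect_identical(res$pd_without, emitted$pd_without)
})

test_that("pd_increase guards its degenerate inputs", {
  tr <- ape::rtree(5)
  expect_warning(res <- pd_increase(tr, character(0)), "no novel")
  expect_equal(res$increase_percent, 0)
  expect_error(pd_increase(tr, tr$tip.label[1:4]), "fewer than two")
  expect_error(pd_increase(tr, "not_a_leaf"), "not in tree")
})

test_that("tree taxonomy transfer assigns pure clades and abstains on mixtures", {
  tr <- ape::read.tree(
    text = "((r1:1,(r2:1,q1:1):1):1,((r3:1,q2:1):1,(r4:1,q3:1):1):1);")
  labels <- c(r1 = "Klosneuvirinae", r2 = "Klosneuvirinae",
              r3 = "Megamimivirinae", r4 = "Tupanvirus")
  out <- assign_taxonomy_by_tree(tr, labels, c("q1", "q2", "q3"))
  expect_equal(out[["q1"]], "Klosneuvirinae")   # sister to one reference
  expect_equal(out[["q2"]], "Megamimivirinae")
  expect_equal(out[["q3"]], "Tupanvirus")
  # a query whose first reference-bearing clade mixes labels stays NA
  tr2 <- ape::read.tree(text = "((r1:1,r2:1):1,q1:1);")
  mixed <- c(r1 = "A", r2 = "B")
  expect_true(is.na(assign_taxonomy_by_tree(tr2, mixed, "q1")[["q1"]]))
  expect_error(assign_taxonomy_by_tree(tr2, mixed, "ghost"), "not in tree")
})

test_that("grafted queries recover their clade labels at high rate", {
  withr::local_seed(91)
  n_clade <- 4; per_clade <- 6
  labs <- sprintf("clade_%d", seq_len(n_clade))
  sub_nwk <- vapply(labs, function(lab) {
    st <- ape::rtree(per_clade)
    st$tip.label <- sprintf("%s_t%d", lab, seq_len(per_clade))
    sub(";$", "", ape::write.tree(st))
  }, character(1))
  tr <- ape::read.tree(
    text = paste0("(", paste(sub_nwk, ":0.5", collapse = ","), ");"))
  tr <- ape::compute.brlen(tr)
  tips <- tr$tip.label
  truth_lab <- sub("_t\\d+$", "", tips)
  # hold out one tip per clade as query, label the rest as references
  queries <- tips[!duplicated(truth_lab)]
  refs <- setdiff(tips, queries)
  labels <- setNames(sub("_t\\d+$", "", refs), refs)
  out <- assign_taxonomy_by_tree(tr, labels, queries)
  correct <- sum(out == sub("_t\\d+$", "", queries), na.rm = TRUE)
  expect_gte(correct / length(queries), 0.75)
})
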