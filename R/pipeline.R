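# End-to-end orchestration: simulate -> screen -> derep -> pd -> network ->
# mcp-survey -> benchmark, with per-stage manifests (input/output digests,
# config snapshot, seed). A stage whose outputs already exist with matching
# input digests is skipped; deleting one stage's outputs re-executes only
# that stage and the ones after it.

stage_order <- c("simulate", "screen", "derep", "pd", "network",
                 "mcp_survey", "benchmark")

# TSV with a provenance header line; readers using read.table skip '#'
write_stage_tsv <- function(df, path, stage, config_digest, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s config=%s seed=%d", stage, config_digest,
                     seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

digest_files <- function(paths, base = NULL) {
  paths <- paths[file.exists(paths)]
  keys <- if (is.null(base)) basename(paths)
          else sub(paste0("^", base, "/?"), "", paths)
  as.list(setNames(unname(md5sum(paths)), keys))
}

#' Serialize / restore a synthetic community truth as plain-text files
#'
#' Writes \code{genomes.tsv}, \code{marker_complement.tsv},
#' \code{tree.nwk}, \code{orthogroups.txt} and \code{truth.json} under
#' \code{dir}; \code{read_truth} reconstructs an equivalent
#' \code{gv_truth}.
#'
#' @param truth a \code{gv_truth}.
#' @param dir directory (created if missing).
#' @return \code{dir} (write) or a \code{gv_truth} (read).
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "gv_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(truth$genomes, file.path(dir, "genomes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$marker_complement,
              file.path(dir, "marker_complement.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(truth$tree, file.path(dir, "tree.nwk"))
  write_orthogroups(truth$orthogroups, file.path(dir, "orthogroups.txt"))
  meta <- list(seed = truth$seed, abundant_virus = truth$abundant_virus,
               bulk_yield_bp = truth$bulk_yield_bp,
               totals = as.list(truth$orthogroups$totals),
               mcp_id = truth$markers$mcp_id,
               core5_ids = truth$markers$core5_ids,
               marker_ids = truth$markers$marker_ids)
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  extra <- setdiff(meta$marker_ids, c(meta$mcp_id, meta$core5_ids))
  markers <- marker_definition(extra_ids = extra, mcp_id = meta$mcp_id,
                               core5_ids = meta$core5_ids)
  og <- read_orthogroups(file.path(dir, "orthogroups.txt"),
                         totals = unlist(meta$totals))
  structure(list(
    genomes = read.table(file.path(dir, "genomes.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE),
    marker_complement = read.table(file.path(dir, "marker_complement.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE),
    tree = read_newick(file.path(dir, "tree.nwk")),
    orthogroups = og, markers = markers,
    abundant_virus = meta$abundant_virus,
    bulk_yield_bp = meta$bulk_yield_bp,
    seed = as.integer(meta$seed)), class = "gv_truth")
}

#' Run the discovery pipeline end-to-end on a synthetic community
#'
#' Orchestrates the full workflow: simulate a community and its sorted
#' pools, screen bins for NCLDV markers at both bulk and pool level,
#' dereplicate genomes by ANI, measure the PD gain of the discovered
#' viruses, build the gene-sharing network, run the MCP survey cascade,
#' and benchmark assembly fidelity on the five-isolate mock design. Each
#' stage writes its outputs plus a JSON manifest (input/output digests,
#' config digest, seed) under \code{outdir/<stage>/}; a stage whose
#' outputs are present with unchanged input digests is skipped on re-run.
#'
#' @param outdir output directory.
#' @param config a \code{gv_config}.
#' @param seed integer seed for every stochastic stage.
#' @param preset simulator preset (see [sim_preset()]).
#' @param force re-run every stage even when outputs are up to date.
#' @param until last stage to run (default: the whole chain). Earlier
#'   stages with up-to-date outputs are skipped, so running a late stage
#'   against an existing output directory executes only what is missing.
#' @return invisibly, a list with the per-stage manifests and key results:
#'   \code{truth}, \code{profiles}, \code{bulk_candidates},
#'   \code{pool_candidates}, \code{clusters}, \code{pd}, \code{network},
#'   \code{mcp}, \code{benchmark}.
#' @export
run_pipeline <- function(outdir, config = gv_config(),
                         seed = config$rng_seed, preset = "barre-woods",
                         force = FALSE, until = "benchmark") {
  until <- match.arg(until, stage_order)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.txt")
  write_config(config, cfg_path)
  ctx <- new.env(parent = emptyenv())
  ctx$outdir <- outdir
  ctx$config <- config
  ctx$seed <- as.integer(seed)
  ctx$preset <- sim_preset(preset)
  ctx$config_digest <- unname(md5sum(cfg_path))
  ctx$force <- force
  ctx$manifests <- list()
  for (stage in stage_order[seq_len(match(until, stage_order))])
    run_stage(ctx, stage)
  invisible(list(manifests = ctx$manifests, truth = ctx$truth,
                 profiles = ctx$profiles,
                 bulk_candidates = ctx$bulk_candidates,
                 pool_candidates = ctx$pool_candidates,
                 clusters = ctx$clusters, pd = ctx$pd,
                 network = ctx$network, mcp = ctx$mcp,
                 benchmark = ctx$benchmark))
}

run_stage <- function(ctx, stage) {
  dir <- file.path(ctx$outdir, stage)
  dir.create(dir, showWarnings = FALSE)
  fn <- get(paste0("stage_", stage), mode = "function")
  manifest_path <- file.path(dir, "manifest.json")
  inputs <- stage_inputs(ctx, stage)
  if (!ctx$force && stage_up_to_date(manifest_path, inputs)) {
    gv_log(stage, "outputs up to date; skipping")
    fn(ctx, dir, execute = FALSE)   # reload results from disk
    old <- jsonlite::read_json(manifest_path)
    old$skipped <- TRUE
    ctx$manifests[[stage]] <- old
    return(invisible())
  }
  gv_log(stage, "running")
  t0 <- Sys.time()
  outputs <- fn(ctx, dir, execute = TRUE)
  manifest <- list(stage = stage,
                   inputs = digest_files(inputs),
                   outputs = digest_files(outputs, base = dir),
                   config_digest = ctx$config_digest,
                   seed = ctx$seed,
                   timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  ctx$manifests[[stage]] <- manifest
  invisible()
}

stage_inputs <- function(ctx, stage) {
  o <- ctx$outdir
  cfg <- file.path(o, "config.txt")
  sim <- file.path(o, "simulate")
  switch(stage,
    simulate = cfg,
    screen = c(cfg, file.path(sim, "hits.tsv"),
               file.path(sim, "pool_depth.tsv"),
               file.path(sim, "truth", "genomes.tsv")),
    derep = c(cfg, file.path(sim, "ani.tsv"),
              file.path(sim, "genome_lengths.tsv")),
    pd = c(cfg, file.path(sim, "truth", "tree.nwk"),
           file.path(o, "screen", "pool_candidates.txt"),
           file.path(o, "screen", "profiles.tsv")),
    network = c(cfg, file.path(sim, "truth", "orthogroups.txt")),
    mcp_survey = c(cfg, file.path(sim, "mcp_candidates.tsv"),
                   file.path(sim, "mcp_nr_hits.tsv"),
                   file.path(sim, "mcp_alignment.faa"),
                   file.path(sim, "mcp_depth.tsv")),
    benchmark = cfg)
}

stage_up_to_date <- function(manifest_path, inputs) {
  if (!file.exists(manifest_path)) return(FALSE)
  man <- tryCatch(jsonlite::read_json(manifest_path),
                  error = function(e) NULL)
  if (is.null(man)) return(FALSE)
  cur <- digest_files(inputs)
  if (!identical(lapply(man$inputs, as.character)[order(names(man$inputs))],
                 lapply(cur, as.character)[order(names(cur))]))
    return(FALSE)
  out <- file.path(dirname(manifest_path), names(man$outputs))
  all(file.exists(out))
}

# ---- stages -----------------------------------------------------------

stage_simulate <- function(ctx, dir, execute) {
  cfg <- ctx$config
  pre <- ctx$preset
  truth_dir <- file.path(dir, "truth")
  if (!execute) {
    ctx$truth <- read_truth(truth_dir)
    ctx$pool_depth <- read.table(file.path(dir, "pool_depth.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    ctx$mcp_catalog <- emit_mcp_catalog(ctx$truth, seed = ctx$seed)
    return(invisible())
  }
  truth <- generate_community(n_cellular = max(pre$n_cellular, 1L),
                              n_ncldv = max(pre$n_ncldv, 1L),
                              seed = ctx$seed)
  write_truth(truth, truth_dir)
  hits <- emit_hit_table(truth, false_pos_rate = 0.002,
                         false_neg_rate = 0.02, seed = ctx$seed)
  write_stage_tsv(hits, file.path(dir, "hits.tsv"), "simulate",
                  ctx$config_digest, ctx$seed)
  # particles are sorted per capsid/cell, so particle abundance is the
  # base abundance divided by genome length, renormalized
  part <- truth$genomes$abundance / truth$genomes$length_bp
  part <- setNames(part / sum(part), truth$genomes$genome_id)
  gv_ids <- truth$genomes$genome_id[truth$genomes$class == "ncldv"]
  n_samples <- 4L
  pools <- draw_pools(part, n_pools = pre$n_pools * n_samples,
                      pool_size = cfg$pool_size,
                      clump_prob = pre$clump_prob,
                      clump_copies = pre$clump_copies,
                      clump_eligible = gv_ids, seed = ctx$seed)
  lens <- setNames(truth$genomes$length_bp, truth$genomes$genome_id)
  depth_rows <- lapply(seq_len(nrow(pools$counts)), function(i) {
    cnt <- pools$counts[i, ]
    present <- cnt > 0
    amp <- amplify(cnt[present], lens, bias_sigma = pre$bias_sigma,
                   seed = sub_seed(ctx$seed, paste0("pool", i)))
    data.frame(pool_id = sprintf("pool_%03d", i),
               genome_id = names(amp$emitted_depth),
               particles = as.integer(cnt[present]),
               depth = round(amp$emitted_depth, 4),
               stringsAsFactors = FALSE)
  })
  pool_depth <- do.call(rbind, depth_rows)
  write_stage_tsv(pool_depth, file.path(dir, "pool_depth.tsv"), "simulate",
                  ctx$config_digest, ctx$seed)
  ani <- emit_ani_table(truth, seed = ctx$seed)
  write_stage_tsv(ani$pairs, file.path(dir, "ani.tsv"), "simulate",
                  ctx$config_digest, ctx$seed)
  write_stage_tsv(data.frame(genome_id = names(ani$lengths),
                             length_bp = as.numeric(ani$lengths)),
                  file.path(dir, "genome_lengths.tsv"), "simulate",
                  ctx$config_digest, ctx$seed)
  mcp <- emit_mcp_catalog(truth, seed = ctx$seed)
  write_stage_tsv(mcp$candidates, file.path(dir, "mcp_candidates.tsv"),
                  "simulate", ctx$config_digest, ctx$seed)
  write_stage_tsv(mcp$nr_hits, file.path(dir, "mcp_nr_hits.tsv"),
                  "simulate", ctx$config_digest, ctx$seed)
  write_alignment(mcp$alignment, file.path(dir, "mcp_alignment.faa"))
  write_stage_tsv(mcp$depth, file.path(dir, "mcp_depth.tsv"), "simulate",
                  ctx$config_digest, ctx$seed)
  ctx$truth <- truth
  ctx$pool_depth <- pool_depth
  ctx$mcp_catalog <- mcp
  c(file.path(truth_dir, c("genomes.tsv", "marker_complement.tsv",
                           "tree.nwk", "orthogroups.txt", "truth.json")),
    file.path(dir, c("hits.tsv", "pool_depth.tsv", "ani.tsv",
                     "genome_lengths.tsv", "mcp_candidates.tsv",
                     "mcp_nr_hits.tsv", "mcp_alignment.faa",
                     "mcp_depth.tsv")))
}

stage_screen <- function(ctx, dir, execute) {
  if (!execute) {
    ctx$profiles <- read.table(file.path(dir, "profiles.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    ctx$bulk_candidates <- readLines(file.path(dir, "bulk_candidates.txt"))
    ctx$pool_candidates <- readLines(file.path(dir, "pool_candidates.txt"))
    return(invisible())
  }
  cfg <- ctx$config
  truth <- ctx$truth
  hits <- read.table(file.path(ctx$outdir, "simulate", "hits.tsv"),
                     header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  markers <- truth$markers
  # bulk screen: only genomes assembling from bulk reads (expected bulk
  # coverage above the contig coverage floor) yield bins at all
  bulk_present <- truth$genomes$genome_id[
    truth$genomes$expected_bulk_cov >= cfg$contig_min_cov]
  # pool screen: genomes reaching the coverage floor in at least one pool
  pd_tab <- ctx$pool_depth
  pool_present <- unique(pd_tab$genome_id[pd_tab$depth >= cfg$contig_min_cov &
                                            pd_tab$particles > 0])
  prof_all <- profile_bins(hits, markers,
                           evalue_cutoff = cfg$mcp_evalue_cutoff,
                           all_bins = truth$genomes$genome_id)
  bulk_prof <- prof_all[prof_all$bin_id %in% bulk_present, ]
  pool_prof <- prof_all[prof_all$bin_id %in% pool_present, ]
  bulk_cand <- bulk_prof$bin_id[bulk_prof$is_candidate]
  pool_cand <- pool_prof$bin_id[pool_prof$is_candidate]
  write_stage_tsv(prof_all, file.path(dir, "profiles.tsv"), "screen",
                  ctx$config_digest, ctx$seed)
  writeLines(bulk_cand, file.path(dir, "bulk_candidates.txt"))
  writeLines(pool_cand, file.path(dir, "pool_candidates.txt"))
  rec <- score_recovery(pool_prof, truth)
  jsonlite::write_json(rec[c("tp", "fp", "fn", "precision", "recall")],
                       file.path(dir, "recovery.json"), auto_unbox = TRUE,
                       digits = NA)
  ctx$profiles <- prof_all
  ctx$bulk_candidates <- bulk_cand
  ctx$pool_candidates <- pool_cand
  file.path(dir, c("profiles.tsv", "bulk_candidates.txt",
                   "pool_candidates.txt", "recovery.json"))
}

stage_derep <- function(ctx, dir, execute) {
  if (!execute) {
    ctx$clusters <- read.table(file.path(dir, "clusters.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    return(invisible())
  }
  cfg <- ctx$config
  sim <- file.path(ctx$outdir, "simulate")
  pairs <- read.table(file.path(sim, "ani.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  lens_tab <- read.table(file.path(sim, "genome_lengths.tsv"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  lens <- setNames(lens_tab$length_bp, lens_tab$genome_id)
  edges <- build_ani_edges(pairs, ani_threshold = cfg$ani_threshold,
                           aligned_min = cfg$aligned_fraction_min)
  clusters <- ani_cluster(names(lens), edges, lengths = lens)
  write_stage_tsv(clusters, file.path(dir, "clusters.tsv"), "derep",
                  ctx$config_digest, ctx$seed)
  ctx$clusters <- clusters
  file.path(dir, "clusters.tsv")
}

stage_pd <- function(ctx, dir, execute) {
  if (!execute) {
    ctx$pd <- read.table(file.path(dir, "pd.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
    return(invisible())
  }
  truth <- ctx$truth
  prof <- ctx$profiles
  eligible <- prof$bin_id[prof$phylogeny_eligible]
  novel <- intersect(ctx$pool_candidates, eligible)
  novel <- intersect(novel, truth$tree$tip.label)
  max_prune <- length(truth$tree$tip.label) - 2L
  if (length(novel) > max_prune) novel <- novel[seq_len(max_prune)]
  res <- if (length(novel) == 0)
    list(pd_with = phylogenetic_diversity(truth$tree),
         pd_without = phylogenetic_diversity(truth$tree),
         increase_percent = 0, mode = "prune")
  else pd_increase(truth$tree, novel)
  tab <- data.frame(pd_with = res$pd_with, pd_without = res$pd_without,
                    increase_percent = res$increase_percent,
                    n_novel = length(novel), mode = res$mode)
  write_stage_tsv(tab, file.path(dir, "pd.tsv"), "pd", ctx$config_digest,
                  ctx$seed)
  ctx$pd <- tab
  file.path(dir, "pd.tsv")
}

stage_network <- function(ctx, dir, execute) {
  if (!execute) {
    ctx$network <- list(edges = read.table(file.path(dir, "edges.tsv"),
                                           header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE))
    return(invisible())
  }
  cfg <- ctx$config
  net <- build_network(ctx$truth$orthogroups,
                       min_weight = cfg$edge_weight_min)
  write_edge_list(net$edges, file.path(dir, "edges.tsv"))
  rep <- connectivity_report(net)
  write_stage_tsv(rep$components, file.path(dir, "components.tsv"),
                  "network", ctx$config_digest, ctx$seed)
  ctx$network <- net
  file.path(dir, c("edges.tsv", "components.tsv"))
}

stage_mcp_survey <- function(ctx, dir, execute) {
  if (!execute) {
    ctx$mcp <- read.table(file.path(dir, "cascade.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
    return(invisible())
  }
  cfg <- ctx$config
  cat_mcp <- ctx$mcp_catalog
  cand <- run_mcp_cascade(cat_mcp$candidates,
                          pairwise_identity = cat_mcp$identity,
                          nr_hits = cat_mcp$nr_hits,
                          trimmed_alignment = cat_mcp$alignment,
                          config = cfg)
  report <- fraction_report(cand, cat_mcp$depth)
  write_stage_tsv(cand, file.path(dir, "cascade.tsv"), "mcp_survey",
                  ctx$config_digest, ctx$seed)
  summary_tab <- data.frame(
    n_reference = report$counts_by_source[["reference"]],
    n_mag = report$counts_by_source[["mag"]],
    n_bulk_unbinned = report$counts_by_source[["bulk_unbinned"]],
    bulk_over_1kb = report$bulk_length_classes[["over_1kb"]],
    bulk_under_1kb = report$bulk_length_classes[["under_1kb"]],
    unbinned_percent = report$unbinned_percent,
    low_cov_count = report$low_cov_count)
  write_stage_tsv(summary_tab, file.path(dir, "summary.tsv"), "mcp_survey",
                  ctx$config_digest, ctx$seed)
  ctx$mcp <- cand
  ctx$mcp_report <- report
  file.path(dir, c("cascade.tsv", "summary.tsv"))
}

stage_benchmark <- function(ctx, dir, execute) {
  if (!execute) {
    ctx$benchmark <- read.table(file.path(dir, "benchmark.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    return(invisible())
  }
  cfg <- ctx$config
  res <- run_mock_benchmark(seed = ctx$seed, config = cfg)
  tab <- data.frame(genome_id = names(res$result$recovered_fraction),
                    recovered_fraction = as.numeric(
                      res$result$recovered_fraction),
                    detected_in_sorts = as.integer(
                      res$detected_sorts[names(res$result$recovered_fraction)]),
                    chimera_rate = res$result$chimera_rate)
  write_stage_tsv(tab, file.path(dir, "benchmark.tsv"), "benchmark",
                  ctx$config_digest, ctx$seed)
  ctx$benchmark <- tab
  file.path(dir, "benchmark.tsv")
}

#' Run the five-isolate mock-community benchmark
#'
#' Emulates the experimental benchmark design: 59 ten-cell sorts from a
#' five-isolate bacterial mock community, MDA amplification, contig
#' emission with quality control, and fidelity scoring. Chimeras are
#' injected at \code{chimera_rate} (default 0, matching the observation
#' that the workflow creates none); they are not emergent because read
#' simulation and assembly are out of scope.
#'
#' @param n_isolates,n_sorts,cells_per_sort the mock design.
#' @param chimera_rate fraction of emitted contigs given a second source.
#' @param bias_sigma MDA bias parameter.
#' @param seed RNG seed.
#' @param config a \code{gv_config} (contig QC thresholds).
#' @return list with \code{result} (a \code{gv_benchmark}),
#'   \code{detected_sorts} (named count of sorts where each genome passed
#'   QC) and \code{contigs} (the surviving contig table).
#' @export
run_mock_benchmark <- function(n_isolates = 5L, n_sorts = 59L,
                               cells_per_sort = 10L, chimera_rate = 0,
                               bias_sigma = 1, seed = 1L,
                               config = gv_config()) {
  with_seed(sub_seed(seed, "mock"), {
    ids <- sprintf("isolate_%d", seq_len(n_isolates))
    lens <- setNames(round(runif(n_isolates, 3e6, 6e6)), ids)
    ab <- setNames(rep(1 / n_isolates, n_isolates), ids)
    pools <- draw_pools(ab, n_pools = n_sorts, pool_size = cells_per_sort,
                        seed = sub_seed(seed, "mockpools"))
    rows <- list()
    for (i in seq_len(n_sorts)) {
      cnt <- pools$counts[i, ]
      present <- cnt > 0
      if (!any(present)) next
      amp <- amplify(cnt[present], lens, bias_sigma = bias_sigma,
                     total_yield = 3e8,
                     seed = sub_seed(seed, paste0("mockamp", i)))
      for (g in names(amp$emitted_depth)) {
        dep <- amp$emitted_depth[[g]]
        n_ctg <- 4L
        ctg_len <- round(runif(n_ctg, 3e3, lens[[g]] / n_ctg))
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = sprintf("s%02d_%s_c%d", i, g, seq_len(n_ctg)),
          source_genome = g, length_bp = ctg_len, mean_depth = dep,
          bin_id = g, pool_id = i, stringsAsFactors = FALSE)
      }
    }
    contigs <- do.call(rbind, rows)
    qc <- contig_qc(contigs, min_len = config$contig_min_len,
                    min_cov = config$contig_min_cov,
                    end_trim = config$contig_end_trim)
    src <- qc[, c("contig_id", "source_genome", "length_bp", "bin_id")]
    if (chimera_rate > 0 && nrow(src)) {
      n_chim <- round(chimera_rate * nrow(src))
      if (n_chim > 0) {
        pick <- sample.int(nrow(src), n_chim)
        extra <- src[pick, , drop = FALSE]
        extra$source_genome <- vapply(extra$source_genome, function(g)
          sample(setdiff(ids, g), 1L), "")
        src <- rbind(src, extra)
      }
    }
    result <- benchmark_mock(src, lens)
    det <- vapply(ids, function(g)
      length(unique(qc$pool_id[qc$source_genome == g])), integer(1))
    list(result = result, detected_sorts = det, contigs = qc)
  })
}
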