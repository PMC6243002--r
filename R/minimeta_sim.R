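#' Simulate FACS-sorted particle pools
#'
#' Draws sorted pools of a fixed particle count (default 100, the sort size
#' of the study) from a community abundance vector. Each pool is a
#' multinomial draw; optionally, with probability \code{clump_prob} per
#' pool, a "vacuole" clumping event delivers several clonal copies of one
#' eligible (viral) genome into the pool — the mechanism proposed to
#' explain how rare giant viruses reach high within-pool coverage. Clonal
#' copies displace randomly chosen non-clump particles so the pool size is
#' preserved.
#'
#' @param abundances named numeric vector of relative abundances (sums
#'   to 1).
#' @param n_pools number of pools to draw.
#' @param pool_size particles per pool.
#' @param clump_prob per-pool probability of a clumping event.
#' @param clump_copies clonal copies delivered by a clump event; must be
#'   below \code{pool_size}.
#' @param clump_eligible genome ids eligible for clumping (default: all).
#' @param seed RNG seed.
#' @return A \code{gv_pools}: list with \code{counts} (n_pools x genomes
#'   integer matrix; rows sum to \code{pool_size}), \code{clump_genome}
#'   (per-pool id of the clumped genome or \code{NA}), \code{pool_size},
#'   \code{abundances}.
#' @examples
#' p <- draw_pools(c(a = 0.99, b = 0.01), n_pools = 5, seed = 1)
#' rowSums(p$counts)
#' @export
draw_pools <- function(abundances, n_pools, pool_size = 100L,
                       clump_prob = 0, clump_copies = 20L,
                       clump_eligible = names(abundances), seed = 1L) {
  if (abs(sum(abundances) - 1) > 1e-8) stopf("abundances must sum to 1")
  if (pool_size < 1) stopf("pool_size must be >= 1")
  if (clump_prob > 0 && clump_copies >= pool_size)
    stopf("clump_copies must be smaller than pool_size")
  ids <- names(abundances)
  if (is.null(ids)) stopf("abundances must be named by genome id")
  with_seed(seed, {
    counts <- t(rmultinom(n_pools, size = pool_size, prob = abundances))
    colnames(counts) <- ids
    clump_genome <- rep(NA_character_, n_pools)
    if (clump_prob > 0 && length(clump_eligible)) {
      w <- abundances[clump_eligible]
      for (i in seq_len(n_pools)) {
        if (runif(1) >= clump_prob) next
        g <- if (length(clump_eligible) == 1L) clump_eligible
             else sample(clump_eligible, 1L, prob = w)
        # displace clump_copies particles drawn uniformly from the pool
        victims <- sample(rep(ids, counts[i, ]), clump_copies)
        for (v in victims) counts[i, v] <- counts[i, v] - 1L
        counts[i, g] <- counts[i, g] + clump_copies
        clump_genome[i] <- g
      }
    }
    structure(list(counts = counts, clump_genome = clump_genome,
                   pool_size = as.integer(pool_size),
                   abundances = abundances),
              class = "gv_pools")
  })
}

#' @export
print.gv_pools <- function(x, ...) {
  cat(sprintf("gv_pools: %d pools x %d genomes, %d particles each (%d clump events)\n",
              nrow(x$counts), ncol(x$counts), x$pool_size,
              sum(!is.na(x$clump_genome))))
  invisible(x)
}

#' Probability that a species is sorted at least twice into one pool
#'
#' Under the binomial marginal of the multinomial pool draw, a species at
#' relative abundance \code{p} appears at least twice in a pool of size
#' \code{n} with probability \code{1 - (1-p)^n - n p (1-p)^(n-1)}. For
#' rare soil viruses this is small — the quantitative form of the argument
#' that multiple identical particles are unlikely to be sorted by chance,
#' so clonal within-pool copies point to vacuole delivery instead.
#'
#' @param p relative abundance, in (0, 1).
#' @param pool_size particles per pool.
#' @return probability in [0, 1].
#' @examples
#' clonal_copy_probability(0.01, 100)
#' @export
clonal_copy_probability <- function(p, pool_size = 100L) {
  if (any(p <= 0 | p >= 1)) stopf("p must lie in (0, 1)")
  n <- pool_size
  1 - (1 - p)^n - n * p * (1 - p)^(n - 1)
}

#' Amplify a sorted pool with MDA-style lognormal bias
#'
#' Multiple displacement amplification yields wildly uneven genome
#' amplification. Each particle gets an i.i.d. lognormal(0, bias_sigma)
#' amplification factor; factors sum per genome; the total sequencing
#' yield is distributed proportionally to the summed factors and converted
#' to mean coverage by genome length. With \code{bias_sigma = 0} every
#' factor is exactly 1 and depth is proportional to particle counts.
#'
#' @param pool one row of pool counts: named integer vector of particle
#'   counts per genome.
#' @param genome_lengths named numeric vector of genome lengths (bp).
#' @param bias_sigma lognormal sigma of the per-particle amplification
#'   factor (0 = unbiased).
#' @param total_yield total sequenced bases emitted for the pool.
#' @param seed RNG seed.
#' @return A \code{gv_amplified}: list with \code{amplification} (summed
#'   factors per genome), \code{emitted_depth} (mean coverage per genome)
#'   and \code{total_yield}; \code{sum(depth * length) == total_yield}.
#' @export
amplify <- function(pool, genome_lengths, bias_sigma = 1,
                    total_yield = 6e8, seed = 1L) {
  if (bias_sigma < 0) stopf("bias_sigma must be >= 0")
  ids <- names(pool)
  if (is.null(ids)) stopf("pool counts must be named by genome id")
  miss <- setdiff(ids[pool > 0], names(genome_lengths))
  if (length(miss))
    stopf("genome length(s) missing for: %s", paste(miss, collapse = ", "))
  with_seed(seed, {
    amp <- setNames(numeric(length(ids)), ids)
    for (g in ids[pool > 0]) {
      factors <- if (bias_sigma == 0) rep(1, pool[[g]])
                 else rlnorm(pool[[g]], 0, bias_sigma)
      amp[g] <- sum(factors)
    }
    depth <- setNames(numeric(length(ids)), ids)
    if (sum(amp) > 0) {
      bases <- total_yield * amp / sum(amp)
      present <- amp > 0
      depth[present] <- bases[present] / genome_lengths[ids[present]]
    }
    structure(list(amplification = amp, emitted_depth = depth,
                   total_yield = total_yield),
              class = "gv_amplified")
  })
}

#' Contig quality control: end-trim then length/coverage filter
#'
#' Reproduces the assembly post-processing rule: every contig end is
#' trimmed by \code{end_trim} bases, then contigs are discarded when the
#' trimmed length is below \code{min_len} or read coverage is below
#' \code{min_cov}. Both comparisons are inclusive on the keep side
#' (exactly 2 kb post-trim, or exactly 2.0x coverage, is kept).
#'
#' @param contigs depth-table data frame (\code{contig_id},
#'   \code{length_bp}, \code{mean_depth}, optional \code{bin_id}).
#' @param min_len minimum post-trim length, bp.
#' @param min_cov minimum read coverage.
#' @param end_trim bases trimmed from each contig end.
#' @return the surviving rows with an added \code{effective_len} column.
#' @examples
#' qc <- contig_qc(data.frame(contig_id = c("c1", "c2"),
#'                            length_bp = c(2400L, 1900L),
#'                            mean_depth = c(2, 10)))
#' qc$contig_id
#' @export
contig_qc <- function(contigs, min_len = 2000L, min_cov = 2.0,
                      end_trim = 200L) {
  if (any(contigs$length_bp <= 0)) stopf("contig lengths must be positive")
  eff <- pmax(0, contigs$length_bp - 2L * end_trim)
  keep <- eff >= min_len & contigs$mean_depth >= min_cov
  out <- contigs[keep, , drop = FALSE]
  out$effective_len <- eff[keep]
  rownames(out) <- NULL
  out
}

#' Benchmark an assembly against known source genomes
#'
#' Mirrors the study's two benchmarks (59 ten-cell sorts of a five-isolate
#' bacterial mock; a simulated 12-giant-virus community): given a map from
#' assembled contigs to their true source genome(s), computes the chimera
#' rate (fraction of contigs with more than one source), the per-genome
#' recovered fraction (bases on clean contigs attributed to the genome over
#' genome length, capped at 1) and, when contigs carry bin assignments,
#' per-bin purity (share of contigs agreeing with the bin's majority
#' source).
#'
#' @param contig_sources data frame with columns \code{contig_id},
#'   \code{source_genome} (one row per contig-source link; chimeric
#'   contigs have several rows), \code{length_bp}, optional \code{bin_id}.
#' @param genome_lengths named numeric vector of true genome lengths.
#' @return A \code{gv_benchmark}: list with \code{chimera_rate},
#'   \code{recovered_fraction} (named over genomes), \code{purity} (named
#'   over bins, or \code{NULL}), \code{n_contigs}.
#' @export
benchmark_mock <- function(contig_sources, genome_lengths) {
  need <- c("contig_id", "source_genome", "length_bp")
  miss <- setdiff(need, names(contig_sources))
  if (length(miss))
    stopf("contig_sources lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(is.na(contig_sources$source_genome)))
    stopf("contig(s) with no source genome")
  by_contig <- split(contig_sources, contig_sources$contig_id)
  n_src <- vapply(by_contig, function(x) length(unique(x$source_genome)), 1L)
  chimera_rate <- mean(n_src > 1)
  clean <- contig_sources[contig_sources$contig_id %in%
                            names(n_src)[n_src == 1], , drop = FALSE]
  clean <- clean[!duplicated(clean$contig_id), , drop = FALSE]
  rec <- setNames(numeric(length(genome_lengths)), names(genome_lengths))
  if (nrow(clean)) {
    got <- tapply(clean$length_bp, clean$source_genome, sum)
    got <- got[names(got) %in% names(rec)]
    rec[names(got)] <- pmin(1, as.numeric(got) / genome_lengths[names(got)])
  }
  purity <- NULL
  if ("bin_id" %in% names(contig_sources)) {
    one <- contig_sources[!duplicated(contig_sources$contig_id), ,
                          drop = FALSE]
    src_of <- vapply(by_contig, function(x) x$source_genome[1], "")
    one$major_src <- src_of[one$contig_id]
    purity <- vapply(split(one, one$bin_id), function(b) {
      best <- max(table(b$major_src))
      best / nrow(b)
    }, numeric(1))
  }
  structure(list(chimera_rate = chimera_rate, recovered_fraction = rec,
                 purity = purity, n_contigs = length(by_contig)),
            class = "gv_benchmark")
}

#' @export
print.gv_benchmark <- function(x, ...) {
  cat(sprintf("gv_benchmark: %d contigs, chimera rate %.3f\n",
              x$n_contigs, x$chimera_rate))
  invisible(x)
}

#' Preset simulator configurations
#'
#' \describe{
#'   \item{barre-woods}{the default soil community: 60 cellular genomes,
#'     12 rare NCLDV (one at bulk-detectable abundance), 90 pools of 100
#'     particles per sample with vacuole clumping.}
#'   \item{mock5}{the experimental benchmark: 5 bacterial isolates, 59
#'     sorts of 10 cells, no viruses.}
#'   \item{gv12}{the computational benchmark: 12 giant viruses, equal
#'     abundances.}
#' }
#'
#' @param name preset name.
#' @return list of simulator arguments.
#' @export
sim_preset <- function(name = c("barre-woods", "mock5", "gv12")) {
  name <- match.arg(name)
  switch(name,
    "barre-woods" = list(n_cellular = 60L, n_ncldv = 12L, n_pools = 90L,
                         pool_size = 100L, clump_prob = 0.08,
                         clump_copies = 20L, bias_sigma = 1.0),
    "mock5" = list(n_cellular = 5L, n_ncldv = 0L, n_pools = 59L,
                   pool_size = 10L, clump_prob = 0, clump_copies = 0L,
                   bias_sigma = 1.0),
    "gv12" = list(n_cellular = 0L, n_ncldv = 12L, n_pools = 12L,
                  pool_size = 100L, clump_prob = 0, clump_copies = 0L,
                  bias_sigma = 1.0))
}
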