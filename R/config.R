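#' Pipeline configuration with the study's published thresholds as defaults
#'
#' Collects every tunable threshold of the discovery pipeline in one object.
#' Defaults are the values used in the original soil giant-virus study:
#' a bin is an NCLDV candidate when it carries more than five distinct
#' ancestral NCVOG markers and/or the major capsid protein (NCVOG0022);
#' completeness is counted out of 20 ancestral NCVOGs; genomes are
#' dereplicated at 95% ANI with at least 100 kb aligned; alignment columns
#' with less than 10% sequence information are trimmed; the MCP survey uses an
#' e-value cutoff of 1e-6, 95% identity clustering and a 50-aa aligned-length
#' floor; the gene-sharing network is filtered at an 18% edge weight; sorted
#' pools hold 100 particles; contigs are end-trimmed by 200 bp and discarded
#' below 2 kb length or 2x coverage.
#'
#' @param ... named overrides for any default listed above.
#'
#' @return An object of class \code{gv_config}: a named list of thresholds.
#' @examples
#' cfg <- gv_config(mcp_evalue_cutoff = 1e-5)
#' cfg$ani_threshold
#' @export
gv_config <- function(...) {
  defaults <- list(
    marker_min_distinct   = 5L,      # strict "more than" comparison
    mcp_marker_id         = "NCVOG0022",
    ancestral_marker_count = 20L,
    core_min_markers      = 3L,      # phylogeny gate: <3 core markers excluded
    ani_threshold         = 95.0,    # percent
    aligned_fraction_min  = 100000L, # bp
    column_info_min       = 0.10,
    mcp_evalue_cutoff     = 1e-6,
    mcp_cluster_identity  = 0.95,
    mcp_min_aligned_aa    = 50L,
    edge_weight_min       = 18.0,    # percent
    pool_size             = 100L,
    contig_min_len        = 2000L,   # bp
    contig_min_cov        = 2.0,
    contig_end_trim       = 200L,    # bp
    rng_seed              = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, over)
  for (key in names(cfg)) {
    if (key %in% c("mcp_marker_id")) next
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stopf("config key '%s' must be a single positive number", key)
  }
  if (cfg$column_info_min > 1) stopf("column_info_min must be in (0,1]")
  if (cfg$mcp_cluster_identity > 1) stopf("mcp_cluster_identity must be in (0,1]")
  if (cfg$ani_threshold > 100) stopf("ani_threshold must be in (0,100]")
  structure(cfg, class = "gv_config")
}

#' @export
print.gv_config <- function(x, ...) {
  cat("gvpipe run configuration\n")
  for (key in names(x)) cat(sprintf("  %-22s %s\n", key, format(x[[key]])))
  invisible(x)
}

#' Write / read a configuration as a plain key = value file
#'
#' @param config a \code{gv_config} object.
#' @param path file path.
#' @return \code{read_config} returns a \code{gv_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "gv_config"))
  lines <- vapply(names(config), function(key) {
    v <- config[[key]]
    val <- if (is.character(v)) v else format(v, digits = 15)
    sprintf("%s = %s", key, val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stopf("unparsable config line: '%s'", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  parsed <- lapply(seq_along(vals), function(i) {
    num <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(num)) vals[i]
    else if (grepl("^(marker_min_distinct|ancestral_marker_count|core_min_markers|aligned_fraction_min|mcp_min_aligned_aa|pool_size|contig_min_len|contig_end_trim|rng_seed)$",
                   keys[i])) as.integer(num)
    else num
  })
  names(parsed) <- keys
  do.call(gv_config, parsed)
}
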