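#' Read a marker hit table (HMMER3 domtblout or plain TSV)
#'
#' Parses per-domain marker hits and collapses them to one record per
#' (protein, marker) pair, keeping the lowest e-value (ties on the log10
#' scale broken by the higher bitscore). Bin membership travels through an
#' explicit contig-to-bin map: the contig of a protein is its id with the
#' trailing \code{_<gene index>} stripped (the prodigal convention);
#' proteins whose contig has no entry are assigned to \code{"unbinned"}.
#'
#' The \code{hmmer_domtbl} dialect is the per-domain tabular output of
#' \code{hmmsearch --domtblout} (target = protein, query = marker profile,
#' per-domain independent e-value, domain bitscore, alignment coordinates
#' 1-based inclusive). The \code{plain_tsv} dialect is a headered TSV with
#' columns \code{query_id}, \code{marker_id}, \code{evalue},
#' \code{bitscore}, \code{aligned_len} and optionally \code{bin_id}.
#'
#' @param path path to the hit table.
#' @param dialect \code{"hmmer_domtbl"} or \code{"plain_tsv"}.
#' @param contig_bin_map optional data frame with columns \code{contig_id},
#'   \code{bin_id}, or a path to a two-column TSV with those names.
#' @return data frame with columns \code{query_id}, \code{bin_id},
#'   \code{marker_id}, \code{evalue}, \code{bitscore}, \code{aligned_len}.
#' @export
read_hit_table <- function(path, dialect = c("hmmer_domtbl", "plain_tsv"),
                           contig_bin_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("hit table not found: %s", path)
  hits <- switch(dialect,
                 hmmer_domtbl = parse_domtbl(path),
                 plain_tsv    = parse_plain_hits(path))
  if (nrow(hits) == 0) return(hits)
  hits <- collapse_best_hits(hits)
  if (!"bin_id" %in% names(hits) || all(is.na(hits$bin_id))) {
    map <- read_contig_bin_map(contig_bin_map)
    contig <- contig_of_protein(hits$query_id)
    hits$bin_id <- if (is.null(map)) "unbinned" else {
      idx <- match(contig, map$contig_id)
      ifelse(is.na(idx), "unbinned", map$bin_id[idx])
    }
  }
  hits[, c("query_id", "bin_id", "marker_id", "evalue", "bitscore",
           "aligned_len")]
}

read_contig_bin_map <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    x <- read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  if (!all(c("contig_id", "bin_id") %in% names(x)))
    stopf("contig->bin map needs columns contig_id, bin_id")
  x
}

parse_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(query_id = character(), marker_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      aligned_len = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "\\s+")
  short <- which(vapply(fields, length, 1L) < 22L)
  if (length(short))
    stopf("domtblout line %d has fewer than 22 columns", short[1])
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(v))
      stopf("unparsable %s on domtblout line %d", what, which(is.na(v))[1])
    v
  }
  ali_from <- num(18L, "ali-from"); ali_to <- num(19L, "ali-to")
  data.frame(
    query_id   = vapply(fields, `[[`, "", 1L),   # target sequence = protein
    marker_id  = vapply(fields, `[[`, "", 4L),   # query profile  = marker
    evalue     = num(13L, "i-Evalue"),
    bitscore   = num(14L, "domain score"),
    aligned_len = as.integer(ali_to - ali_from + 1),
    stringsAsFactors = FALSE)
}

parse_plain_hits <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(trimws(first)))
    return(data.frame(query_id = character(), marker_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      aligned_len = integer(), stringsAsFactors = FALSE))
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
  need <- c("query_id", "marker_id", "evalue", "bitscore", "aligned_len")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("plain hit TSV lacks column(s): %s", paste(miss, collapse = ", "))
  for (col in c("evalue", "bitscore", "aligned_len")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v))
      stopf("unparsable %s on line %d of %s", col, which(is.na(v))[1] + 1L,
            path)
    tab[[col]] <- v
  }
  tab$aligned_len <- as.integer(tab$aligned_len)
  if (any(tab$evalue <= 0)) stopf("e-values must be > 0")
  tab
}

# one record per (query, marker): lowest e-value, log10-tie -> higher bitscore
collapse_best_hits <- function(hits) {
  key <- paste(hits$query_id, hits$marker_id, sep = "\r")
  ord <- order(key, log10(hits$evalue), -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(key[ord]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write a hit table in the plain TSV dialect
#'
#' @param hits data frame as returned by [read_hit_table()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
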