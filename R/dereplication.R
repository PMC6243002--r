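#' Build the ANI graph used for dereplication
#'
#' Symmetrizes asymmetric ANI estimates (arithmetic mean of the two
#' orientations; minimum of the aligned bases) and keeps an edge between
#' two genomes when the mean ANI is at least \code{ani_threshold} percent
#' and the aligned fraction is at least \code{aligned_min} bases — the
#' 95% / 100 kb rule. Both comparisons are inclusive ("at least").
#' The aligned fraction is absolute base pairs, not a percentage of genome
#' length.
#'
#' @param pairs ANI table data frame from [read_ani_table()] (columns
#'   \code{genome_a}, \code{genome_b}, \code{ani}, \code{aligned_bp}).
#' @param ani_threshold minimum mean ANI, percent.
#' @param aligned_min minimum aligned bases.
#' @return data frame of undirected edges: \code{genome_a}, \code{genome_b}
#'   (canonical \code{a < b} order), \code{ani}, \code{aligned_bp}.
#' @export
build_ani_edges <- function(pairs, ani_threshold = 95, aligned_min = 1e5) {
  if (ani_threshold <= 0 || aligned_min <= 0)
    stopf("thresholds must be positive")
  if (nrow(pairs) == 0)
    return(data.frame(genome_a = character(), genome_b = character(),
                      ani = numeric(), aligned_bp = numeric(),
                      stringsAsFactors = FALSE))
  if (anyNA(pairs$ani) || anyNA(pairs$aligned_bp))
    stopf("ANI table contains missing values")
  if (any(pairs$ani < 0 | pairs$ani > 100))
    stopf("ANI values must lie in [0, 100]")
  a <- pmin(pairs$genome_a, pairs$genome_b)
  b <- pmax(pairs$genome_a, pairs$genome_b)
  key <- paste(a, b, sep = "\r")
  ani <- tapply(pairs$ani, key, mean)
  bp <- tapply(pairs$aligned_bp, key, min)
  keys <- names(ani)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(genome_a = vapply(parts, `[[`, "", 1L),
                    genome_b = vapply(parts, `[[`, "", 2L),
                    ani = as.numeric(ani), aligned_bp = as.numeric(bp),
                    stringsAsFactors = FALSE)
  out <- out[out$ani >= ani_threshold & out$aligned_bp >= aligned_min, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster genomes on the ANI graph and pick representatives
#'
#' Single-linkage dereplication: clusters are the connected components of
#' the thresholded ANI graph; genomes with no retained edge are singletons.
#' The representative of each cluster is its longest genome (ties broken by
#' the lexicographically smallest id); without lengths the smallest id is
#' used. A greedy-centroid mode is available for sensitivity checks: genomes
#' are visited longest-first and each joins the first representative it
#' shares an edge with, otherwise founds a new cluster.
#'
#' @param genomes character vector of all genome ids (including genomes
#'   absent from the edge list).
#' @param edges edge data frame from [build_ani_edges()].
#' @param lengths optional named numeric vector of genome lengths (bp).
#' @param method \code{"single"} (connected components, default) or
#'   \code{"greedy"}.
#' @return data frame with columns \code{cluster_id}, \code{genome_id},
#'   \code{representative}, one row per genome; clusters partition the
#'   genome set.
#' @examples
#' edges <- data.frame(genome_a = "A", genome_b = "B",
#'                     ani = 97, aligned_bp = 2e5)
#' ani_cluster(c("A", "B", "C"), edges)
#' @export
ani_cluster <- function(genomes, edges, lengths = NULL,
                        method = c("single", "greedy")) {
  method <- match.arg(method)
  genomes <- sort(unique(genomes))
  bad <- setdiff(c(edges$genome_a, edges$genome_b), genomes)
  if (length(bad))
    stopf("edge endpoint(s) not in genome set: %s",
          paste(bad, collapse = ", "))
  comp <- switch(method,
                 single = components_single(genomes, edges),
                 greedy = components_greedy(genomes, edges, lengths))
  reps <- vapply(split(genomes, comp), function(members) {
    if (!is.null(lengths)) {
      len <- lengths[members]
      members <- members[order(-len, members)]
    }
    members[1]
  }, character(1))
  out <- data.frame(cluster_id = sprintf("cluster_%03d", comp),
                    genome_id = genomes,
                    representative = reps[as.character(comp)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$cluster_id, out$genome_id), ]
}

# union-find over genome indices; returns component label per genome
components_single <- function(genomes, edges) {
  parent <- seq_along(genomes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(edges$genome_a, genomes)
  ib <- match(edges$genome_b, genomes)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(genomes), find, 1L)
  match(roots, sort(unique(roots)))
}

components_greedy <- function(genomes, edges, lengths) {
  ord <- if (is.null(lengths)) order(genomes)
         else order(-lengths[genomes], genomes)
  adj_key <- paste(pmin(edges$genome_a, edges$genome_b),
                   pmax(edges$genome_a, edges$genome_b), sep = "\r")
  has_edge <- function(a, b)
    paste(min(a, b), max(a, b), sep = "\r") %in% adj_key
  comp <- setNames(integer(length(genomes)), genomes)
  reps <- character(0)
  for (g in genomes[ord]) {
    joined <- FALSE
    for (ri in seq_along(reps)) {
      if (has_edge(g, reps[ri])) {
        comp[g] <- ri; joined <- TRUE; break
      }
    }
    if (!joined) {
      reps <- c(reps, g)
      comp[g] <- length(reps)
    }
  }
  as.integer(comp[genomes])
}

#' Write a cluster table and the dereplicated representative list
#'
#' @param clusters data frame from [ani_cluster()].
#' @param path output TSV path; the representative list is written next to
#'   it with suffix \code{.reps.txt}.
#' @return \code{path}, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  agg <- do.call(rbind, lapply(split(clusters, clusters$cluster_id),
    function(cl) data.frame(cluster_id = cl$cluster_id[1],
                            representative = cl$representative[1],
                            members = paste(cl$genome_id, collapse = ","),
                            stringsAsFactors = FALSE)))
  write.table(agg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sort(unique(clusters$representative)),
             paste0(path, ".reps.txt"))
  invisible(path)
}
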