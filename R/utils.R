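# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible sub-seed for a named RNG stream so that independent
# sub-generators (abundances, tree, orthogroups, ...) do not share draws.
# Kept below 2^31 - 1; plain integer arithmetic for cross-platform stability.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}

#' Structured log line to stderr: "[stage] message".
#' @noRd
gv_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Compare two e-values on the log10 scale; exact tie broken by bitscore.
#' Returns TRUE when hit a (evalue_a, score_a) is preferred over hit b.
#' @noRd
better_hit <- function(evalue_a, score_a, evalue_b, score_b) {
  la <- log10(evalue_a); lb <- log10(evalue_b)
  if (la != lb) la < lb else score_a > score_b
}

# strip prodigal-style "_<n>" gene index to get the contig id of a protein
contig_of_protein <- function(protein_id) sub("_[0-9]+$", "", protein_id)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
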