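#' Read and write FASTA sequence sets
#'
#' Thin wrappers around \pkg{Biostrings} that enforce the pipeline's
#' invariants: ids unique within a set, no empty records, and an explicit
#' alphabet tag. Both wrapped (60-column) and single-line FASTA dialects are
#' accepted. The id is the first whitespace-delimited token of the header;
#' the remainder is kept as the description.
#'
#' @param path path to a FASTA file.
#' @param alphabet one of \code{"auto"}, \code{"nucleotide"},
#'   \code{"protein"}. With \code{"auto"} the alphabet is inferred from the
#'   residue characters (IUPAC codes permitted).
#'
#' @return A \code{gv_seqset}: a data frame with columns \code{id},
#'   \code{description}, \code{residues} and an \code{alphabet} attribute.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 capsid", "MAGTKL", ">p2", "MKV"), tf)
#' ss <- read_fasta(tf)
#' attr(ss, "alphabet")
#' @export
read_fasta <- function(path, alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  if (file.size(path) == 0) stopf("FASTA file is empty: %s", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stopf("no FASTA records in %s", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stopf("duplicate sequence id(s) in %s: %s", path,
          paste(unique(dup), collapse = ", "))
  residues <- as.character(raw)
  if (any(!nzchar(residues)))
    stopf("empty sequence record(s) in %s: %s", path,
          paste(ids[!nzchar(residues)], collapse = ", "))
  if (alphabet == "auto") alphabet <- infer_alphabet(residues)
  seqset(ids, desc, residues, alphabet)
}

seqset <- function(ids, desc, residues, alphabet) {
  out <- data.frame(id = ids, description = desc, residues = residues,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("gv_seqset", "data.frame")
  out
}

# ACGTUN + IUPAC ambiguity codes and gaps dominate -> nucleotide
infer_alphabet <- function(residues) {
  chars <- toupper(paste(residues, collapse = ""))
  nuc <- nchar(gsub("[^ACGTUNRYSWKMBDHV.-]", "", chars))
  if (nuc / nchar(chars) > 0.95) "nucleotide" else "protein"
}

#' @rdname read_fasta
#' @param seqset a \code{gv_seqset} as returned by \code{read_fasta}, or any
#'   data frame with \code{id} and \code{residues} columns.
#' @param width line-wrap width for the sequence lines.
#' @return \code{write_fasta} returns \code{path} invisibly.
#' @export
write_fasta <- function(seqset, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(seqset)))
  if (anyDuplicated(seqset$id))
    stopf("duplicate sequence id(s): %s",
          paste(unique(seqset$id[duplicated(seqset$id)]), collapse = ", "))
  x <- Biostrings::BStringSet(seqset$residues)
  desc <- if ("description" %in% names(seqset)) seqset$description
          else rep("", nrow(seqset))
  names(x) <- ifelse(nzchar(desc), paste(seqset$id, desc), seqset$id)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read an aligned FASTA file as a multiple sequence alignment
#'
#' @param path path to an aligned FASTA (equal-length rows; gaps \code{-}
#'   or \code{.}).
#' @return A \code{gv_msa}: a named character vector of aligned rows.
#' @seealso [trim_columns()], [concatenate_alignments()]
#' @export
read_alignment <- function(path) {
  ss <- read_fasta(path)
  as_msa(setNames(ss$residues, ss$id))
}

#' Construct a multiple sequence alignment from named aligned strings
#'
#' @param rows named character vector, one aligned sequence per element.
#' @return A \code{gv_msa} object.
#' @export
as_msa <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stopf("alignment rows must be named by sequence id")
  if (anyDuplicated(names(rows)))
    stopf("duplicate id(s) in alignment: %s",
          paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stopf("alignment rows differ in length (%s)",
          paste(range(widths), collapse = "-"))
  structure(rows, class = "gv_msa")
}

#' @export
print.gv_msa <- function(x, ...) {
  cat(sprintf("gv_msa: %d sequences x %d columns\n", length(x), nchar(x[[1]])))
  invisible(x)
}

msa_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), ""))
}

#' @rdname read_alignment
#' @param aln a \code{gv_msa}.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(data.frame(id = names(aln), residues = as.character(aln),
                         stringsAsFactors = FALSE), path)
}
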