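#' Marker set definition for NCLDV screening
#'
#' The screen rests on a set of 20 "ancestral" NCVOGs — orthologous gene
#' families inferred to have been present in the common ancestor of the
#' NCLDV. Six members are fixed by their role in the pipeline: the major
#' capsid protein (NCVOG0022) and the five core phylogenetic markers — DNA
#' polymerase family B (NCVOG0038), D5-like helicase-primase (NCVOG0023),
#' the packaging ATPase (NCVOG0249), the superfamily II helicase
#' (NCVOG0076) and the VLTF3-like transcription factor (NCVOG0262). The
#' remaining 14 ancestral markers are configurable labels, since different
#' curations of the ancestral set circulate.
#'
#' The MCP is counted inside the 20-marker ancestral set but also tracked by
#' its own id because the candidate rule applies it as an independent
#' condition ("more than five different markers and/or the MCP").
#'
#' @param extra_ids character vector of the 14 non-core, non-MCP ancestral
#'   marker ids.
#' @param mcp_id id of the major capsid protein marker.
#' @param core5_ids ids of the five core phylogenetic markers.
#' @return A \code{gv_markers}: list with \code{marker_ids} (length 20),
#'   \code{mcp_id} and \code{core5_ids}.
#' @examples
#' md <- marker_definition()
#' length(md$marker_ids)
#' @export
marker_definition <- function(extra_ids = default_extra_markers(),
                              mcp_id = "NCVOG0022",
                              core5_ids = c("NCVOG0038", "NCVOG0023",
                                            "NCVOG0249", "NCVOG0076",
                                            "NCVOG0262")) {
  stopifnot(is_string(mcp_id), length(core5_ids) == 5L)
  marker_ids <- unique(c(mcp_id, core5_ids, extra_ids))
  if (length(marker_ids) != 20L)
    stopf("ancestral marker set must contain 20 distinct ids, got %d",
          length(marker_ids))
  structure(list(marker_ids = marker_ids, mcp_id = mcp_id,
                 core5_ids = core5_ids),
            class = "gv_markers")
}

# stand-in labels for the 14 ancestral NCVOGs outside the MCP + core five
default_extra_markers <- function() {
  sprintf("NCVOG%04d", c(21, 31, 35, 49, 52, 62, 271, 274, 276, 278,
                         320, 1060, 1117, 1164))
}

#' @export
print.gv_markers <- function(x, ...) {
  cat(sprintf("gv_markers: %d ancestral NCVOGs (MCP %s; core: %s)\n",
              length(x$marker_ids), x$mcp_id,
              paste(x$core5_ids, collapse = ", ")))
  invisible(x)
}
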