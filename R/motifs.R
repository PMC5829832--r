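# Sequence motif scanning for the CcoA and CopA signature motifs.

# X positions in a motif match any residue (including the ambiguity code X);
# literal positions match only their own letter, so an input X never
# satisfies M/H/C/D/K/G/T/P.
motif_regex <- function(pattern) {
  abort_if(!grepl("^[A-Z]+$", pattern), "invalid motif pattern: ", pattern)
  chartr_ok <- gsub("X", ".", pattern, fixed = TRUE)
  paste0("(?=(", chartr_ok, "))")
}

#' Scan a protein for signature motifs
#'
#' Reports every window matching each pattern, left to right; overlapping
#' matches are all reported. `X` in a pattern matches any residue; literal
#' pattern positions never match the ambiguity code `X` in the input.
#'
#' @param sequence protein sequence (single string).
#' @param patterns character vector of motif patterns, e.g.
#'   `c("MXXXM", "HXXXM", "CXXC", "DKTGT", "CPC")`.
#' @return data.frame with columns `pattern`, `position` (1-based start),
#'   `matched` (the matching substring) and `helix_index` (`NA` until
#'   assigned by [assign_helix_index()]).
#' @examples
#' scan_motifs("AAMGGGMAA", "MXXXM")
#' @export
scan_motifs <- function(sequence, patterns = c("MXXXM", "HXXXM")) {
  abort_if(length(sequence) != 1L || !is.character(sequence),
           "`sequence` must be a single string")
  sequence <- toupper(sequence)
  out <- lapply(patterns, function(p) {
    m <- gregexpr(motif_regex(p), sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    pos <- as.integer(m)
    data.frame(pattern = p, position = pos,
               matched = substring(sequence, pos, pos + nchar(p) - 1L),
               helix_index = NA_integer_)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(pattern = character(0), position = integer(0),
                      matched = character(0), helix_index = integer(0))
  }
  out[order(out$position, out$pattern), , drop = FALSE]
}

#' Assign motif hits to transmembrane helices
#'
#' A hit gets `helix_index = i` iff its full span lies inside helix `i`
#' (optionally expanded by `flank` residues on both sides); otherwise
#' `helix_index` stays `NA`.
#'
#' @param hits data.frame from [scan_motifs()].
#' @param topology a `tm_topology` from [predict_tm_helices()].
#' @param flank non-negative integer tolerance around each helix span.
#' @return `hits` with `helix_index` filled in.
#' @export
assign_helix_index <- function(hits, topology, flank = 0L) {
  abort_if(!inherits(topology, "tm_topology"), "`topology` must be a tm_topology")
  if (nrow(hits) == 0L || topology$n_helices == 0L) return(hits)
  hs <- topology$helices$start - flank
  he <- topology$helices$end + flank
  for (i in seq_len(nrow(hits))) {
    s <- hits$position[i]
    e <- s + nchar(hits$matched[i]) - 1L
    j <- which(s >= hs & e <= he)
    if (length(j) >= 1L) hits$helix_index[i] <- j[1]
  }
  hits
}
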