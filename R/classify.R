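# CcoA-like classification: similarity + topology + motif conservation.

#' Classification parameters
#'
#' @param window,threshold,min_len,merge_gap topology parameters, see
#'   [predict_tm_helices()].
#' @param min_similarity minimum normalized alignment score against the
#'   seed sequence (score divided by the seed self-score).
#' @param motif_flank residues of tolerance around helix spans when
#'   requiring a motif to lie inside a helix (0 = strict).
#' @param seed_self_score optional precomputed self-alignment score of the
#'   seed sequence (avoids recomputation in batch runs).
#' @return a named list of parameters.
#' @export
classify_params <- function(window = 19, threshold = 1.6, min_len = 15,
                            merge_gap = 4, min_similarity = 0.3,
                            motif_flank = 0L, seed_self_score = NULL) {
  list(window = window, threshold = threshold, min_len = min_len,
       merge_gap = merge_gap, min_similarity = min_similarity,
       motif_flank = motif_flank, seed_self_score = seed_self_score)
}

#' Classify a protein as CcoA-like
#'
#' A protein is called `ccoA_like` when (i) its normalized global
#' alignment score against the seed CcoA is at least
#' `params$min_similarity`, (ii) an MXXXM motif lies inside predicted
#' transmembrane helix 7 and an HXXXM motif inside helix 8, and (iii) 12
#' helices are predicted. With 11 helices (C-terminal truncation removing
#' helix 12) the verdict is `ccoA_like_truncated`. Anything else is
#' `negative`, with every failed criterion listed in `reasons`.
#'
#' @param protein protein sequence (single string).
#' @param seed_sequence the reference CcoA protein; defaults to
#'   [ccoa_reference_protein()].
#' @param params list from [classify_params()].
#' @return an object of class `ccoa_classification`: list with `verdict`,
#'   `similarity_score` (normalized), `topology`, `motif_evidence`
#'   (data.frame of motif hits with helix assignments) and `reasons`.
#' @examples
#' cls <- classify_ccoa(generate_ccoa_like(seed = 1))
#' cls$verdict
#' @export
classify_ccoa <- function(protein, seed_sequence = ccoa_reference_protein(),
                          params = classify_params()) {
  abort_if(is.null(seed_sequence) || nchar(seed_sequence) == 0L,
           "a seed sequence (reference CcoA) is required")
  topo <- predict_tm_helices(protein, window = params$window,
                             threshold = params$threshold,
                             min_len = params$min_len,
                             merge_gap = params$merge_gap)
  hits <- scan_motifs(protein, c("MXXXM", "HXXXM"))
  hits <- assign_helix_index(hits, topo, flank = params$motif_flank)

  self_seed <- params$seed_self_score %||%
    pairwise_align(seed_sequence, seed_sequence)$score
  sim <- pairwise_align(protein, seed_sequence)$score / self_seed

  reasons <- character(0)
  if (sim < params$min_similarity) reasons <- c(reasons, "low_similarity")
  m7 <- any(hits$pattern == "MXXXM" & hits$helix_index %in% 7L)
  h8 <- any(hits$pattern == "HXXXM" & hits$helix_index %in% 8L)
  if (!m7) reasons <- c(reasons, "missing_MXXXM_helix7")
  if (!h8) reasons <- c(reasons, "missing_HXXXM_helix8")
  if (!topo$n_helices %in% c(11L, 12L))
    reasons <- c(reasons, "unexpected_helix_count")

  verdict <- if (length(reasons) == 0L) {
    if (topo$n_helices == 12L) "ccoA_like" else "ccoA_like_truncated"
  } else "negative"

  structure(list(verdict = verdict, similarity_score = sim,
                 topology = topo, motif_evidence = hits,
                 reasons = reasons),
            class = "ccoa_classification")
}

#' @export
print.ccoa_classification <- function(x, ...) {
  cat("CcoA classification:", x$verdict,
      sprintf("(%d helices, normalized score %.3f)\n",
              x$topology$n_helices, x$similarity_score))
  if (length(x$reasons)) cat("  failed:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a set of proteins against the seed CcoA
#'
#' Batch wrapper around [classify_ccoa()] producing one row per protein,
#' suitable for writing as the classification TSV.
#'
#' @param proteins data.frame with columns `protein_id`, `genome_id`,
#'   `sequence` (e.g. from [cohort_proteins()]), or a named character
#'   vector of sequences.
#' @inheritParams classify_ccoa
#' @return data.frame with columns `protein_id`, `genome_id`, `verdict`,
#'   `n_helices`, `mxxxm_helix7`, `hxxxm_helix8`, `score`, `reasons`.
#' @export
classify_proteins <- function(proteins, seed_sequence = ccoa_reference_protein(),
                              params = classify_params()) {
  if (is.character(proteins)) {
    proteins <- data.frame(protein_id = names(proteins) %||%
                             paste0("p", seq_along(proteins)),
                           genome_id = NA_character_,
                           sequence = unname(proteins))
  }
  if (nrow(proteins) == 0L) {
    return(data.frame(protein_id = character(0), genome_id = character(0),
                      verdict = character(0), n_helices = integer(0),
                      mxxxm_helix7 = integer(0), hxxxm_helix8 = integer(0),
                      score = numeric(0), reasons = character(0)))
  }
  if (is.null(params$seed_self_score)) {
    params$seed_self_score <- pairwise_align(seed_sequence, seed_sequence)$score
  }
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    cls <- classify_ccoa(proteins$sequence[i], seed_sequence, params)
    hp <- function(pat, hel) {
      h <- cls$motif_evidence
      p <- h$position[h$pattern == pat & h$helix_index %in% hel]
      if (length(p)) p[1] else NA_integer_
    }
    data.frame(protein_id = proteins$protein_id[i],
               genome_id = proteins$genome_id[i],
               verdict = cls$verdict,
               n_helices = cls$topology$n_helices,
               mxxxm_helix7 = hp("MXXXM", 7L),
               hxxxm_helix8 = hp("HXXXM", 8L),
               score = cls$similarity_score,
               reasons = paste(cls$reasons, collapse = ";"))
  })
  do.call(rbind, rows)
}
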