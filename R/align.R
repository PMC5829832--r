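# Global pairwise protein alignment (Needleman-Wunsch via Biostrings).

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- get("BLOSUM62", envir = e)
    }
    mat
  }
})

#' Global pairwise alignment with identity and similarity percentages
#'
#' Needleman-Wunsch global alignment. Identity is the number of identical
#' aligned residue pairs divided by the number of alignment columns
#' (including gap columns), as a percentage; similarity counts aligned
#' pairs with a positive substitution score.
#'
#' @param a,b protein sequences (single non-empty strings).
#' @param substitution substitution matrix name (only `"BLOSUM62"` is
#'   shipped) or a numeric matrix.
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return list with `score`, `identity` (percent), `similarity` (percent),
#'   `columns`, and the gapped `aligned_a` / `aligned_b` strings.
#' @examples
#' pairwise_align("MKLLIVF", "MKLLIVF")$identity
#' @export
pairwise_align <- function(a, b, substitution = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  abort_if(!is.character(a) || length(a) != 1L || nchar(a) == 0L,
           "`a` must be a non-empty protein string")
  abort_if(!is.character(b) || length(b) != 1L || nchar(b) == 0L,
           "`b` must be a non-empty protein string")
  mat <- if (is.matrix(substitution)) substitution else {
    abort_if(!identical(substitution, "BLOSUM62"),
             "unknown substitution matrix: ", substitution)
    blosum62()
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "", fixed = TRUE)[[1]]
  cb <- strsplit(pb, "", fixed = TRUE)[[1]]
  cols <- length(ca)
  paired <- ca != "-" & cb != "-"
  ident <- sum(paired & ca == cb)
  simil <- sum(mat[cbind(ca[paired], cb[paired])] > 0)
  list(score = Biostrings::score(aln),
       identity = 100 * ident / cols,
       similarity = 100 * simil / cols,
       columns = cols,
       aligned_a = pa, aligned_b = pb)
}

#' Normalized similarity score between two proteins
#'
#' Global alignment score normalized by the geometric mean of the two
#' self-alignment scores, so identical sequences score 1 and unrelated
#' sequences score near (or below) 0. This dimensionless score is the
#' package's analog of database-search alignment scores for network
#' thresholds.
#'
#' @inheritParams pairwise_align
#' @param self_a,self_b optional precomputed self-alignment scores.
#' @return a single numeric score.
#' @export
normalized_score <- function(a, b, substitution = "BLOSUM62",
                             gap_open = 10, gap_extend = 0.5,
                             self_a = NULL, self_b = NULL) {
  sab <- pairwise_align(a, b, substitution, gap_open, gap_extend)$score
  saa <- self_a %||% pairwise_align(a, a, substitution, gap_open, gap_extend)$score
  sbb <- self_b %||% pairwise_align(b, b, substitution, gap_open, gap_extend)$score
  sab / sqrt(saa * sbb)
}
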