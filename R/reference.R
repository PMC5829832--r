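# The canonical CcoA-like reference protein used as the classification seed
# and as the backbone from which synthetic homologs are derived.

HYDROPHOBIC <- c("L", "I", "V", "F")
POLAR_CHARGED <- c("D", "E", "K", "R", "N", "Q", "S", "G")

REF_N_HELICES <- 12L
REF_HELIX_LEN <- 21L
REF_LOOP_LEN <- 25L

ref_layout <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    nterm <- strsplit("MSDNKEQSGR", "")[[1]]
    ctail <- strsplit("DEKRSGNQDEKR", "")[[1]]
    block <- rep_len(HYDROPHOBIC, REF_HELIX_LEN)
    loop <- rep_len(POLAR_CHARGED, REF_LOOP_LEN)

    res <- nterm
    class <- rep("nterm", length(nterm))
    helix_of <- rep(NA_integer_, length(nterm))
    helix_start <- integer(REF_N_HELICES)
    for (i in seq_len(REF_N_HELICES)) {
      b <- block
      # splice the copper-ligand motifs into the centres of helices 7 and 8
      if (i == 7L) { b[9] <- "M"; b[13] <- "M" }   # MXXXM
      if (i == 8L) { b[9] <- "H"; b[13] <- "M" }   # HXXXM
      helix_start[i] <- length(res) + 1L
      res <- c(res, b)
      class <- c(class, rep("helix", REF_HELIX_LEN))
      helix_of <- c(helix_of, rep(i, REF_HELIX_LEN))
      if (i < REF_N_HELICES) {
        res <- c(res, loop)
        class <- c(class, rep("loop", REF_LOOP_LEN))
        helix_of <- c(helix_of, rep(NA_integer_, REF_LOOP_LEN))
      }
    }
    res <- c(res, ctail)
    class <- c(class, rep("tail", length(ctail)))
    helix_of <- c(helix_of, rep(NA_integer_, length(ctail)))

    # positions that must never mutate: initiator Met and the literal
    # motif residues (the X positions are free to vary)
    fixed <- rep(FALSE, length(res))
    fixed[1] <- TRUE
    fixed[helix_start[7] + c(8L, 12L)] <- TRUE
    fixed[helix_start[8] + c(8L, 12L)] <- TRUE
    cache <<- list(residues = res, class = class, helix_of = helix_of,
                   helix_start = helix_start, fixed = fixed)
    cache
  }
})

#' The reference CcoA-like seed protein
#'
#' A deterministic canonical CcoA-like sequence: 12 transmembrane helices
#' of 21 hydrophobic residues separated by 25-residue polar loops, with
#' the MXXXM motif in helix 7 and the HXXXM motif in helix 8. It serves
#' as the seed sequence for [classify_ccoa()] and as the backbone mutated
#' by [generate_ccoa_like()].
#'
#' @return a single protein string.
#' @export
ccoa_reference_protein <- function() {
  paste(ref_layout()$residues, collapse = "")
}
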