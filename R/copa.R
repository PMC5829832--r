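# Synthetic copA alleles: embedded nucleotide tandem repeats, metal-binding
# motifs, and tract-internal indels with ground-truth frameshift reports.

COPA_MOTIFS <- c("CXXC", "DKTGT", "CPC")

# varied filler codons (no stops, no doubled letters at codon junctions
# likely to seed spurious tandem repeats)
FILLER_CODONS <- c("GAT", "GAA", "CTG", "AAG", "CGT", "AGC",
                   "GGT", "ACC", "TTC", "GCA")

motif_codons <- list(
  CXXC = c("TGT", "GAA", "CTG", "TGC"),
  DKTGT = c("GAT", "AAG", "ACA", "GGA", "ACG"),
  CPC = c("TGT", "CCA", "TGC"))

#' Specification of a synthetic copA allele
#'
#' Describes a copA coding sequence with an embedded nucleotide tandem
#' repeat (NTR), the N-terminal metal-binding CXXC motif before the tract
#' and the DKTGT phosphorylation and CPC transmembrane metal-binding
#' motifs after it, plus an optional tract-internal indel.
#'
#' @param tract_unit repeat unit, 1-3 bases over ACGT, primitive.
#' @param tract_copies number of unit copies (>= 4).
#' @param tract_codon_offset 1-based codon index where the tract begins.
#' @param indel optional list `list(op = "ins"|"del", sequence = <bases>)`,
#'   applied at the start of the tract (leftmost placement), plus an
#'   optional `position` (1-based nucleotide) which must fall inside the
#'   tract.
#' @param motif_layout named integer vector of 1-based amino-acid start
#'   positions for `CXXC`, `DKTGT`, `CPC`.
#' @param protein_length total encoded protein length in residues.
#' @return a list of class `copa_spec`.
#' @export
copa_spec <- function(tract_unit = "CG", tract_copies = 5L,
                      tract_codon_offset = 80L, indel = NULL,
                      motif_layout = c(CXXC = 15L, DKTGT = 150L, CPC = 220L),
                      protein_length = 300L) {
  abort_if(!grepl("^[ACGT]{1,3}$", tract_unit),
           "`tract_unit` must be 1-3 bases over ACGT")
  abort_if(is_nonprimitive_unit(tract_unit),
           "`tract_unit` must be primitive (not itself a repeat)")
  abort_if(tract_copies < 4L, "`tract_copies` must be >= 4")
  abort_if(!all(COPA_MOTIFS %in% names(motif_layout)),
           "`motif_layout` must name CXXC, DKTGT and CPC")
  tract_len <- nchar(tract_unit) * tract_copies
  tract_codons <- ceiling(tract_len / 3)
  abort_if(motif_layout[["CXXC"]] + 3L >= tract_codon_offset,
           "CXXC must lie entirely before the tract")
  abort_if(motif_layout[["DKTGT"]] <= tract_codon_offset + tract_codons,
           "DKTGT must follow the tract")
  abort_if(motif_layout[["CPC"]] <= motif_layout[["DKTGT"]] + 4L,
           "CPC must follow DKTGT")
  abort_if(motif_layout[["CPC"]] + 2L > protein_length,
           "tract and motifs must fit inside the coding frame")
  if (!is.null(indel)) {
    abort_if(!is.list(indel) || !indel$op %in% c("ins", "del") ||
               !grepl("^[ACGT]+$", indel$sequence),
             "`indel` must be list(op = 'ins'|'del', sequence = <ACGT>)")
  }
  structure(list(tract_unit = tract_unit, tract_copies = as.integer(tract_copies),
                 tract_codon_offset = as.integer(tract_codon_offset),
                 indel = indel, motif_layout = motif_layout,
                 protein_length = as.integer(protein_length)),
            class = "copa_spec")
}

is_nonprimitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        strrep(substr(unit, 1L, d), u / d) == unit) return(TRUE)
  }
  FALSE
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate wild-type and mutant copA coding sequences
#'
#' Builds a CDS realizing a [copa_spec()]: ATG start, the CXXC, DKTGT and
#' CPC motif codons at their laid-out positions, the nucleotide tandem
#' repeat at its codon offset (padded to the codon boundary with bases
#' that cannot extend the tract), and varied filler codons elsewhere. If
#' the spec carries an indel it is applied at the start of the tract and
#' a ground-truth frameshift report is computed from the layout.
#'
#' @param spec a [copa_spec()].
#' @return list with `wt_cds`, `mut_cds`, `truth` (a `frameshift_report`
#'   or `NULL` when no indel), and `tract` (the embedded [RepeatTract]
#'   as a one-row data.frame).
#' @examples
#' allele <- generate_copa(copa_spec(tract_unit = "C", tract_copies = 10,
#'                                   indel = list(op = "ins", sequence = "C")))
#' allele$truth$frameshift
#' @export
generate_copa <- function(spec = copa_spec()) {
  abort_if(!inherits(spec, "copa_spec"), "`spec` must be a copa_spec")
  u <- nchar(spec$tract_unit)
  tract_nt <- strrep(spec$tract_unit, spec$tract_copies)
  tract_len <- nchar(tract_nt)
  n_tract_codons <- ceiling(tract_len / 3)

  codons <- rep_len(FILLER_CODONS, spec$protein_length)
  codons[1] <- "ATG"
  for (m in COPA_MOTIFS) {
    at <- spec$motif_layout[[m]]
    codons[at:(at + length(motif_codons[[m]]) - 1L)] <- motif_codons[[m]]
  }

  # tract occupies codons tract_codon_offset .. +n_tract_codons-1; pad the
  # tail of the last codon so the tract is not extendable to the right
  pad_needed <- n_tract_codons * 3L - tract_len
  next_expected <- substr(spec$tract_unit, tract_len %% u + 1L,
                          tract_len %% u + 1L)
  pad <- character(0)
  if (pad_needed > 0L) {
    first <- setdiff(c("A", "T", "G", "C"), next_expected)[1]
    rest <- rep_len(setdiff(c("A", "C"), first)[1], max(0L, pad_needed - 1L))
    pad <- c(first, rest)
  }
  tract_block <- strsplit(paste0(tract_nt, paste(pad, collapse = "")), "")[[1]]
  tract_codon_str <- vapply(seq_len(n_tract_codons), function(i) {
    paste(tract_block[(3L * i - 2L):(3L * i)], collapse = "")
  }, "")
  abort_if(any(tract_codon_str %in% STOP_CODONS),
           "tract would introduce an in-frame stop codon")
  ti <- spec$tract_codon_offset
  codons[ti:(ti + n_tract_codons - 1L)] <- tract_codon_str

  # the codon before the tract must not extend the tract to the left
  prev_last <- substr(spec$tract_unit, u, u)
  cand <- FILLER_CODONS[substr(FILLER_CODONS, 3L, 3L) != prev_last]
  if (substr(codons[ti - 1L], 3L, 3L) == prev_last) codons[ti - 1L] <- cand[1]

  wt <- paste(codons, collapse = "")
  tract_start <- (ti - 1L) * 3L + 1L
  tract <- data.frame(unit = spec$tract_unit, copies = spec$tract_copies,
                      start = tract_start, end = tract_start + tract_len - 1L,
                      canonical = TRUE)

  # wild-type must translate cleanly
  aa <- translate_cds(wt)
  abort_if(grepl("\\*", substr(aa, 1L, nchar(aa) - 0L)),
           "internal error: wild-type CDS contains a stop codon")

  if (is.null(spec$indel)) {
    return(list(wt_cds = wt, mut_cds = wt, truth = NULL, tract = tract))
  }

  op <- spec$indel$op
  seq_ <- spec$indel$sequence
  pos <- spec$indel$position %||% tract_start
  inside <- if (op == "del") {
    pos >= tract_start && (pos + nchar(seq_) - 1L) <= tract$end
  } else {
    pos >= tract_start && pos <= tract$end + 1L
  }
  abort_if(!inside, "indel must be placed inside the repeat tract")

  mut <- if (op == "ins") {
    paste0(substr(wt, 1L, pos - 1L), seq_, substr(wt, pos, nchar(wt)))
  } else {
    abort_if(substr(wt, pos, pos + nchar(seq_) - 1L) != seq_,
             "deletion sequence does not match the reference at its position")
    paste0(substr(wt, 1L, pos - 1L), substr(wt, pos + nchar(seq_), nchar(wt)))
  }

  frameshift <- nchar(seq_) %% 3L != 0L
  shift_codon <- ceiling(pos / 3L)
  present <- names(spec$motif_layout)
  motif_end_aa <- spec$motif_layout +
    vapply(names(spec$motif_layout), function(m) length(motif_codons[[m]]) - 1L, 0L)
  if (frameshift) {
    retained <- present[motif_end_aa < shift_codon]
  } else {
    retained <- present  # in-frame tract indels never touch the motifs
  }
  mut_aa <- translate_cds(mut)
  stop_at <- regexpr("*", mut_aa, fixed = TRUE)
  stop_idx <- if (stop_at > 0L && stop_at < nchar(mut_aa)) as.integer(stop_at)
              else NA_integer_
  truth <- new_frameshift_report(
    frameshift = frameshift,
    indel = data.frame(position = pos, op = op, sequence = seq_,
                       length = nchar(seq_)),
    premature_stop_codon_index = stop_idx,
    truncated_length = if (!is.na(stop_idx)) stop_idx - 1L
                       else nchar(gsub("\\*.*$", "", mut_aa)),
    retained_motifs = retained,
    lost_motifs = setdiff(present, retained))
  list(wt_cds = wt, mut_cds = mut, truth = truth, tract = tract)
}

translate_cds <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

new_frameshift_report <- function(frameshift, indel, premature_stop_codon_index,
                                  truncated_length, retained_motifs,
                                  lost_motifs) {
  structure(list(frameshift = frameshift, indel = indel,
                 premature_stop_codon_index = premature_stop_codon_index,
                 truncated_length = truncated_length,
                 retained_motifs = retained_motifs,
                 lost_motifs = lost_motifs),
            class = "frameshift_report")
}

#' @export
print.frameshift_report <- function(x, ...) {
  cat("Frameshift report: frameshift =", x$frameshift, "\n")
  if (!is.null(x$indel) && nrow(x$indel))
    cat(sprintf("  %s of %s at %d\n", x$indel$op, x$indel$sequence,
                x$indel$position))
  cat("  premature stop codon:", x$premature_stop_codon_index,
      "| truncated length:", x$truncated_length, "\n")
  cat("  retained:", paste(x$retained_motifs, collapse = ","),
      "| lost:", paste(x$lost_motifs, collapse = ","), "\n")
  invisible(x)
}
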