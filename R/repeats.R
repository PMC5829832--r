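# Nucleotide tandem repeat scanning, indel localization and frameshift
# consequence prediction for copA suppressor alleles.

#' Scan a DNA sequence for nucleotide tandem repeats
#'
#' Finds all maximal tandem repeats with primitive units of 1-3 bases,
#' reported canonically (smallest unit, leftmost phase) in left-to-right
#' order. A tract is reported when its copy number reaches the threshold
#' for its unit size; its span covers whole unit copies only and is not
#' extendable by a further full copy on either side.
#'
#' @param dna DNA sequence over ACGT (single string).
#' @param min_copies named integer vector of minimum copy numbers keyed by
#'   unit size (`"1"`, `"2"`, `"3"`).
#' @param on_ambiguous `"skip"` treats non-ACGT characters as tract
#'   breakers (with a warning); `"error"` rejects them.
#' @return data.frame (one row per tract) with `unit`, `copies`, `start`,
#'   `end` (1-based inclusive) and `canonical`.
#' @examples
#' scan_ntr(paste0("AAT", strrep("C", 10), "GGA"))
#' @export
scan_ntr <- function(dna, min_copies = c(`1` = 5L, `2` = 4L, `3` = 3L),
                     on_ambiguous = c("skip", "error")) {
  on_ambiguous <- match.arg(on_ambiguous)
  abort_if(length(dna) != 1L || !is.character(dna),
           "`dna` must be a single string")
  dna <- toupper(dna)
  if (grepl("[^ACGT]", dna)) {
    abort_if(on_ambiguous == "error", "`dna` contains non-ACGT characters")
    warning("non-ACGT characters present; treated as repeat breakers",
            call. = FALSE)
  }
  # scan each maximal ACGT chunk independently (ambiguity codes break tracts)
  chunks <- gregexpr("[ACGT]+", dna)[[1]]
  out <- list()
  for (ci in seq_along(chunks)) {
    if (chunks[ci] == -1L) break
    off <- as.integer(chunks[ci]) - 1L
    s <- strsplit(substr(dna, chunks[ci],
                         chunks[ci] + attr(chunks, "match.length")[ci] - 1L),
                  "", fixed = TRUE)[[1]]
    n <- length(s)
    for (u in 1:3) {
      minc <- suppressWarnings(as.integer(min_copies[as.character(u)]))
      if (is.na(minc) || n < u * minc || n <= u) next
      # positions i where s[i] == s[i+u]: maximal runs of this self-match
      # property delimit maximal period-u regions (leftmost phase)
      m <- seq_len(n - u)
      eq <- s[m] == s[m + u]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        region_start <- starts[k]
        region_len <- r$lengths[k] + u        # nucleotides in the region
        copies <- region_len %/% u
        if (copies < minc) next
        unit <- paste(s[region_start:(region_start + u - 1L)], collapse = "")
        if (u > 1L && is_nonprimitive_unit(unit)) next
        out[[length(out) + 1L]] <- data.frame(
          unit = unit, copies = copies, start = off + region_start,
          end = off + region_start + u * copies - 1L, canonical = TRUE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(unit = character(0), copies = integer(0),
                      start = integer(0), end = integer(0),
                      canonical = logical(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, nchar(res$unit)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Locate a single contiguous indel between two alleles
#'
#' Validates that the mutant differs from the reference by exactly one
#' contiguous insertion or deletion and reports it with leftmost-aligned
#' placement (as in VCF normalization). When the indel falls inside (or,
#' for insertions, immediately extends) a tandem repeat tract of the
#' reference, the tract is attached as `in_tract`.
#'
#' @param ref_cds,mut_cds reference and mutant DNA sequences.
#' @param min_copies tract thresholds passed to [scan_ntr()].
#' @return list of class `indel_call` with `position` (1-based coordinate
#'   in the reference of the first inserted/deleted base), `op`
#'   (`"ins"`/`"del"`/`"none"`), `sequence`, `length` and `in_tract`
#'   (one-row data.frame or `NULL`).
#' @export
locate_indel <- function(ref_cds, mut_cds,
                         min_copies = c(`1` = 5L, `2` = 4L, `3` = 3L)) {
  ref_cds <- toupper(ref_cds); mut_cds <- toupper(mut_cds)
  R <- nchar(ref_cds); M <- nchar(mut_cds)
  if (identical(ref_cds, mut_cds)) {
    return(structure(list(position = NA_integer_, op = "none", sequence = "",
                          length = 0L, in_tract = NULL), class = "indel_call"))
  }
  abort_if(R == M, "sequences differ but have equal length: not a single indel")
  a <- strsplit(ref_cds, "", fixed = TRUE)[[1]]
  b <- strsplit(mut_cds, "", fixed = TRUE)[[1]]
  short <- min(R, M)
  pref <- 0L
  while (pref < short && a[pref + 1L] == b[pref + 1L]) pref <- pref + 1L
  suff <- 0L
  while (suff < short && a[R - suff] == b[M - suff]) suff <- suff + 1L
  abort_if(pref + suff < short,
           "alleles differ by more than one contiguous indel block")
  # leftmost placement: maximal suffix match pushes the event left
  i <- max(0L, short - suff)         # bases retained before the event
  abort_if(i > pref, "alleles differ by more than one contiguous indel block")
  if (M > R) {
    op <- "ins"; len <- M - R
    seq_ <- substr(mut_cds, i + 1L, i + len)
    pos <- i + 1L                     # insertion before this ref position
  } else {
    op <- "del"; len <- R - M
    seq_ <- substr(ref_cds, i + 1L, i + len)
    pos <- i + 1L
  }
  tracts <- scan_ntr(ref_cds, min_copies)
  in_tract <- NULL
  if (nrow(tracts)) {
    hit <- if (op == "del") {
      tracts$start <= (pos + len - 1L) & tracts$end >= pos
    } else {
      pos >= tracts$start & pos <= tracts$end + 1L
    }
    if (any(hit)) in_tract <- tracts[which(hit)[1], , drop = FALSE]
  }
  structure(list(position = pos, op = op, sequence = seq_, length = len,
                 in_tract = in_tract), class = "indel_call")
}

#' @export
print.indel_call <- function(x, ...) {
  if (x$op == "none") cat("No indel (alleles identical)\n")
  else cat(sprintf("%s of %s (length %d) at reference position %d%s\n",
                   x$op, x$sequence, x$length, x$position,
                   if (!is.null(x$in_tract))
                     sprintf(" [in %sx%d tract]", x$in_tract$unit,
                             x$in_tract$copies) else ""))
  invisible(x)
}

#' Apply an indel call to a reference sequence
#'
#' Reconstructs the mutant allele from a reference and an `indel_call`;
#' the round trip through [locate_indel()] is exact.
#'
#' @param ref_cds reference DNA sequence.
#' @param indel an `indel_call`.
#' @return the mutant sequence.
#' @export
apply_indel <- function(ref_cds, indel) {
  if (indel$op == "none") return(ref_cds)
  n <- nchar(ref_cds)
  abort_if(indel$position > n + 1L, "indel lies beyond the sequence end")
  if (indel$op == "ins") {
    paste0(substr(ref_cds, 1L, indel$position - 1L), indel$sequence,
           substr(ref_cds, indel$position, n))
  } else {
    abort_if(indel$position + indel$length - 1L > n,
             "indel lies beyond the sequence end")
    abort_if(substr(ref_cds, indel$position,
                    indel$position + indel$length - 1L) != indel$sequence,
             "deletion sequence does not match the reference")
    paste0(substr(ref_cds, 1L, indel$position - 1L),
           substr(ref_cds, indel$position + indel$length, n))
  }
}

#' Predict the translational consequence of an indel
#'
#' Applies the indel to the reference CDS, translates the mutant in frame
#' 1 with the standard genetic code, and reports whether the indel causes
#' a frameshift (length not a multiple of 3), the first premature stop,
#' the truncated product length, and which of the wild-type protein
#' motifs are retained. Under a frameshift, a motif is retained iff its
#' full wild-type span ends strictly before the first frameshifted codon;
#' residues encoded after the shift are treated as non-homologous. For
#' in-frame indels retention is determined by rescanning the mutant
#' translation for the motif patterns.
#'
#' @param ref_cds reference CDS (frame 1, no internal stop).
#' @param indel an `indel_call` from [locate_indel()].
#' @param motif_layout named integer vector of 1-based amino-acid start
#'   positions of motifs present in the wild-type protein (patterns among
#'   `CXXC`, `DKTGT`, `CPC`, `CPX`).
#' @return a `frameshift_report`.
#' @export
frameshift_consequence <- function(ref_cds, indel,
                                   motif_layout = c(CXXC = 15L, DKTGT = 150L,
                                                    CPC = 220L)) {
  ref_aa <- translate_cds(ref_cds)
  abort_if(grepl("*", ref_aa, fixed = TRUE),
           "reference CDS contains an internal stop codon")
  abort_if(indel$op != "none" && indel$position > nchar(ref_cds) + 1L,
           "indel lies beyond the sequence end")
  mut <- apply_indel(ref_cds, indel)
  mut_aa <- translate_cds(mut)
  frameshift <- indel$length %% 3L != 0L

  stop_at <- regexpr("*", mut_aa, fixed = TRUE)
  stop_idx <- if (stop_at > 0L) as.integer(stop_at) else NA_integer_
  trunc_len <- if (!is.na(stop_idx)) stop_idx - 1L else nchar(mut_aa)

  present <- names(motif_layout)
  motif_len <- nchar(present)   # pattern length == motif length in residues
  motif_end <- as.integer(motif_layout) + motif_len - 1L
  if (frameshift) {
    shift_codon <- ceiling(indel$position / 3L)
    retained <- present[motif_end < shift_codon]
  } else if (indel$op == "none") {
    retained <- present
  } else {
    prot <- sub("\\*.*$", "", mut_aa)
    found <- scan_motifs(prot, unique(present))
    retained <- present[present %in% found$pattern]
  }
  new_frameshift_report(
    frameshift = frameshift,
    indel = data.frame(position = indel$position, op = indel$op,
                       sequence = indel$sequence, length = indel$length),
    premature_stop_codon_index = stop_idx,
    truncated_length = trunc_len,
    retained_motifs = retained,
    lost_motifs = setdiff(present, retained))
}
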