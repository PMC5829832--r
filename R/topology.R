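# Transmembrane topology prediction by Kyte-Doolittle hydropathy.

#' Kyte-Doolittle hydropathy scale
#'
#' The standard Kyte-Doolittle (1982) hydropathy index for the 20 amino
#' acids. The ambiguity code `X` scores 0.
#'
#' @return named numeric vector of length 21.
#' @export
kd_scale <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
    X =  0.0)
}

#' Predict transmembrane helices from sliding-window hydropathy
#'
#' Scores a protein with the Kyte-Doolittle scale averaged over a sliding
#' window, calls candidate segments from maximal runs of window centres at
#' or above `threshold`, expands each run by half a window on both sides
#' (clipped to the sequence), merges segments separated by fewer than
#' `merge_gap` residues, and discards segments shorter than `min_len`.
#'
#' @param sequence protein sequence (single string, upper case).
#' @param window odd window width in residues.
#' @param threshold mean hydropathy required to call a window centre.
#' @param min_len minimum helix length (residues) after trimming/merging.
#' @param merge_gap adjacent segments separated by fewer than this many
#'   residues are merged into one helix.
#' @param on_nonstandard `"zero"` scores residues outside the standard
#'   alphabet (plus `X`) as 0; `"error"` rejects them.
#' @return an object of class `tm_topology`: a list with `helices`
#'   (data.frame of 1-based inclusive `start`/`end` spans) and `n_helices`.
#' @examples
#' tm <- predict_tm_helices(strrep("K", 10) %+% strrep("L", 25) %+% strrep("K", 10))
#' tm$n_helices
#' @export
predict_tm_helices <- function(sequence, window = 19, threshold = 1.6,
                               min_len = 15, merge_gap = 4,
                               on_nonstandard = c("zero", "error")) {
  on_nonstandard <- match.arg(on_nonstandard)
  abort_if(length(sequence) != 1L || !is.character(sequence),
           "`sequence` must be a single string")
  abort_if(window %% 2L != 1L, "`window` must be odd")
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < window) return(new_tm_topology(integer(0), integer(0)))

  scale <- kd_scale()
  h <- scale[res]
  if (anyNA(h)) {
    bad <- unique(res[is.na(h)])
    abort_if(on_nonstandard == "error",
             "non-standard residue(s): ", paste(bad, collapse = ", "))
    h[is.na(h)] <- 0
  }
  half <- (window - 1L) %/% 2L
  # window mean centred on positions (half+1)..(n-half)
  cs <- c(0, cumsum(h))
  centres <- (half + 1L):(n - half)
  wmean <- (cs[centres + half + 1L] - cs[centres - half]) / window

  above <- wmean >= threshold
  if (!any(above)) return(new_tm_topology(integer(0), integer(0)))
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values
  seg_start <- pmax(1L, centres[starts_i[keep]] - half)
  seg_end <- pmin(n, centres[ends_i[keep]] + half)

  # merge segments separated by < merge_gap residues
  if (length(seg_start) > 1L) {
    ms <- seg_start[1]; me <- seg_end[1]
    out_s <- integer(0); out_e <- integer(0)
    for (i in seq_along(seg_start)[-1]) {
      if (seg_start[i] - me - 1L < merge_gap) {
        me <- max(me, seg_end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- seg_start[i]; me <- seg_end[i]
      }
    }
    seg_start <- c(out_s, ms); seg_end <- c(out_e, me)
  }
  long <- (seg_end - seg_start + 1L) >= min_len
  new_tm_topology(seg_start[long], seg_end[long])
}

new_tm_topology <- function(start, end) {
  structure(list(helices = data.frame(start = as.integer(start),
                                      end = as.integer(end)),
                 n_helices = length(start)),
            class = "tm_topology")
}

#' @export
print.tm_topology <- function(x, ...) {
  cat("Transmembrane topology:", x$n_helices, "helices\n")
  if (x$n_helices > 0) print(x$helices)
  invisible(x)
}

#' Paste two strings (infix convenience)
#' @param a,b character vectors.
#' @keywords internal
#' @export
`%+%` <- function(a, b) paste0(a, b)
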