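# Independent brute-force oracles used to validate the package's
# implementations. Deliberately written with different algorithms than
# the implementation code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# all-window motif scan: test every start position against the pattern
brute_motif_scan <- function(sequence, pattern) {
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(length(s) - length(p) + 1L)) {
    win <- s[i:(i + length(p) - 1L)]
    if (all(p == "X" | win == p)) hits <- c(hits, i)
  }
  hits
}

# tandem repeat scan: try every (start, unit size), count whole copies,
# keep canonical (leftmost-phase, primitive-unit) tracts meeting minima
brute_ntr_scan <- function(dna, min_copies = c(`1` = 5L, `2` = 4L, `3` = 3L)) {
  s <- strsplit(dna, "")[[1]]
  n <- length(s)
  rows <- list()
  for (u in 1:3) {
    minc <- as.integer(min_copies[as.character(u)])
    for (i in seq_len(max(0L, n - u * minc + 1L))) {
      if (i > 1L && i - 1L + u <= n && s[i - 1L] == s[i - 1L + u]) next
      unit <- paste(s[i:(i + u - 1L)], collapse = "")
      if (u == 2L && s[i] == s[i + 1L]) next
      if (u == 3L && s[i] == s[i + 1L] && s[i + 1L] == s[i + 2L]) next
      k <- 1L
      while (i + u * (k + 1L) - 1L <= n &&
             paste(s[(i + u * k):(i + u * (k + 1L) - 1L)], collapse = "") == unit)
        k <- k + 1L
      # extend by trailing partial period to match whole-copy counting
      extra <- 0L
      j <- i + u * k
      while (j <= n && s[j] == s[j - u]) { extra <- extra + 1L; j <- j + 1L }
      k <- (u * k + extra) %/% u
      if (k >= minc)
        rows[[length(rows) + 1L]] <- data.frame(unit = unit, copies = k,
                                                start = i,
                                                end = i + u * k - 1L)
    }
  }
  if (!length(rows)) return(data.frame(unit = character(0), copies = integer(0),
                                       start = integer(0), end = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, nchar(out$unit)), , drop = FALSE]
}

# per-genome Venn tally by explicit branching
brute_venn_tally <- function(mat) {
  cells <- c(none = 0L, ccoA = 0L, cbb3 = 0L, aa3 = 0L, ccoA_cbb3 = 0L,
             ccoA_aa3 = 0L, cbb3_aa3 = 0L, all = 0L)
  for (i in seq_len(nrow(mat))) {
    a <- mat$ccoA[i]; b <- mat$cbb3[i]; c <- mat$aa3[i]
    cell <- if (a && b && c) "all"
      else if (a && b) "ccoA_cbb3"
      else if (a && c) "ccoA_aa3"
      else if (b && c) "cbb3_aa3"
      else if (a) "ccoA" else if (b) "cbb3" else if (c) "aa3" else "none"
    cells[cell] <- cells[cell] + 1L
  }
  cells
}

# classic union-find for connected-component labelling
union_find_components <- function(nodes, edges_a, edges_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, "")
}

random_pa_matrix <- function(n) {
  data.frame(genome_id = sprintf("g%03d", seq_len(n)),
             ccoA = sample(c(TRUE, FALSE), n, TRUE),
             cbb3 = sample(c(TRUE, FALSE), n, TRUE),
             aa3 = sample(c(TRUE, FALSE), n, TRUE),
             ccoA_copies = 0L)
}

# minimal gene table builder for neighborhood tests
gene_table <- function(labels, genome_id = "G1", contig = "G1_c1",
                       strand = "+", len = 300L, gap = 50L) {
  n <- length(labels)
  strand <- rep_len(strand, n)
  start <- 101L + (seq_len(n) - 1L) * (len + gap)
  data.frame(genome_id = genome_id, contig = contig,
             start = start, end = start + len - 1L, strand = strand,
             locus_tag = sprintf("%s_%03d", genome_id, seq_len(n)),
             gene_label = labels)
}

# flip a contig: reverse coordinates and strands
flip_contig <- function(genes) {
  L <- max(genes$end) + 100L
  new_start <- L - genes$end + 1L
  new_end <- L - genes$start + 1L
  genes$start <- new_start
  genes$end <- new_end
  genes$strand <- ifelse(genes$strand == "+", "-", "+")
  genes
}
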