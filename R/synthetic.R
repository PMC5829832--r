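# Synthetic genomes, proteins and gene clusters with known ground truth.

MARKERS <- c("ccoA", "cbb3", "aa3")
VENN_CELLS <- c("none", "ccoA", "cbb3", "aa3",
                "ccoA_cbb3", "ccoA_aa3", "cbb3_aa3", "all")

cell_markers <- function(cell) {
  switch(cell,
         none = character(0),
         ccoA = "ccoA",
         cbb3 = "cbb3",
         aa3 = "aa3",
         ccoA_cbb3 = c("ccoA", "cbb3"),
         ccoA_aa3 = c("ccoA", "aa3"),
         cbb3_aa3 = c("cbb3", "aa3"),
         all = MARKERS)
}

#' Construct a Venn partition over the three markers
#'
#' The eight mutually exclusive presence/absence cells over
#' \{ccoA, cbb3 (ccoN), aa3 (cox1)\}.
#'
#' @param none,ccoA,cbb3,aa3,ccoA_cbb3,ccoA_aa3,cbb3_aa3,all non-negative
#'   integer cell counts. Single-marker names mean "only that marker".
#' @return named integer vector of class `venn_partition` with a `total`
#'   attribute.
#' @examples
#' venn_cells(none = 44, all = 115, cbb3_aa3 = 68, aa3 = 84,
#'            cbb3 = 6, ccoA_cbb3 = 3, ccoA_aa3 = 7)
#' @export
venn_cells <- function(none = 0, ccoA = 0, cbb3 = 0, aa3 = 0,
                       ccoA_cbb3 = 0, ccoA_aa3 = 0, cbb3_aa3 = 0, all = 0) {
  x <- c(none = none, ccoA = ccoA, cbb3 = cbb3, aa3 = aa3,
         ccoA_cbb3 = ccoA_cbb3, ccoA_aa3 = ccoA_aa3,
         cbb3_aa3 = cbb3_aa3, all = all)
  abort_if(any(is.na(x)) || any(x < 0) || any(x != round(x)),
           "all Venn cell counts must be non-negative integers")
  structure(setNames(as.integer(x), VENN_CELLS),
            total = sum(as.integer(x)), class = "venn_partition")
}

as_venn_partition <- function(x) {
  if (inherits(x, "venn_partition")) return(x)
  abort_if(is.null(names(x)) || !all(names(x) %in% VENN_CELLS),
           "partition must be named with cells: ",
           paste(VENN_CELLS, collapse = ", "))
  do.call(venn_cells, as.list(x))
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition over {ccoA, cbb3, aa3} (total ",
      attr(x, "total"), " genomes):\n", sep = "")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

# Deterministic seeded evaluation that never disturbs the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

mutate_classes <- function(res, mutable, class, rate) {
  idx <- which(mutable & stats::runif(length(res)) < rate)
  for (i in idx) {
    pool <- if (class[i] == "helix") HYDROPHOBIC else POLAR_CHARGED
    pool <- setdiff(pool, res[i])
    res[i] <- pool[sample.int(length(pool), 1L)]
  }
  res
}

#' Generate a CcoA-like protein
#'
#' Derives a homolog from the canonical reference backbone by substituting
#' a fraction of residues within their residue class (hydrophobic helix
#' residues stay hydrophobic, loop residues stay polar/charged); the
#' MXXXM/HXXXM literal positions never mutate. `truncated = TRUE` removes
#' helix 12, emulating the C-terminally truncated Rhizobiales forms.
#'
#' @param truncated drop the 12th transmembrane helix.
#' @param seed integer RNG seed; identical seeds give identical sequences.
#' @param mut_rate per-position substitution probability.
#' @return a single protein string.
#' @export
generate_ccoa_like <- function(truncated = FALSE, seed = 1, mut_rate = 0.1) {
  lay <- ref_layout()
  res <- with_seed(seed, mutate_classes(lay$residues, !lay$fixed, lay$class, mut_rate))
  if (truncated) {
    h12 <- which(lay$helix_of %in% 12L)
    res <- res[-h12]
  }
  paste(res, collapse = "")
}

#' Generate a negative decoy protein
#'
#' `"soluble"` decoys are polar/charged sequences with no Met, no His and
#' no transmembrane helix; `"membrane"` decoys carry five hydrophobic
#' helices but none of the CcoA motifs. Both must classify `negative`.
#'
#' @param seed integer RNG seed.
#' @param kind decoy class.
#' @param length soluble decoy length (residues).
#' @return a single protein string.
#' @export
generate_decoy <- function(seed = 1, kind = c("soluble", "membrane"),
                           length = 200L) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "soluble") {
      paste(sample(POLAR_CHARGED, length, replace = TRUE), collapse = "")
    } else {
      parts <- character(0)
      for (i in 1:5) {
        parts <- c(parts,
                   paste(sample(HYDROPHOBIC, REF_HELIX_LEN, TRUE), collapse = ""),
                   paste(sample(POLAR_CHARGED, REF_LOOP_LEN, TRUE), collapse = ""))
      }
      paste(parts, collapse = "")
    }
  })
}

random_soluble <- function(len) {
  paste(sample(POLAR_CHARGED, len, replace = TRUE), collapse = "")
}

# Lay out one synthetic genome: gene order, coordinates, protein sequences.
build_genome <- function(genome_id, taxonomy, markers, n_ccoA_copies,
                         clustered, truncated, include_sequences) {
  abort_if(clustered && !all(c("ccoA", "cbb3") %in% markers),
           "clustered layout requires both ccoA and cbb3 markers")
  abort_if(("ccoA" %in% markers) != (n_ccoA_copies >= 1L),
           "n_ccoA_copies must be >= 1 iff ccoA is a marker")

  labels <- c("other")
  if ("cbb3" %in% markers) labels <- c(labels, "ccoN", "ccoO", "ccoQ", "ccoP")
  if (clustered) labels <- c(labels, "ccoG", "ccoH", "ccoI", "ccoS", "ccoA")
  labels <- c(labels, "other")
  if ("aa3" %in% markers) labels <- c(labels, "cox1")
  labels <- c(labels, "other")
  n_unclustered_ccoA <- n_ccoA_copies - as.integer(clustered)
  if (n_unclustered_ccoA > 0L)
    labels <- c(labels, rep("ccoA", n_unclustered_ccoA), "other")

  n <- length(labels)
  locus <- sprintf("%s_%03d", genome_id, seq_len(n))
  is_cluster_gene <- labels %in% c("ccoN", "ccoO", "ccoQ", "ccoP",
                                   "ccoG", "ccoH", "ccoI", "ccoS")
  clustered_ccoA_idx <- if (clustered) which(labels == "ccoA")[1] else integer(0)
  strand <- ifelse(is_cluster_gene | seq_len(n) %in% clustered_ccoA_idx,
                   "+", sample(c("+", "-"), n, replace = TRUE))

  proteins <- character(n)
  ccoA_first <- TRUE
  for (i in seq_len(n)) {
    if (labels[i] == "ccoA") {
      trunc_i <- truncated && (clustered && i == clustered_ccoA_idx)
      if (!clustered && ccoA_first) { trunc_i <- truncated; ccoA_first <- FALSE }
      sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      proteins[i] <- generate_ccoa_like(truncated = trunc_i, seed = sub_seed)
    } else if (include_sequences) {
      proteins[i] <- random_soluble(60L + sample.int(40L, 1L))
    } else {
      proteins[i] <- ""
    }
  }
  lens <- ifelse(nchar(proteins) > 0, 3L * (nchar(proteins) + 1L), 300L)
  gaps <- 50L
  start <- cumsum(c(101L, head(lens + gaps, -1L)))
  genes <- data.frame(genome_id = genome_id,
                      contig = paste0(genome_id, "_c1"),
                      start = as.integer(start),
                      end = as.integer(start + lens - 1L),
                      strand = strand,
                      locus_tag = locus,
                      gene_label = labels)
  ccoA_loci <- locus[labels == "ccoA"]
  structure(list(genome_id = genome_id, taxonomy = taxonomy, genes = genes,
                 proteins = setNames(proteins, locus),
                 truth = list(markers = markers,
                              n_ccoA_copies = n_ccoA_copies,
                              clustered = clustered, truncated = truncated,
                              ccoA_loci = ccoA_loci)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Genome", x$genome_id, "(", x$taxonomy, "):", nrow(x$genes), "genes;",
      "markers:", paste(x$truth$markers, collapse = ","), "\n")
  invisible(x)
}

#' Generate a genome cohort realizing an exact Venn partition
#'
#' Emits one synthetic genome per requested Venn cell occupant, with
#' marker genes, filler genes, CcoA-like protein sequences, and (for
#' Rhizobiales-assigned genomes carrying both ccoA and cbb3) the
#' clustered ccoNOQP-ccoGHIS-ccoA layout with a C-terminally truncated
#' CcoA. Recomputing the partition from the cohort's ground truth
#' reproduces the request exactly.
#'
#' @param partition a [venn_cells()] partition (or a named vector of the
#'   eight cell counts).
#' @param taxonomy_mix named numeric vector of taxonomy label fractions
#'   (normalized internally).
#' @param seed integer RNG seed; the single source of randomness.
#' @param include_sequences generate protein sequences for filler and
#'   marker genes too (`FALSE` leaves only CcoA-like sequences, which is
#'   faster and sufficient for profiling on ground truth).
#' @return an object of class `cohort`: list of `genome_annotation`
#'   objects plus the requested partition.
#' @examples
#' coh <- generate_cohort(venn_cells(all = 2, none = 1), seed = 42)
#' length(coh$genomes)
#' @export
generate_cohort <- function(partition,
                            taxonomy_mix = c(Rhodobacterales = 0.3,
                                             Rhizobiales = 0.25,
                                             Caulobacterales = 0.15,
                                             Sphingomonadales = 0.15,
                                             Rickettsiales = 0.15),
                            seed = 1, include_sequences = TRUE) {
  partition <- as_venn_partition(partition)
  abort_if(is.null(names(taxonomy_mix)) || any(taxonomy_mix < 0) ||
             sum(taxonomy_mix) <= 0,
           "`taxonomy_mix` must be a named non-negative vector")
  prob <- taxonomy_mix / sum(taxonomy_mix)
  total <- attr(partition, "total")

  genomes <- with_seed(seed, {
    cells <- rep(names(partition), times = as.integer(partition))
    out <- vector("list", total)
    for (i in seq_len(total)) {
      markers <- cell_markers(cells[i])
      tax <- sample(names(prob), 1L, prob = prob)
      has_ccoA <- "ccoA" %in% markers
      n_copies <- if (has_ccoA) sample(1:3, 1L, prob = c(0.85, 0.10, 0.05)) else 0L
      clustered <- has_ccoA && "cbb3" %in% markers && tax == "Rhizobiales"
      truncated <- clustered
      out[[i]] <- build_genome(sprintf("G%04d", i), tax, markers, n_copies,
                               clustered, truncated, include_sequences)
    }
    out
  })
  structure(list(genomes = genomes, partition_requested = partition,
                 seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort of", length(x$genomes), "genomes (seed ",
      x$seed, ")\n")
  print(x$partition_requested)
  invisible(x)
}

#' Combined gene table of a cohort
#' @param cohort a `cohort` from [generate_cohort()].
#' @return data.frame of all gene features.
#' @export
cohort_genes <- function(cohort) {
  out <- do.call(rbind, lapply(cohort$genomes, function(g) g$genes))
  if (is.null(out)) {
    out <- data.frame(genome_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), locus_tag = character(0),
                      gene_label = character(0))
  }
  out
}

#' All protein sequences of a cohort
#' @param cohort a `cohort`.
#' @param only_nonempty drop records without a generated sequence.
#' @return data.frame with `protein_id`, `genome_id`, `sequence`.
#' @export
cohort_proteins <- function(cohort, only_nonempty = TRUE) {
  out <- do.call(rbind, lapply(cohort$genomes, function(g) {
    data.frame(protein_id = names(g$proteins), genome_id = g$genome_id,
               sequence = unname(g$proteins))
  }))
  if (is.null(out)) out <- data.frame(protein_id = character(0),
                                      genome_id = character(0),
                                      sequence = character(0))
  if (only_nonempty) out <- out[nchar(out$sequence) > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Taxonomy table of a cohort
#' @param cohort a `cohort`.
#' @return data.frame with `genome_id`, `taxonomy`.
#' @export
cohort_taxonomy <- function(cohort) {
  data.frame(genome_id = vapply(cohort$genomes, `[[`, "", "genome_id"),
             taxonomy = vapply(cohort$genomes, `[[`, "", "taxonomy"))
}

#' Ground-truth per-protein classifications of a cohort
#'
#' Emits the verdict each CcoA-like protein was generated with (truncated
#' forms as `ccoA_like_truncated`), for profiling without running the
#' classifier.
#'
#' @param cohort a `cohort`.
#' @return data.frame with `protein_id`, `genome_id`, `verdict`.
#' @export
truth_classifications <- function(cohort) {
  rows <- lapply(cohort$genomes, function(g) {
    loci <- g$truth$ccoA_loci
    if (length(loci) == 0L) return(NULL)
    lab <- g$genes$gene_label[match(loci, g$genes$locus_tag)]
    stopifnot(all(lab == "ccoA"))
    # only the clustered copy is truncated (extra copies are full-length)
    verd <- rep("ccoA_like", length(loci))
    if (g$truth$truncated) verd[1] <- "ccoA_like_truncated"
    data.frame(protein_id = loci, genome_id = g$genome_id, verdict = verd)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(protein_id = character(0),
                                      genome_id = character(0),
                                      verdict = character(0))
  out
}
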