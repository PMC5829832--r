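# Presence/absence profiling and Venn partitioning over the three markers.

#' Build the per-genome presence/absence matrix
#'
#' ccoA is present in a genome iff at least one of its proteins carries a
#' verdict of `ccoA_like` or `ccoA_like_truncated` (truncated homologs
#' count as present); cbb3 and aa3 presence come from the `ccoN` and
#' `cox1` gene labels of the annotation. The genome universe is taken
#' from the annotations.
#'
#' @param classifications data.frame with `protein_id`, `genome_id`,
#'   `verdict` (from [classify_proteins()] or [truth_classifications()]).
#' @param annotations data.frame of gene features with `genome_id` and
#'   `gene_label` (e.g. from [cohort_genes()] or [read_gff3()]).
#' @return data.frame of class `presence_absence_matrix` with one row per
#'   genome and columns `genome_id`, `ccoA`, `cbb3`, `aa3` (logical) and
#'   `ccoA_copies`.
#' @export
build_matrix <- function(classifications, annotations) {
  abort_if(!all(c("genome_id", "gene_label") %in% names(annotations)),
           "`annotations` needs genome_id and gene_label columns")
  genomes <- unique(annotations$genome_id)
  if (nrow(classifications)) {
    unknown <- setdiff(unique(classifications$genome_id), genomes)
    abort_if(length(unknown) > 0L,
             "proteins reference unknown genome_id(s): ",
             paste(unknown, collapse = ", "))
  }
  pos <- classifications[classifications$verdict %in%
                           c("ccoA_like", "ccoA_like_truncated"), , drop = FALSE]
  copies <- table(factor(pos$genome_id, levels = genomes))
  mat <- data.frame(
    genome_id = genomes,
    ccoA = as.integer(copies) > 0L,
    cbb3 = genomes %in% annotations$genome_id[annotations$gene_label == "ccoN"],
    aa3 = genomes %in% annotations$genome_id[annotations$gene_label == "cox1"],
    ccoA_copies = as.integer(copies))
  class(mat) <- c("presence_absence_matrix", "data.frame")
  mat
}

#' Compute the Venn partition of a presence/absence matrix
#'
#' Counts each genome in exactly one of the eight presence/absence cells
#' over \{ccoA, cbb3, aa3\}.
#'
#' @param matrix a `presence_absence_matrix` (or any data.frame with
#'   logical `ccoA`, `cbb3`, `aa3` columns).
#' @return a `venn_partition` (see [venn_cells()]).
#' @export
venn_partition <- function(matrix) {
  abort_if(!all(MARKERS %in% names(matrix)),
           "`matrix` needs logical ccoA, cbb3 and aa3 columns")
  key <- paste0(ifelse(matrix$ccoA, "A", "."),
                ifelse(matrix$cbb3, "B", "."),
                ifelse(matrix$aa3, "C", "."))
  map <- c("..." = "none", "A.." = "ccoA", ".B." = "cbb3", "..C" = "aa3",
           "AB." = "ccoA_cbb3", "A.C" = "ccoA_aa3", ".BC" = "cbb3_aa3",
           "ABC" = "all")
  counts <- table(factor(map[key], levels = VENN_CELLS))
  part <- do.call(venn_cells, as.list(as.integer(counts)) |>
                    setNames(VENN_CELLS))
  stopifnot(attr(part, "total") == nrow(matrix))
  part
}

#' Marginal and conditional co-occurrence summary of a Venn partition
#'
#' Reports the marker marginals, the ccoA intersections and differences,
#' and percentages with their denominators recorded beside each value.
#' Percentages are rounded half up to integers; a zero denominator gives
#' `NA` (undefined), never 0.
#'
#' @param partition a `venn_partition`.
#' @return list of class `cooccurrence_summary` with `counts` (named
#'   integers), `percentages` (data.frame with `name`, `numerator`,
#'   `denominator`, `percent`) and `total`.
#' @export
cooccurrence_summary <- function(partition) {
  p <- as_venn_partition(partition)
  total <- attr(p, "total")
  counts <- c(
    n_ccoA = p[["ccoA"]] + p[["ccoA_cbb3"]] + p[["ccoA_aa3"]] + p[["all"]],
    n_cbb3 = p[["cbb3"]] + p[["ccoA_cbb3"]] + p[["cbb3_aa3"]] + p[["all"]],
    n_aa3 = p[["aa3"]] + p[["ccoA_aa3"]] + p[["cbb3_aa3"]] + p[["all"]],
    n_ccoA_and_cbb3 = p[["ccoA_cbb3"]] + p[["all"]],
    n_ccoA_and_aa3 = p[["ccoA_aa3"]] + p[["all"]],
    n_cbb3_not_ccoA = p[["cbb3"]] + p[["cbb3_aa3"]],
    n_aa3_not_ccoA = p[["aa3"]] + p[["cbb3_aa3"]])
  pct <- function(name, num, den) {
    data.frame(name = name, numerator = num, denominator = den,
               percent = if (den > 0) round_half_up(100 * num / den)
                         else NA_real_)
  }
  percentages <- rbind(
    pct("pct_ccoA_of_total", counts[["n_ccoA"]], total),
    pct("pct_cbb3_with_ccoA", counts[["n_ccoA_and_cbb3"]], counts[["n_cbb3"]]),
    pct("pct_aa3_with_ccoA", counts[["n_ccoA_and_aa3"]], counts[["n_aa3"]]),
    pct("pct_cbb3_not_ccoA_of_total", counts[["n_cbb3_not_ccoA"]], total),
    pct("pct_aa3_not_ccoA_of_total", counts[["n_aa3_not_ccoA"]], total))
  structure(list(counts = counts, percentages = percentages, total = total),
            class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat("Co-occurrence summary over", x$total, "genomes\n")
  print(x$counts)
  print(x$percentages, row.names = FALSE)
  invisible(x)
}
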