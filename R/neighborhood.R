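# Gene-neighborhood detection: ccoA immediately downstream of the
# ccoNOQP (structural) and ccoGHIS (assembly) clusters.

CCONOQP <- c("ccoN", "ccoO", "ccoQ", "ccoP")
CCOGHIS <- c("ccoG", "ccoH", "ccoI", "ccoS")

order_genes <- function(genes) {
  abort_if(anyDuplicated(genes$locus_tag) > 0L,
           "duplicate locus_tags: ",
           paste(unique(genes$locus_tag[duplicated(genes$locus_tag)]),
                 collapse = ", "))
  genes[order(genes$contig, genes$start), , drop = FALSE]
}

#' Find gene clusters containing a required label set
#'
#' Reports maximal runs of genes on one contig that contain every
#' required label, allowing at most `max_intervening` unrelated genes
#' between consecutive members. Member order within the run is recorded
#' but not enforced.
#'
#' @param genes data.frame of gene features (`genome_id`, `contig`,
#'   `start`, `end`, `strand`, `locus_tag`, `gene_label`).
#' @param required_labels labels that must all be present in the run.
#' @param max_intervening maximum number of non-member genes tolerated
#'   between consecutive member genes.
#' @return data.frame with one row per cluster: `genome_id`, `contig`,
#'   `first_index`, `last_index` (gene indices in contig order),
#'   `members` (comma-separated locus tags), `labels`, `strands`.
#' @export
find_gene_cluster <- function(genes, required_labels,
                              max_intervening = 1L) {
  genes <- order_genes(genes)
  out <- list()
  for (ctg in unique(genes$contig)) {
    g <- genes[genes$contig == ctg, , drop = FALSE]
    member <- g$gene_label %in% required_labels
    idx <- which(member)
    if (length(idx) == 0L) next
    # group member genes into runs with <= max_intervening genes between
    grp <- cumsum(c(1L, diff(idx) - 1L > max_intervening))
    for (k in unique(grp)) {
      run <- idx[grp == k]
      if (!all(required_labels %in% g$gene_label[run])) next
      out[[length(out) + 1L]] <- data.frame(
        genome_id = g$genome_id[run[1]], contig = ctg,
        first_index = run[1], last_index = run[length(run)],
        members = paste(g$locus_tag[run], collapse = ","),
        labels = paste(g$gene_label[run], collapse = ","),
        strands = paste(g$strand[run], collapse = ","))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(genome_id = character(0), contig = character(0),
                      first_index = integer(0), last_index = integer(0),
                      members = character(0), labels = character(0),
                      strands = character(0)))
  }
  do.call(rbind, out)
}

#' Detect ccoA colocalization downstream of the cbb3-Cox gene clusters
#'
#' A hit requires, on a single contig, both the structural (ccoNOQP; ccoQ
#' optional by default) and assembly (ccoGHIS) clusters, and a ccoA gene
#' lying 3' of the combined cluster run - strand-aware "downstream"
#' relative to the cluster's majority strand - within `window` genes.
#' `gene_offset` counts intervening genes, not nucleotides.
#'
#' @param genes data.frame of gene features for one or more genomes.
#' @param window maximum number of intervening genes between the cluster
#'   edge and ccoA (default 2: "right downstream").
#' @param max_intervening spacing tolerance within clusters, see
#'   [find_gene_cluster()].
#' @param require_ccoQ require ccoQ in the structural cluster (it is a
#'   small, inconsistently annotated gene; default `FALSE`).
#' @return data.frame with one row per hit: `genome_id`, `contig`,
#'   `cluster_members`, `ccoA_locus`, `gene_offset`, `same_strand`,
#'   `mixed_strand_cluster`.
#' @export
ccoa_colocalization <- function(genes, window = 2L, max_intervening = 1L,
                                require_ccoQ = FALSE) {
  genes <- order_genes(genes)
  struct_req <- if (require_ccoQ) CCONOQP else setdiff(CCONOQP, "ccoQ")
  out <- list()
  for (ctg in unique(genes$contig)) {
    g <- genes[genes$contig == ctg, , drop = FALSE]
    sc <- find_gene_cluster(g, struct_req, max_intervening)
    ac <- find_gene_cluster(g, CCOGHIS, max_intervening)
    if (nrow(sc) == 0L || nrow(ac) == 0L) next
    # combined run over the first structural + assembly cluster pair
    lo <- min(sc$first_index[1], ac$first_index[1])
    hi <- max(sc$last_index[1], ac$last_index[1])
    run_idx <- lo:hi
    members <- run_idx[g$gene_label[run_idx] %in% c(CCONOQP, CCOGHIS)]
    strands <- g$strand[members]
    plus <- sum(strands == "+")
    majority <- if (plus * 2L >= length(strands)) "+" else "-"
    mixed <- length(unique(strands)) > 1L
    if (mixed) {
      warning("mixed-strand cluster on contig ", ctg, call. = FALSE)
    }
    cco_idx <- which(g$gene_label == "ccoA")
    if (length(cco_idx) == 0L) next
    if (majority == "+") {
      down <- cco_idx[cco_idx > hi]
      offs <- down - hi - 1L
    } else {
      down <- cco_idx[cco_idx < lo]
      offs <- lo - down - 1L
    }
    keep <- offs <= window & offs >= 0L
    for (j in which(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        genome_id = g$genome_id[1], contig = ctg,
        cluster_members = paste(g$locus_tag[members], collapse = ","),
        ccoA_locus = g$locus_tag[down[j]],
        gene_offset = offs[j],
        same_strand = g$strand[down[j]] == majority,
        mixed_strand_cluster = mixed)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(genome_id = character(0), contig = character(0),
                      cluster_members = character(0), ccoA_locus = character(0),
                      gene_offset = integer(0), same_strand = logical(0),
                      mixed_strand_cluster = logical(0)))
  }
  do.call(rbind, out)
}
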