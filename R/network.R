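# Protein similarity network: all-vs-all normalized alignment scores,
# thresholded edges, connected-component clusters.

#' All-vs-all pairwise similarity scores
#'
#' Computes the normalized global alignment score (see
#' [normalized_score()]) for every unordered pair of proteins: exactly
#' n(n-1)/2 scores, symmetric and deterministic.
#'
#' @param proteins named character vector of protein sequences, or a
#'   data.frame with `protein_id` and `sequence` columns.
#' @param gap_open,gap_extend alignment gap penalties.
#' @return data.frame with columns `a`, `b` (protein ids, a < b in input
#'   order) and `score`.
#' @export
all_vs_all_scores <- function(proteins, gap_open = 10, gap_extend = 0.5) {
  if (is.data.frame(proteins)) {
    proteins <- setNames(proteins$sequence, proteins$protein_id)
  }
  ids <- names(proteins)
  abort_if(is.null(ids) || any(ids == ""), "proteins must be named")
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0L,
           "duplicate protein ids: ", paste(dup, collapse = ", "))
  n <- length(proteins)
  abort_if(n < 2L, "need at least 2 proteins")
  selfs <- vapply(proteins, function(p) pairwise_align(p, p,
                  gap_open = gap_open, gap_extend = gap_extend)$score, 0)
  pairs <- utils::combn(n, 2L)
  score <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    pairwise_align(proteins[[i]], proteins[[j]],
                   gap_open = gap_open, gap_extend = gap_extend)$score /
      sqrt(selfs[i] * selfs[j])
  }, 0)
  data.frame(a = ids[pairs[1, ]], b = ids[pairs[2, ]], score = score)
}

#' Build a thresholded similarity network with component clusters
#'
#' Edges are exactly the pairs scoring at or above `threshold`; clusters
#' are the connected components of the resulting undirected graph.
#' Cluster ids are assigned by decreasing component size, ties broken by
#' the lexicographically smallest member id. Raising the threshold never
#' decreases the number of components.
#'
#' @param scores data.frame from [all_vs_all_scores()] (`a`, `b`,
#'   `score`), with no self-pairs.
#' @param threshold minimum score for an edge; the package's normalized
#'   analog of a database alignment-score cutoff.
#' @param nodes optional character vector of all node ids (defaults to
#'   every id appearing in `scores`); isolated proteins become singleton
#'   components.
#' @param node_attrs optional data.frame with `protein_id` plus attribute
#'   columns (e.g. `genome_id`, `taxonomy`, `ccoN_present`), joined onto
#'   the node table.
#' @return list of class `similarity_network` with `nodes` (data.frame:
#'   `protein_id`, `cluster`, attributes), `edges` (pairs >= threshold),
#'   `threshold` and `n_components`.
#' @export
build_network <- function(scores, threshold, nodes = NULL, node_attrs = NULL) {
  abort_if(!is.finite(threshold), "`threshold` must be finite")
  abort_if(any(scores$a == scores$b), "self-edges are not allowed")
  nodes <- nodes %||% unique(c(scores$a, scores$b))
  edges <- scores[scores$score >= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  member <- split(nodes, comp$membership)
  ord <- order(-vapply(member, length, 0L),
               vapply(member, function(m) min(m), ""))
  cluster_of <- integer(length(nodes))
  names(cluster_of) <- nodes
  for (r in seq_along(ord)) cluster_of[member[[ord[r]]]] <- r
  node_df <- data.frame(protein_id = nodes,
                        cluster = unname(cluster_of[nodes]))
  if (!is.null(node_attrs)) {
    node_df <- merge(node_df, node_attrs, by = "protein_id",
                     all.x = TRUE, sort = FALSE)
    node_df <- node_df[order(match(node_df$protein_id, nodes)), , drop = FALSE]
    rownames(node_df) <- NULL
  }
  structure(list(nodes = node_df, edges = edges, threshold = threshold,
                 n_components = as.integer(comp$no)),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("Similarity network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (threshold", x$threshold, "),", x$n_components, "components\n")
  invisible(x)
}
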