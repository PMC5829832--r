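# End-to-end orchestration: simulate -> classify -> profile -> neighborhood
# -> network, with a reproducible run manifest.

#' Pipeline run configuration
#'
#' Collects every tunable with its documented default plus the stage
#' toggles and the single RNG seed all randomness flows from. The
#' configuration serializes losslessly through JSON.
#'
#' @param partition Venn partition for the simulated cohort (see
#'   [venn_cells()]); may be a named vector.
#' @param seed integer RNG seed.
#' @param out_dir output directory.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "classify", "profile", "neighborhood", "network")`.
#' @param use_truth_classifications profile from generator ground truth
#'   instead of running the classifier (fast path).
#' @param window,threshold,min_len,merge_gap topology parameters.
#' @param min_similarity classification similarity threshold.
#' @param neighborhood_window gene window for [ccoa_colocalization()].
#' @param network_threshold edge threshold for [build_network()].
#' @param min_mono,min_di,min_tri tandem-repeat copy thresholds.
#' @param taxonomy_mix taxonomy label fractions for the simulator.
#' @return list of class `run_config`.
#' @export
run_config <- function(partition = venn_cells(all = 5, none = 2, cbb3_aa3 = 3),
                       seed = 1, out_dir = tempfile("ccoarun"),
                       stages = c("simulate", "classify", "profile",
                                  "neighborhood", "network"),
                       use_truth_classifications = FALSE,
                       window = 19, threshold = 1.6, min_len = 15,
                       merge_gap = 4, min_similarity = 0.3,
                       neighborhood_window = 2L, network_threshold = 0.5,
                       min_mono = 5L, min_di = 4L, min_tri = 3L,
                       taxonomy_mix = c(Rhodobacterales = 0.3,
                                        Rhizobiales = 0.25,
                                        Caulobacterales = 0.15,
                                        Sphingomonadales = 0.15,
                                        Rickettsiales = 0.15)) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(partition = as_venn_partition(partition), seed = as.integer(seed),
                 out_dir = out_dir, stages = stages,
                 use_truth_classifications = use_truth_classifications,
                 window = window, threshold = threshold, min_len = min_len,
                 merge_gap = merge_gap, min_similarity = min_similarity,
                 neighborhood_window = as.integer(neighborhood_window),
                 network_threshold = network_threshold,
                 min_mono = as.integer(min_mono), min_di = as.integer(min_di),
                 min_tri = as.integer(min_tri), taxonomy_mix = taxonomy_mix),
            class = "run_config")
}

stage_step <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the toggled stages in order on a simulated cohort, writes all
#' stage outputs under `config$out_dir`, and returns a manifest with the
#' configuration hash, input/output checksums and per-stage row counts.
#' Re-running with an identical configuration reproduces byte-identical
#' data outputs.
#'
#' @param config a [run_config()].
#' @return list of class `run_manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  abort_if(!inherits(config, "run_config"), "`config` must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  outputs <- character(0)

  cohort <- NULL
  classifications <- NULL
  genes <- NULL

  if ("simulate" %in% config$stages) {
    cohort <- stage_step("simulate",
      generate_cohort(config$partition, taxonomy_mix = config$taxonomy_mix,
                      seed = config$seed))
    paths <- write_cohort(cohort, config$out_dir)
    outputs <- c(outputs, paths)
    genes <- cohort_genes(cohort)
    counts$simulate <- length(cohort$genomes)
  }

  if ("classify" %in% config$stages) {
    abort_if(is.null(cohort), "classify requires the simulate stage")
    classifications <- stage_step("classify", {
      if (config$use_truth_classifications) {
        truth_classifications(cohort)
      } else {
        params <- classify_params(window = config$window,
                                  threshold = config$threshold,
                                  min_len = config$min_len,
                                  merge_gap = config$merge_gap,
                                  min_similarity = config$min_similarity)
        classify_proteins(cohort_proteins(cohort), params = params)
      }
    })
    p <- file.path(config$out_dir, "classifications.tsv")
    write_tsv(classifications, p)
    outputs <- c(outputs, classifications = p)
    counts$classify <- nrow(classifications)
  }

  if ("profile" %in% config$stages) {
    abort_if(is.null(classifications) || is.null(genes),
             "profile requires simulate and classify")
    res <- stage_step("profile", {
      mat <- build_matrix(classifications, genes)
      part <- venn_partition(mat)
      list(mat = mat, part = part, summary = cooccurrence_summary(part))
    })
    pm <- file.path(config$out_dir, "matrix.tsv")
    pp <- file.path(config$out_dir, "partition.tsv")
    ps <- file.path(config$out_dir, "summary.json")
    write_tsv(res$mat, pm)
    write_tsv(data.frame(cell = names(res$part),
                         count = as.integer(res$part)), pp)
    jsonlite::write_json(list(counts = as.list(res$summary$counts),
                              percentages = res$summary$percentages,
                              total = res$summary$total),
                         ps, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, matrix = pm, partition = pp, summary = ps)
    counts$profile <- nrow(res$mat)
  }

  if ("neighborhood" %in% config$stages) {
    abort_if(is.null(genes), "neighborhood requires simulate")
    hits <- stage_step("neighborhood",
      ccoa_colocalization(genes, window = config$neighborhood_window))
    p <- file.path(config$out_dir, "neighborhood.tsv")
    write_tsv(hits, p)
    outputs <- c(outputs, neighborhood = p)
    counts$neighborhood <- nrow(hits)
  }

  if ("network" %in% config$stages) {
    abort_if(is.null(cohort), "network requires simulate")
    net <- stage_step("network", {
      prot <- cohort_proteins(cohort)
      ccoa <- if (!is.null(classifications)) {
        prot[prot$protein_id %in% classifications$protein_id[
          classifications$verdict != "negative"], , drop = FALSE]
      } else prot
      if (nrow(ccoa) < 2L) NULL else {
        scores <- all_vs_all_scores(ccoa)
        tax <- cohort_taxonomy(cohort)
        attrs <- merge(ccoa[, c("protein_id", "genome_id")], tax,
                       by = "genome_id")[, c("protein_id", "genome_id",
                                             "taxonomy")]
        cbb3 <- unique(genes$genome_id[genes$gene_label == "ccoN"])
        attrs$ccoN_present <- attrs$genome_id %in% cbb3
        build_network(scores, config$network_threshold,
                      nodes = ccoa$protein_id, node_attrs = attrs)
      }
    })
    if (!is.null(net)) {
      pe <- file.path(config$out_dir, "network_edges.tsv")
      pn <- file.path(config$out_dir, "network_nodes.tsv")
      write_tsv(net$edges, pe)
      write_tsv(net$nodes, pn)
      outputs <- c(outputs, network_edges = pe, network_nodes = pn)
      counts$network <- net$n_components
    } else counts$network <- 0L
  }

  cfg <- config
  cfg$partition <- as.list(setNames(as.integer(cfg$partition),
                                    names(cfg$partition)))
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  manifest <- structure(list(
    tool_version = as.character(utils::packageVersion("ccoaprofiler")),
    config = config,
    config_hash = unname(tools::md5sum(local({
      f <- tempfile(); writeLines(as.character(cfg_json), f); f
    }))),
    output_checksums = tools::md5sum(unname(outputs)),
    stage_counts = counts,
    timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
  jsonlite::write_json(
    list(tool_version = manifest$tool_version,
         config_hash = manifest$config_hash,
         output_checksums = as.list(manifest$output_checksums),
         stage_counts = manifest$stage_counts,
         timestamp = manifest$timestamp),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (ccoaprofiler", x$tool_version, ")\n")
  cat("  stages:", paste(names(x$stage_counts), unlist(x$stage_counts),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}
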