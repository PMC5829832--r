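# File formats: FASTA (Biostrings) and GFF3 (rtracklayer), TSV and JSON.

#' Read protein or DNA FASTA
#'
#' Sequences are case-folded to upper case; duplicate record ids are an
#' error (all duplicates listed).
#'
#' @param path FASTA file path.
#' @param type `"AA"` or `"DNA"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  abort_if(!file.exists(path), "no such file: ", path)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0L,
           "duplicate FASTA ids in ", path, ": ", paste(dup, collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Coordinates are preserved 1-based inclusive; the `ID` attribute maps to
#' `locus_tag`, `gene` to `gene_label`, and the (optional) `genome`
#' attribute to `genome_id` (falling back to the part of the seqid before
#' `"_c"`).
#'
#' @param path GFF3 file path.
#' @return data.frame of gene features (`genome_id`, `contig`, `start`,
#'   `end`, `strand`, `locus_tag`, `gene_label`).
#' @export
read_gff3 <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  df <- data.frame(
    genome_id = if (!is.null(gr$genome)) as.character(gr$genome)
                else sub("_c[0-9]+$", "", as.character(GenomicRanges::seqnames(gr))),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    locus_tag = as.character(gr$ID),
    gene_label = as.character(gr$gene))
  abort_if(any(df$end < df$start), "GFF3 features with end < start in ", path)
  df
}

#' Write gene features as GFF3
#'
#' Emits one `gene` feature per row with `ID`, `gene` and `genome`
#' attributes. Volatile header comments (export date) are stripped so
#' identical inputs give byte-identical files.
#'
#' @param genes data.frame of gene features as in [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  abort_if(any(genes$end < genes$start), "gene features with end < start")
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    source = "ccoaprofiler", type = "gene",
    ID = genes$locus_tag, gene = genes$gene_label, genome = genes$genome_id)
  rtracklayer::export(gr, path, format = "gff3")
  lines <- readLines(path)
  keep <- !grepl("^##(date|source-version)", lines)
  writeLines(lines[keep], path)
  invisible(path)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Emits the cohort's protein FASTA, combined gene table (GFF3), taxonomy
#' TSV and ground-truth JSON into a directory.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.faa"),
             genes = file.path(dir, "genes.gff3"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"))
  prot <- cohort_proteins(cohort)
  write_fasta(setNames(prot$sequence, prot$protein_id), paths[["proteins"]])
  write_gff3(cohort_genes(cohort), paths[["genes"]])
  write_tsv(cohort_taxonomy(cohort), paths[["taxonomy"]])
  truth <- lapply(cohort$genomes, function(g)
    c(list(genome_id = g$genome_id, taxonomy = g$taxonomy), g$truth))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
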