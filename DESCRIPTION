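Package: ccoaprofiler
Title: Comparative Genomics of the Copper Importer CcoA and Its
    Co-Occurrence with Heme-Copper Oxidases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling the distribution of the major facilitator
    superfamily copper importer CcoA across bacterial genomes. Classifies
    candidate proteins as CcoA-like from predicted transmembrane topology
    (Kyte-Doolittle hydropathy) and conservation of the MXXXM/HXXXM copper
    ligand motifs in helices 7 and 8; builds presence/absence matrices and
    Venn partitions over the cbb3-type (ccoN) and aa3-type (cox1) oxidase
    markers; detects ccoA colocalization downstream of the ccoNOQP-ccoGHIS
    gene clusters; clusters proteins in a pairwise similarity network; and
    analyses frameshift indels in nucleotide tandem repeats of copA
    suppressor alleles, including retention of metal-binding motifs. A
    synthetic-genome generator with full ground truth supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
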