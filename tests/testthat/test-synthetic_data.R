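# Cohort, protein and copA allele generators: ground truth and determinism.

test_that("cohorts realize the requested Venn partition exactly", {
  part <- venn_cells(none = 44, all = 115, cbb3_aa3 = 68, aa3 = 84,
                     cbb3 = 6, ccoA_cbb3 = 3, ccoA_aa3 = 7)
  coh <- generate_cohort(part, seed = 1, include_sequences = FALSE)
  expect_equal(length(coh$genomes), 327L)
  ids <- vapply(coh$genomes, `[[`, "", "genome_id")
  expect_false(anyDuplicated(ids) > 0)

  recomputed <- venn_partition(build_matrix(truth_classifications(coh),
                                            cohort_genes(coh)))
  expect_equal(as.integer(recomputed), as.integer(part))
})

test_that("an all-zero partition gives an empty cohort", {
  coh <- generate_cohort(venn_cells(), seed = 1)
  expect_equal(length(coh$genomes), 0L)
  expect_error(venn_cells(none = -1), "non-negative")
})

test_that("random partitions are recovered from their cohorts", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      counts <- as.integer(stats::rmultinom(1, 50, rep(1 / 8, 8)))
      part <- do.call(venn_cells, setNames(as.list(counts),
                                           names(venn_cells())))
      coh <- generate_cohort(part, seed = rep, include_sequences = FALSE)
      got <- venn_partition(build_matrix(truth_classifications(coh),
                                         cohort_genes(coh)))
      expect_equal(as.integer(got), as.integer(part))
    }
  })
})

test_that("generation is deterministic: same seed, byte-identical files", {
  part <- venn_cells(all = 3, ccoA_cbb3 = 2, none = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(generate_cohort(part, seed = 5), d1)
  p2 <- write_cohort(generate_cohort(part, seed = 5), d2)
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
                     readBin(p2[[k]], "raw", file.size(p2[[k]])),
                     label = k)
  }
  # different seed changes the sequences
  coh3 <- generate_cohort(part, seed = 6)
  expect_false(identical(cohort_proteins(generate_cohort(part, seed = 5)),
                         cohort_proteins(coh3)))
})

test_that("ccoA-like generation is seed-deterministic and motif-safe", {
  expect_identical(generate_ccoa_like(seed = 123), generate_ccoa_like(seed = 123))
  expect_false(identical(generate_ccoa_like(seed = 123),
                         generate_ccoa_like(seed = 124)))
  p <- generate_ccoa_like(seed = 77)
  expect_equal(nrow(scan_motifs(p, "MXXXM")), 1L)
  expect_equal(nrow(scan_motifs(p, "HXXXM")), 1L)
})

test_that("clustered genomes carry the Rhizobiales-style layout", {
  part <- venn_cells(ccoA_cbb3 = 6, all = 6)
  coh <- generate_cohort(part, taxonomy_mix = c(Rhizobiales = 1), seed = 3,
                         include_sequences = FALSE)
  g <- coh$genomes[[1]]
  expect_true(g$truth$clustered)
  lab <- g$genes$gene_label
  cl <- which(lab %in% c("ccoN", "ccoO", "ccoQ", "ccoP",
                         "ccoG", "ccoH", "ccoI", "ccoS", "ccoA"))
  # contiguous cluster with ccoA last
  expect_equal(lab[cl[1]:(cl[1] + 8L)],
               c("ccoN", "ccoO", "ccoQ", "ccoP", "ccoG", "ccoH", "ccoI",
                 "ccoS", "ccoA"))
  # truncated clustered ccoA classifies as present
  tc <- truth_classifications(coh)
  expect_true(all(tc$verdict[tc$genome_id == g$genome_id][1] ==
                    "ccoA_like_truncated"))
})

test_that("copA alleles embed their tract and metal-binding motifs", {
  spec <- copa_spec(tract_unit = "C", tract_copies = 10,
                    indel = list(op = "ins", sequence = "C"))
  al <- generate_copa(spec)
  # wild-type translates without internal stop
  aa <- Biostrings::translate(Biostrings::DNAString(al$wt_cds))
  expect_false(grepl("*", as.character(aa), fixed = TRUE))
  # the embedded tract is recovered exactly by the scanner
  tr <- scan_ntr(al$wt_cds)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$unit, "C")
  expect_equal(tr$copies, 10L)
  expect_equal(tr$start, al$tract$start)
  # motifs present in the encoded protein at their laid-out positions
  found <- scan_motifs(as.character(aa), c("CXXC", "DKTGT", "CPC"))
  for (m in c("CXXC", "DKTGT", "CPC")) {
    expect_true(spec$motif_layout[[m]] %in% found$position[found$pattern == m])
  }
  expect_true(al$truth$frameshift)
})

test_that("copA ground truth distinguishes frameshift from in-frame indels", {
  ins1 <- generate_copa(copa_spec(tract_unit = "C", tract_copies = 10,
                                  indel = list(op = "ins", sequence = "C")))
  expect_true(ins1$truth$frameshift)
  expect_equal(ins1$truth$retained_motifs, "CXXC")
  expect_setequal(ins1$truth$lost_motifs, c("DKTGT", "CPC"))

  del2 <- generate_copa(copa_spec(indel = list(op = "del", sequence = "CG")))
  expect_true(del2$truth$frameshift)
  expect_equal(nchar(del2$wt_cds) - nchar(del2$mut_cds), 2L)

  none <- generate_copa(copa_spec())
  expect_identical(none$wt_cds, none$mut_cds)
  expect_null(none$truth)

  inframe <- generate_copa(copa_spec(tract_unit = "ACT", tract_copies = 4,
                                     indel = list(op = "del", sequence = "ACT")))
  expect_false(inframe$truth$frameshift)
  expect_setequal(inframe$truth$retained_motifs, c("CXXC", "DKTGT", "CPC"))
})

test_that("copA spec validation rejects inconsistent layouts", {
  expect_error(copa_spec(tract_unit = "CGCG"), "1-3 bases")
  expect_error(copa_spec(tract_unit = "AA"), "primitive")
  expect_error(copa_spec(tract_copies = 3), ">= 4")
  expect_error(copa_spec(motif_layout = c(CXXC = 90, DKTGT = 150, CPC = 220)),
               "before the tract")
  expect_error(generate_copa(copa_spec(indel = list(op = "ins", sequence = "C",
                                                    position = 10L))),
               "inside the repeat tract")
})

test_that("classifier round-trip holds across many generator seeds", {
  withr::with_seed(11, seeds <- sample.int(1e6, 40))
  for (s in seeds) {
    trunc <- s %% 2L == 0L
    verdict <- classify_ccoa(generate_ccoa_like(truncated = trunc, seed = s))$verdict
    expect_equal(verdict, if (trunc) "ccoA_like_truncated" else "ccoA_like")
  }
  for (s in seeds[1:10]) {
    kind <- if (s %% 2L == 0L) "soluble" else "membrane"
    expect_equal(classify_ccoa(generate_decoy(s, kind))$verdict, "negative")
  }
})
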