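# Tandem repeat scanning, indel localization, frameshift consequences.

test_that("scanner finds the canonical suppressor-class tracts", {
  tr <- scan_ntr(paste0("AAT", strrep("C", 10), "GGA"))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$unit, "C"); expect_equal(tr$copies, 10L)
  expect_equal(tr$start, 4L); expect_equal(tr$end, 13L)

  tr <- scan_ntr(paste0("AT", strrep("CG", 5), "AT"))
  expect_equal(tr$unit, "CG"); expect_equal(tr$copies, 5L)

  # primitive unit rule: never CGCG
  tr <- scan_ntr("CGCGCG", min_copies = c(`1` = 5, `2` = 2, `3` = 2))
  expect_equal(tr$unit, "CG")
  expect_equal(tr$copies, 3L)
})

test_that("scanner equals the brute-force scanner on random sequences", {
  withr::with_seed(77, {
    for (i in 1:300) {
      dna <- random_dna(sample(30:400, 1))
      got <- scan_ntr(dna)
      exp <- brute_ntr_scan(dna)
      expect_equal(got[c("unit", "copies", "start", "end")],
                   exp[c("unit", "copies", "start", "end")],
                   ignore_attr = TRUE, label = paste("seq", i))
    }
  })
})

test_that("ambiguity codes break tracts and can be rejected", {
  expect_warning(tr <- scan_ntr(paste0(strrep("C", 5), "N", strrep("C", 5))),
                 "non-ACGT")
  expect_equal(tr$copies, c(5L, 5L))
  expect_error(scan_ntr("CCCCCN", on_ambiguous = "error"), "non-ACGT")
})

test_that("indel localization is leftmost and tract-annotated", {
  ref <- paste0("AAT", strrep("C", 10), "GGATTC")
  ins <- paste0("AAT", strrep("C", 11), "GGATTC")
  call <- locate_indel(ref, ins)
  expect_equal(call$op, "ins")
  expect_equal(call$sequence, "C")
  expect_equal(call$position, 4L)          # leftmost: start of the tract
  expect_equal(call$in_tract$unit, "C")

  ref2 <- paste0("AT", strrep("CG", 5), "ATGG")
  del <- paste0("AT", strrep("CG", 4), "ATGG")
  call2 <- locate_indel(ref2, del)
  expect_equal(call2$op, "del")
  expect_equal(call2$sequence, "CG")
  expect_equal(call2$length, 2L)
  expect_equal(call2$position, 3L)
  expect_equal(call2$in_tract$copies, 5L)

  same <- locate_indel(ref, ref)
  expect_equal(same$op, "none")

  expect_error(locate_indel("AAACCC", "AAAGGG"), "indel")
  expect_error(locate_indel("AACCAATT", "AAGGCCAAGGTT"), "contiguous")
})

test_that("locate/apply round-trips on random tract indels", {
  withr::with_seed(88, {
    for (i in 1:50) {
      u <- sample(c("C", "CG", "ACT"), 1)
      copies <- sample(4:9, 1)
      flank1 <- random_dna(sample(5:30, 1))
      flank2 <- random_dna(sample(5:30, 1))
      ref <- paste0(flank1, strrep(u, copies), flank2)
      op <- sample(c("ins", "del"), 1)
      mut <- if (op == "ins") {
        paste0(flank1, strrep(u, copies + 1L), flank2)
      } else {
        paste0(flank1, strrep(u, copies - 1L), flank2)
      }
      call <- locate_indel(ref, mut)
      expect_identical(apply_indel(ref, call), mut, label = paste(u, op, i))
      expect_equal(call$length, nchar(u))
      expect_equal(call$op, op)
    }
  })
})

test_that("frameshift flag always equals length mod 3", {
  withr::with_seed(99, {
    for (len in 1:6) {
      al <- generate_copa(copa_spec(tract_unit = "C", tract_copies = 10,
                                    indel = list(op = "ins",
                                                 sequence = strrep("C", len))))
      call <- locate_indel(al$wt_cds, al$mut_cds)
      rep_ <- frameshift_consequence(al$wt_cds, call,
                                     motif_layout = c(CXXC = 15L, DKTGT = 150L,
                                                      CPC = 220L))
      expect_equal(rep_$frameshift, len %% 3L != 0L, label = paste("len", len))
    }
  })
})

test_that("in-frame single-codon deletion shortens the protein by one", {
  al <- generate_copa(copa_spec(tract_unit = "ACT", tract_copies = 4,
                                indel = list(op = "del", sequence = "ACT")))
  call <- locate_indel(al$wt_cds, al$mut_cds)
  rep_ <- frameshift_consequence(al$wt_cds, call)
  expect_false(rep_$frameshift)
  wt_len <- nchar(al$wt_cds) / 3
  expect_equal(rep_$truncated_length, wt_len - 1L)
  expect_setequal(rep_$retained_motifs, c("CXXC", "DKTGT", "CPC"))
})

test_that("premature stop matches an independent translate-and-scan oracle", {
  al <- generate_copa(copa_spec(tract_unit = "C", tract_copies = 10,
                                indel = list(op = "ins", sequence = "C")))
  call <- locate_indel(al$wt_cds, al$mut_cds)
  rep_ <- frameshift_consequence(al$wt_cds, call)
  # oracle: translate codon by codon with Biostrings' genetic code
  mut <- apply_indel(al$wt_cds, call)
  codons <- substring(mut, seq(1, nchar(mut) - 2, 3), seq(3, nchar(mut), 3))
  aas <- Biostrings::GENETIC_CODE[codons]
  first_stop <- which(aas == "*")[1]
  expect_equal(rep_$premature_stop_codon_index, as.integer(first_stop))
  expect_equal(rep_$truncated_length, as.integer(first_stop) - 1L)
})

test_that("suppressor fixtures retain the MBD and lose DKTGT/CPC", {
  capsulatus <- generate_copa(copa_spec(tract_unit = "C", tract_copies = 10,
                                        indel = list(op = "ins", sequence = "C")))
  sphaeroides <- generate_copa(copa_spec(tract_unit = "CG", tract_copies = 5,
                                         indel = list(op = "del", sequence = "CG")))
  for (al in list(capsulatus, sphaeroides)) {
    call <- locate_indel(al$wt_cds, al$mut_cds)
    expect_false(is.null(call$in_tract))
    rep_ <- frameshift_consequence(al$wt_cds, call)
    expect_true(rep_$frameshift)
    expect_equal(rep_$retained_motifs, "CXXC")
    expect_setequal(rep_$lost_motifs, c("DKTGT", "CPC"))
    # computed report agrees with generator ground truth
    expect_equal(rep_$frameshift, al$truth$frameshift)
    expect_equal(rep_$retained_motifs, al$truth$retained_motifs)
    expect_equal(rep_$premature_stop_codon_index,
                 al$truth$premature_stop_codon_index)
  }
})
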