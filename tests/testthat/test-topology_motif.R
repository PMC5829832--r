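# Topology prediction, motif scanning, alignment and classification.

test_that("hydropathy caller finds single hydrophobic segments and nothing else", {
  tm <- predict_tm_helices(paste0(strrep("K", 10), strrep("L", 25), strrep("K", 10)))
  expect_equal(tm$n_helices, 1L)
  # the called helix covers the Leu block
  expect_lte(tm$helices$start, 11L)
  expect_gte(tm$helices$end, 35L)

  expect_equal(predict_tm_helices(strrep("D", 50))$n_helices, 0L)
  # shorter than the window: empty model
  expect_equal(predict_tm_helices("LLLLL")$n_helices, 0L)
})

test_that("generated CcoA-like proteins have the planted helix counts", {
  for (s in c(1, 2, 3, 10)) {
    expect_equal(predict_tm_helices(generate_ccoa_like(seed = s))$n_helices, 12L)
    expect_equal(predict_tm_helices(generate_ccoa_like(TRUE, seed = s))$n_helices, 11L)
  }
})

test_that("helix spans never overlap and concatenation adds helix counts", {
  withr::with_seed(99, {
    for (i in 1:10) {
      p <- generate_ccoa_like(seed = sample.int(1e6, 1))
      tm <- predict_tm_helices(p)
      h <- tm$helices
      expect_true(all(diff(h$start) > 0))
      expect_true(all(h$start[-1] > h$end[-nrow(h)]))
      # charged linker between two proteins: union of helix counts
      q <- generate_decoy(sample.int(1e6, 1), "membrane")
      joined <- paste0(p, strrep("K", 30), q)
      expect_equal(predict_tm_helices(joined)$n_helices,
                   tm$n_helices + predict_tm_helices(q)$n_helices)
    }
  })
})

test_that("non-standard residues are configurable", {
  seq <- paste0(strrep("K", 10), strrep("L", 10), "B", strrep("L", 14), strrep("K", 10))
  expect_error(predict_tm_helices(seq, on_nonstandard = "error"), "non-standard")
  expect_silent(predict_tm_helices(seq))
})

test_that("motif scan reports all and only matching windows", {
  hits <- scan_motifs("AAMGGGMAA", "MXXXM")
  expect_equal(hits$position, 3L)
  expect_equal(hits$matched, "MGGGM")

  hits <- scan_motifs("MAAAMAAAM", "MXXXM")
  expect_equal(hits$position, c(1L, 5L))      # overlapping matches reported

  hits <- scan_motifs("HKLGM", "HXXXM")
  expect_equal(hits$position, 1L)

  # ambiguity code X never satisfies a literal pattern position
  expect_equal(nrow(scan_motifs("XAAAM", "MXXXM")), 0L)
  expect_equal(scan_motifs("MXXXM", "MXXXM")$position, 1L)  # X matches wildcards
})

test_that("motif scan equals the brute-force window scan on random proteins", {
  patterns <- c("MXXXM", "HXXXM", "CXXC", "DKTGT", "CPC")
  withr::with_seed(42, {
    for (i in 1:200) {
      s <- random_protein(sample(20:120, 1))
      for (p in patterns) {
        expect_identical(scan_motifs(s, p)$position, brute_motif_scan(s, p),
                         label = paste("seq", i, "pattern", p))
      }
    }
  })
})

test_that("motif-helix assignment requires the full match inside the span", {
  topo <- predict_tm_helices(paste0(strrep("K", 10), strrep("L", 25), strrep("K", 10)))
  hits <- data.frame(pattern = "MXXXM", position = 20L, matched = "LLLLL",
                     helix_index = NA_integer_)
  expect_equal(assign_helix_index(hits, topo)$helix_index, 1L)
  out <- assign_helix_index(transform(hits, position = 2L), topo)
  expect_true(is.na(out$helix_index))
})

test_that("global alignment percentages follow the column-count definition", {
  a <- strrep("MKLIVFDERS", 10)   # 100 residues
  self <- pairwise_align(a, a)
  expect_equal(self$identity, 100)
  expect_equal(self$similarity, 100)

  # one substitution to a positive-scoring partner (L -> I scores +2)
  b <- sub("L", "I", a)
  one <- pairwise_align(a, b)
  expect_equal(one$columns, 100L)
  expect_equal(one$identity, 99)
  expect_equal(one$similarity, 100)

  pal <- pairwise_align("AAAA", "AAAA")
  expect_equal(pal$identity, 100)

  # symmetry in (a, b)
  x <- generate_ccoa_like(seed = 5); y <- generate_ccoa_like(seed = 6)
  expect_equal(pairwise_align(x, y)$score, pairwise_align(y, x)$score)
  expect_error(pairwise_align("", "AAA"), "non-empty")
})

test_that("classification round-trips generator ground truth", {
  expect_equal(classify_ccoa(generate_ccoa_like(seed = 21))$verdict, "ccoA_like")
  expect_equal(classify_ccoa(generate_ccoa_like(TRUE, seed = 21))$verdict,
               "ccoA_like_truncated")

  # soluble 200-mer with no Met
  dec <- classify_ccoa(generate_decoy(8, "soluble"))
  expect_equal(dec$verdict, "negative")
  expect_true("missing_MXXXM_helix7" %in% dec$reasons)

  mem <- classify_ccoa(generate_decoy(8, "membrane"))
  expect_equal(mem$verdict, "negative")
  expect_true(length(mem$reasons) > 0)
})

test_that("classification ignores appended charged C-terminal tails", {
  p <- generate_ccoa_like(seed = 31)
  expect_equal(classify_ccoa(paste0(p, strrep("KDRE", 15)))$verdict, "ccoA_like")
})

test_that("batch classification emits one row per protein with evidence", {
  prot <- data.frame(protein_id = c("p1", "p2"), genome_id = c("G1", "G1"),
                     sequence = c(generate_ccoa_like(seed = 1),
                                  generate_decoy(1)))
  tab <- classify_proteins(prot)
  expect_equal(tab$verdict, c("ccoA_like", "negative"))
  expect_equal(tab$n_helices[1], 12L)
  expect_false(is.na(tab$mxxxm_helix7[1]))
})
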