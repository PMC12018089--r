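test_that("dinucleotide steps score +17 for CpG and -1 otherwise", {
  expect_equal(dinucleotide_score_steps("ACGT"), c(-1, 17, -1))
  expect_equal(dinucleotide_score_steps("CGCG"), c(17, -1, 17))  # middle is GC
  expect_equal(dinucleotide_score_steps("AAAA"), c(-1, -1, -1))
  expect_equal(dinucleotide_score_steps("A"), numeric(0))
  # the step scores are parameters, not constants
  expect_equal(dinucleotide_score_steps("ACGT", cpg_params(cpg_step_score = 9)),
               c(-1, 9, -1))
})

test_that("the running sum after one CpG needs exactly 17 decrements to close", {
  steps <- dinucleotide_score_steps(paste0("CG", strrep("A", 30)))
  rs <- cumsum(steps)
  first_zero <- which(rs == 0)[1]
  expect_equal(sum(steps[seq_len(first_zero)] < 0), 17L)
  # hence the closed span is 2 + 17 = 19 bp, below the length threshold
  expect_equal(first_zero + 1L, 19L)
  expect_equal(nrow(find_cpg_islands(paste0("CG", strrep("A", 30)))), 0L)
})

test_that("island metrics follow the observed/expected CpG definition", {
  m <- island_metrics("CGCGCG", 1, 6)
  expect_equal(m$gc_percent, 100)
  expect_equal(m$obs_exp_ratio, 3 * 6 / (3 * 3))
  m2 <- island_metrics("GCGC", 1, 4)
  expect_equal(m2$obs_exp_ratio, 1 * 4 / (2 * 2))
  m3 <- island_metrics("ATAT", 1, 4)
  expect_equal(m3$gc_percent, 0)
  expect_equal(m3$obs_exp_ratio, 0)  # degenerate guard
})

test_that("a dense alternating-CG sequence is one full-span island", {
  isl <- find_cpg_islands(strrep("CG", 125))
  expect_equal(nrow(isl), 1L)
  expect_equal(c(isl$start, isl$end), c(1L, 250L))
  expect_equal(isl$gc_percent, 100)
  expect_equal(isl$obs_exp_ratio, 2)
})

test_that("poly-A yields no island and reported islands satisfy all criteria", {
  expect_equal(nrow(find_cpg_islands(strrep("A", 500))), 0L)
  set.seed(8)
  p <- cpg_params()
  for (rep in 1:10) {
    dna <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE,
                        prob = c(.2, .3, .3, .2)), collapse = "")
    isl <- find_cpg_islands(dna, p)
    if (!nrow(isl)) next
    # soundness: re-verify each report independently
    for (i in seq_len(nrow(isl))) {
      m <- island_metrics(dna, isl$start[i], isl$end[i])
      expect_gt(isl$length_bp[i], p$min_length_bp)
      expect_gt(m$gc_percent, p$min_gc_percent)
      expect_gt(m$obs_exp_ratio, p$min_obs_exp)
      expect_equal(m$gc_percent, isl$gc_percent[i])
      expect_equal(m$obs_exp_ratio, isl$obs_exp_ratio[i])
    }
    # non-overlapping, sorted
    if (nrow(isl) > 1) {
      expect_true(all(diff(isl$start) > 0))
      expect_true(all(isl$start[-1] > isl$end[-nrow(isl)]))
    }
  }
})

test_that("TTS-island annotation reports overlap or signed nearest distance", {
  islands <- data.frame(start = c(90L, 500L), end = c(400L, 800L),
                        length_bp = c(311L, 301L), gc_percent = 60,
                        obs_exp_ratio = 0.8)
  hits <- data.frame(tts_start = c(100L, 10L, 950L), tts_end = c(120L, 30L, 990L))
  ann <- annotate_tts_islands(hits, islands[1, ])
  expect_identical(ann$cpg_island[1], "90-400")
  expect_equal(ann$cpg_distance_bp[1], 0L)
  ann2 <- annotate_tts_islands(hits, islands[2, ])
  expect_equal(ann2$cpg_distance_bp[2], 470L)      # island downstream: positive
  expect_equal(ann2$cpg_distance_bp[3], -150L)     # island upstream: negative
  ann3 <- annotate_tts_islands(hits, islands[0, ])
  expect_identical(ann3$cpg_island, rep(".", 3))
  expect_true(all(is.na(ann3$cpg_distance_bp)))
})
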