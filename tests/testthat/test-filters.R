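test_that("end trimming strips unmatched termini and shifts intervals", {
  # leading mismatch removed, offsets advanced by one
  tr <- trim_to_matched_ends(mk_cand("011111111", tts_start0 = 10, tfo_start0 = 20,
                                     tts_seq = "GAAAAAAAA", tfo_seq = "AUUUUUUUU"))
  expect_equal(tr$length, 8L)
  expect_equal(c(tr$tts_start0, tr$tts_end0), c(11L, 19L))
  expect_equal(c(tr$tfo_start0, tr$tfo_end0), c(21L, 29L))
  expect_identical(tr$mask, "11111111")
  expect_identical(tr$tts_seq, "AAAAAAAA")
  expect_identical(tr$tfo_seq, "UUUUUUUU")

  # all matched: identity
  c2 <- mk_cand(strrep("1", 9))
  expect_identical(trim_to_matched_ends(c2), c2)

  # zeros stripped from both ends
  tr3 <- trim_to_matched_ends(mk_cand("00110", tts_start0 = 0, tfo_start0 = 0))
  expect_identical(tr3$mask, "11")
  expect_equal(c(tr3$tts_start0, tr3$tts_end0), c(2L, 4L))
  expect_equal(tr3$mismatches, 0L)

  # an all-mismatch candidate disappears
  expect_equal(nrow(trim_to_matched_ends(mk_cand("000"))), 0L)
})

test_that("trimming respects strand and orientation coordinate conventions", {
  # minus strand, parallel: alignment-left trim removes the highest plus coords
  m <- trim_to_matched_ends(mk_cand("0111", tts_start0 = 100, tfo_start0 = 5,
                                    strand = "-", tts_seq = "GAAA", tfo_seq = "AUUU"))
  expect_equal(c(m$tts_start0, m$tts_end0), c(100L, 103L))
  expect_equal(c(m$tfo_start0, m$tfo_end0), c(6L, 9L))
  # plus strand, antiparallel: TFO trim mirrored on the RNA
  a <- trim_to_matched_ends(mk_cand("0111", tts_start0 = 100, tfo_start0 = 5,
                                    frame = "ANTIPARALLEL_MIXED",
                                    tts_seq = "GAAA", tfo_seq = "UUUA"))
  expect_equal(c(a$tts_start0, a$tts_end0), c(101L, 104L))
  expect_equal(c(a$tfo_start0, a$tfo_end0), c(5L, 8L))
  expect_identical(a$tfo_seq, "UUU")
})

test_that("the seven-consecutive-match core requirement is exact", {
  expect_false(passes_core_run(mk_cand("1111110111111")))  # runs of 6 and 6
  expect_true(passes_core_run(mk_cand("11111110111")))     # run of 7
  expect_true(passes_core_run(mk_cand("1111111")))         # boundary
  expect_equal(passes_core_run(rbind(mk_cand("1111111"), mk_cand("110111"))),
               c(TRUE, FALSE))
})

test_that("region selection keeps the longest at equal error, plus lower-error shorter ones", {
  long12 <- mk_cand("111101111111", tts_start0 = 0, tfo_start0 = 0)   # 1/12
  short10_same_err <- mk_cand("1110111111", tts_start0 = 1, tfo_start0 = 1)  # 1/10 > 1/12
  kept <- select_by_region(rbind(long12, short10_same_err))
  expect_equal(kept$length, 12L)

  short10_better <- mk_cand("1111111111", tts_start0 = 1, tfo_start0 = 1)  # err 0
  kept2 <- select_by_region(rbind(long12, short10_better))
  expect_setequal(kept2$length, c(12L, 10L))

  # equal error rates, equal length: both stand (rule 5 territory)
  a <- mk_cand("11111111", tts_start0 = 0, tfo_start0 = 0)
  b <- mk_cand("11111111", tts_start0 = 2, tfo_start0 = 2)
  expect_equal(nrow(select_by_region(rbind(a, b))), 2L)
})

test_that("identical sequences at distinct positions are all preserved", {
  a <- mk_cand(strrep("1", 8), tts_start0 = 0, tfo_start0 = 0,
               tts_seq = "AGAGAGAG", tfo_seq = "UCUCUCUC")
  b <- mk_cand(strrep("1", 8), tts_start0 = 50, tfo_start0 = 0,
               tts_seq = "AGAGAGAG", tfo_seq = "UCUCUCUC")
  out <- apply_candidate_filters(rbind(a, b), search_params())
  expect_equal(nrow(out), 2L)
  expect_setequal(out$tts_start0, c(0L, 50L))
})

test_that("sliding ties resolve to the central placement(s)", {
  # TTS run of 10 vs TFO of 7 (mixed parity): 4 offsets -> the 2 central kept
  cands <- do.call(rbind, lapply(0:3, function(o) {
    mk_cand(strrep("1", 7), tts_start0 = o, tfo_start0 = 0)
  }))
  kept <- resolve_slide_ties(cands)
  expect_setequal(kept$tts_start0, c(1L, 2L))

  # TTS run of 9 vs TFO of 7 (odd/odd): 3 offsets -> 1 central kept
  cands2 <- do.call(rbind, lapply(0:2, function(o) {
    mk_cand(strrep("1", 7), tts_start0 = o, tfo_start0 = 0)
  }))
  kept2 <- resolve_slide_ties(cands2)
  expect_equal(kept2$tts_start0, 1L)

  # a single candidate is untouched
  one <- mk_cand(strrep("1", 7), tts_start0 = 5, tfo_start0 = 3)
  expect_identical(resolve_slide_ties(one), one)
})

test_that("slide ties resolve within the full search on a homopolymer repeat", {
  dna <- paste0("CTCTCT", strrep("A", 10), "TCTCT")
  h <- search_triplexes(dna, "UUUUUUU")
  pp <- h[h$frame == "PARALLEL_PYRIMIDINE", ]
  expect_equal(nrow(pp), 2L)
  expect_setequal(pp$tts_start, c(8L, 9L))  # central two of four placements
})

test_that("the filter chain is idempotent, order-independent, and sound", {
  set.seed(99)
  p <- search_params()
  sorted <- function(df) {
    df <- df[do.call(order, unname(as.list(df[, c("frame", "strand", "tts_start0",
                                                  "tfo_start0", "length")]))), ]
    rownames(df) <- NULL
    df
  }
  for (rep in 1:15) {
    g <- gen_noisy_instance()
    tracts <- find_purine_tracts(g$dna, 7)
    if (!nrow(tracts)) next
    raw <- do.call(rbind, unlist(lapply(seq_len(nrow(tracts)), function(i) {
      lapply(TRIPLEX_FRAMES, function(f) scan_pair(tracts[i, ], g$rna, f, p))
    }), recursive = FALSE))
    once <- apply_candidate_filters(raw, p)
    twice <- apply_candidate_filters(once, p)
    expect_identical(sorted(twice), sorted(once))
    shuffled <- raw[sample(nrow(raw)), , drop = FALSE]
    expect_identical(sorted(apply_candidate_filters(shuffled, p)), sorted(once))
    if (nrow(once)) {
      expect_true(all(startsWith(once$mask, "1") & endsWith(once$mask, "1")))
      expect_true(all(passes_core_run(once, 7)))
      expect_true(all(once$length >= 7))
      expect_true(all(once$mismatches <= 0.2 * once$length + 1e-9))
      expect_lte(nrow(once), nrow(raw))
    }
  }
})
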