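test_that("the canonical perfect duplex/RNA pair yields the full-length hit", {
  h <- search_triplexes("GGAAGGAAGGAA", "CCUUCCUUCCUU",
                        search_params(max_error_rate = 0))
  expect_gte(nrow(h), 1L)
  top <- h[1, ]
  expect_equal(c(top$tts_start, top$tts_end), c(1L, 12L))
  expect_identical(top$tts_strand, "+")
  expect_equal(c(top$tfo_start, top$tfo_end), c(1L, 12L))
  expect_equal(top$length, 12L)
  expect_equal(top$error_rate_pct, 0)
  expect_equal(top$gu_pct, 50)
  expect_identical(top$frame, "PARALLEL_PYRIMIDINE")
})

test_that("code-incompatible and too-short inputs give empty results", {
  # minus-strand purine tract is all G, but G:U is no canonical code
  expect_equal(nrow(search_triplexes("CCCCCCCCCCCC", "UUUUUUUUUUUU")), 0L)
  expect_equal(nrow(search_triplexes("GGAAGG", "CCUUCC")), 0L)   # dna < 7
  expect_equal(nrow(search_triplexes("GGAAGGAAGGAA", "CCUUCC")), 0L)
})

test_that("a bridged mismatch hit coexists with its shorter error-free runs", {
  h <- search_triplexes("GGAAGGAAGGAA", "CCUUCCUACCUU",
                        search_params(max_error_rate = 0.10))
  expect_true(any(h$length == 12 & abs(h$error_rate_pct - 100 / 12) < 1e-9))
  expect_true(any(h$length == 7 & h$error_rate_pct == 0 &
                    h$tts_start == 1 & h$tfo_start == 1))
})

test_that("every reported hit satisfies the validity contract", {
  set.seed(2024)
  p <- search_params()
  for (rep in 1:40) {
    g <- gen_noisy_instance()
    h <- search_triplexes(g$dna, g$rna, p)
    if (!nrow(h)) next
    expect_true(all(grepl("^[AG]+$", h$tts_seq)))
    expect_true(all(startsWith(h$mask, "1") & endsWith(h$mask, "1")))
    runs <- vapply(h$mask, function(mk) {
      m <- gregexpr("1+", mk)[[1]]
      max(attr(m, "match.length"))
    }, integer(1))
    expect_true(all(runs >= 7))
    expect_true(all(h$length >= p$min_consecutive))
    expect_true(all(h$mismatches <= p$max_error_rate * h$length + 1e-9))
    expect_true(all(h$error_rate_pct <= 100 * p$max_error_rate + 1e-6))
    expect_true(all(h$gu_pct >= 0 & h$gu_pct <= 100))
    expect_true(all(h$tts_end - h$tts_start + 1 == h$length))
    expect_true(all(h$tfo_end - h$tfo_start + 1 == h$length))
  }
})

test_that("results are sorted by length, then error, then position", {
  set.seed(5)
  for (rep in 1:20) {
    g <- gen_noisy_instance()
    h <- search_triplexes(g$dna, g$rna)
    if (nrow(h) < 2) next
    key <- order(-h$length, h$mismatches, h$tts_start, h$frame, h$tts_strand,
                 h$tfo_start)
    expect_equal(key, seq_len(nrow(h)))
  }
})

test_that("reverse-complementing the DNA mirrors hits between strands", {
  set.seed(77)
  for (rep in 1:15) {
    g <- gen_noisy_instance()
    n <- nchar(g$dna)
    h1 <- search_triplexes(g$dna, g$rna)
    h2 <- search_triplexes(revcomp_chr(g$dna), g$rna)
    key1 <- with(h1, sort(paste(ifelse(tts_strand == "+", "-", "+"),
                                n + 1 - tts_end, n + 1 - tts_start,
                                tfo_start, tfo_end, frame, mask, tts_seq)))
    key2 <- with(h2, sort(paste(tts_strand, tts_start, tts_end,
                                tfo_start, tfo_end, frame, mask, tts_seq)))
    expect_identical(key2, key1)
  }
})

test_that("loosening parameters never loses a reported region (covering)", {
  covered <- function(strict, loose) {
    if (!nrow(strict)) return(TRUE)
    all(vapply(seq_len(nrow(strict)), function(i) {
      s <- strict[i, ]
      ov_t <- pmin(s$tts_end, loose$tts_end) - pmax(s$tts_start, loose$tts_start) + 1
      ov_f <- pmin(s$tfo_end, loose$tfo_end) - pmax(s$tfo_start, loose$tfo_start) + 1
      shorter <- pmin(s$length, loose$length)
      any(2 * ov_t >= shorter & 2 * ov_f >= shorter)
    }, logical(1)))
  }
  set.seed(31)
  for (rep in 1:20) {
    g <- gen_noisy_instance()
    h_tight <- search_triplexes(g$dna, g$rna, search_params(max_error_rate = 0.1))
    h_loose <- search_triplexes(g$dna, g$rna, search_params(max_error_rate = 0.2))
    expect_true(covered(h_tight, h_loose))
    h_min8 <- search_triplexes(g$dna, g$rna, search_params(min_consecutive = 8))
    h_min7 <- search_triplexes(g$dna, g$rna, search_params(min_consecutive = 7))
    expect_true(covered(h_min8, h_min7))
  }
})

test_that("identical inputs produce identical results", {
  g <- list(dna = "TTCCGGAAGGAATCCTTGGAAGGAATT", rna = "CCUUCCUUCC")
  h1 <- search_triplexes(g$dna, g$rna)
  h2 <- search_triplexes(g$dna, g$rna)
  expect_identical(norm_hits(h1), norm_hits(h2))
})
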