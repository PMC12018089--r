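# Shared test utilities: candidate construction, hit normalization for
# engine-vs-reference comparison, random instances with planted noisy motifs
# (pure random sequences almost never contain a 7-triplet match, so motifs
# are planted to make equivalence checks non-vacuous), and CpG probe spans
# with controlled composition.

.code_by_frame <- list(
  PARALLEL_PYRIMIDINE = c(A = "U", G = "C"),
  PARALLEL_MIXED      = c(A = "U", G = "G"),
  ANTIPARALLEL_PURINE = c(A = "A", G = "G"),
  ANTIPARALLEL_MIXED  = c(A = "U", G = "G")
)

mk_cand <- function(mask, tts_start0 = 0L, tfo_start0 = 0L,
                    frame = "PARALLEL_PYRIMIDINE", strand = "+",
                    tts_seq = NULL, tfo_seq = NULL,
                    dna_id = "dna", rna_id = "rna") {
  len <- nchar(mask)
  if (is.null(tts_seq)) tts_seq <- strrep("A", len)
  if (is.null(tfo_seq)) tfo_seq <- strrep("U", len)
  data.frame(
    dna_id = dna_id, rna_id = rna_id, strand = strand, frame = frame,
    tts_start0 = as.integer(tts_start0),
    tts_end0 = as.integer(tts_start0) + len,
    tfo_start0 = as.integer(tfo_start0),
    tfo_end0 = as.integer(tfo_start0) + len,
    length = len,
    mismatches = nchar(gsub("1", "", mask, fixed = TRUE)),
    mask = mask, tts_seq = tts_seq, tfo_seq = tfo_seq,
    stringsAsFactors = FALSE
  )
}

hit_cols <- c("tts_start", "tts_end", "tts_strand", "tfo_start", "tfo_end",
              "frame", "length", "mismatches", "mask", "tts_seq", "tfo_seq")

norm_hits <- function(x) {
  y <- as.data.frame(x)[, hit_cols]
  rownames(y) <- NULL
  y
}

# random DNA/RNA pair with one planted, possibly mutated, code-consistent
# segment; uses the current RNG state
gen_noisy_instance <- function(min_len = 14L, max_len = 40L) {
  nd <- sample(min_len:max_len, 1L)
  nr <- sample(min_len:max_len, 1L)
  dna <- sample(c("A", "G", "C", "T"), nd, TRUE, prob = c(.3, .3, .2, .2))
  rna <- sample(c("A", "C", "G", "U"), nr, TRUE, prob = c(.2, .2, .3, .3))
  fr <- sample(names(.code_by_frame), 1L)
  L <- sample(7:min(14L, nd, nr), 1L)
  pd <- sample(1:(nd - L + 1L), 1L)
  pr <- sample(1:(nr - L + 1L), 1L)
  tts <- sample(c("A", "G"), L, TRUE)
  dna[pd:(pd + L - 1L)] <- tts
  tfo <- unname(.code_by_frame[[fr]][tts])
  nmut <- sample(0:3, 1L, prob = c(.4, .3, .2, .1))
  if (nmut) {
    mp <- sample(L, min(nmut, L))
    tfo[mp] <- sample(c("A", "C", "G", "U"), length(mp), TRUE)
  }
  if (startsWith(fr, "ANTI")) tfo <- rev(tfo)
  rna[pr:(pr + L - 1L)] <- tfo
  list(dna = paste(dna, collapse = ""), rna = paste(rna, collapse = ""))
}

# 300-bp (default) CpG probe span: n_cg CG dinucleotides spaced so the
# running sum stays positive throughout, with filler C/G/A arranged so no
# accidental CG dinucleotide arises; total C and G counts are exact.
build_cpg_span <- function(n_cg, n_c, n_g, len = 300L) {
  stopifnot(n_cg >= 17L, n_c >= n_cg, n_g >= n_cg,
            (n_c - n_cg) + (n_g - n_cg) <= len - 2L * n_cg)
  s <- min(17L, (len - 2L) %/% max(1L, n_cg - 1L))
  starts <- 1L + (seq_len(n_cg) - 1L) * s
  stopifnot(starts[n_cg] + 1L <= len)
  pool <- c(rep("G", n_g - n_cg), rep("C", n_c - n_cg),
            rep("A", len - 2L * n_cg - (n_c - n_cg) - (n_g - n_cg)))
  out <- character(len)
  out[starts] <- "C"
  out[starts + 1L] <- "G"
  out[-c(starts, starts + 1L)] <- pool
  paste(out, collapse = "")
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}
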