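#' Search parameters for triplex prediction
#'
#' @param min_consecutive Minimum number of consecutive code-conforming base
#'   triplets a reported triplex must contain; also the minimum total triplex
#'   length. Default 7, the floor suitable for both long and short noncoding
#'   RNAs.
#' @param max_error_rate Maximum allowed fraction of mismatching triplets
#'   within a reported triplex, in `[0, 1]`. Default 0.20.
#' @param report_cpg Whether downstream reporting should annotate target sites
#'   with CpG islands. Default `FALSE`.
#' @param core_run_floor Hard floor on the error-free core run (default 7);
#'   `min_consecutive` may not be set below it. Lowering it is only meant for
#'   small didactic examples.
#' @return A `search_params` object (list).
#' @export
search_params <- function(min_consecutive = 7L, max_error_rate = 0.20,
                          report_cpg = FALSE, core_run_floor = 7L) {
  min_consecutive <- as.integer(min_consecutive)
  core_run_floor <- as.integer(core_run_floor)
  if (is.na(core_run_floor) || core_run_floor < 1L) {
    stop("core_run_floor must be a positive integer", call. = FALSE)
  }
  if (is.na(min_consecutive) || min_consecutive < core_run_floor) {
    stop("min_consecutive must be >= the core run floor (",
         core_run_floor, ")", call. = FALSE)
  }
  if (!is.numeric(max_error_rate) || is.na(max_error_rate) ||
      max_error_rate < 0 || max_error_rate > 1) {
    stop("max_error_rate must be a fraction in [0, 1]", call. = FALSE)
  }
  structure(
    list(min_consecutive = min_consecutive,
         max_error_rate = as.numeric(max_error_rate),
         report_cpg = isTRUE(report_cpg),
         core_run_floor = core_run_floor),
    class = "search_params"
  )
}

.empty_candidates <- function() {
  data.frame(
    dna_id = character(), rna_id = character(), strand = character(),
    frame = character(), tts_start0 = integer(), tts_end0 = integer(),
    tfo_start0 = integer(), tfo_end0 = integer(), length = integer(),
    mismatches = integer(), mask = character(), tts_seq = character(),
    tfo_seq = character(), stringsAsFactors = FALSE
  )
}

#' Find maximal purine tracts on both DNA strands
#'
#' A triplex target site is constrained to an uninterrupted A/G tract on one
#' duplex strand, so candidate regions are the maximal purine runs of the plus
#' strand and of the reverse complement (minus strand). Minus-strand tracts
#' correspond to maximal C/T runs of the input and are reported in plus-strand
#' coordinates with `strand = "-"`; their `purine_seq` is read 5'->3' on the
#' minus strand.
#'
#' @param dna A DNA `seq_record` or raw string.
#' @param min_len Minimum tract length to report (a shorter tract cannot host
#'   a valid triplex).
#' @return data.frame with columns `dna_id`, `strand`, `start0`, `end0`
#'   (0-based half-open, plus strand), `length`, `purine_seq`.
#' @export
find_purine_tracts <- function(dna, min_len = 7L) {
  dna <- .as_record(dna, "DNA")
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  runs_of <- function(pattern) {
    m <- gregexpr(pattern, dna$residues)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(start0 = as.integer(m) - 1L,
               len = attr(m, "match.length"))
  }
  out <- list()
  plus <- runs_of("[AG]+")
  if (!is.null(plus)) {
    plus <- plus[plus$len >= min_len, , drop = FALSE]
    if (nrow(plus)) {
      out$plus <- data.frame(
        dna_id = dna$id, strand = "+",
        start0 = plus$start0, end0 = plus$start0 + plus$len,
        length = plus$len,
        purine_seq = substring(dna$residues, plus$start0 + 1L,
                               plus$start0 + plus$len),
        stringsAsFactors = FALSE
      )
    }
  }
  minus <- runs_of("[CT]+")
  if (!is.null(minus)) {
    minus <- minus[minus$len >= min_len, , drop = FALSE]
    if (nrow(minus)) {
      out$minus <- data.frame(
        dna_id = dna$id, strand = "-",
        start0 = minus$start0, end0 = minus$start0 + minus$len,
        length = minus$len,
        purine_seq = vapply(seq_len(nrow(minus)), function(i) {
          .revcomp_dna(substring(dna$residues, minus$start0[i] + 1L,
                                 minus$start0[i] + minus$len[i]))
        }, character(1L)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(dna_id = character(), strand = character(),
                      start0 = integer(), end0 = integer(), length = integer(),
                      purine_seq = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start0, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Containment-maximal matched-end windows of a 0/1 diagonal, at every
# mismatch level k = 0..floor(rate * L). Returns a matrix with columns
# t1, t2 (1-based inclusive within the diagonal) and mism.
.diagonal_windows <- function(v, rate) {
  L <- length(v)
  ones <- which(v)
  if (!length(ones)) return(NULL)
  cs <- cumsum(!v)
  kmax <- floor(rate * L + 1e-9)
  csa <- c(0L, cs)[ones]  # mismatches strictly before each left end
  acc_a <- integer(0)
  acc_b <- integer(0)
  for (k in 0:kmax) {
    bmax <- findInterval(csa + k + 0.5, cs)
    bstar <- ones[findInterval(bmax, ones)]
    pm <- cummax(bstar)
    keep <- bstar > c(-1L, pm[-length(pm)])
    a <- ones[keep]
    b <- bstar[keep]
    mism <- cs[b] - csa[keep]
    len <- b - a + 1L
    ok <- mism <= rate * len + 1e-9
    acc_a <- c(acc_a, a[ok])
    acc_b <- c(acc_b, b[ok])
  }
  if (!length(acc_a)) return(NULL)
  dup <- duplicated(acc_a * (L + 1L) + acc_b)
  a <- acc_a[!dup]; b <- acc_b[!dup]
  cbind(t1 = a, t2 = b, mism = cs[b] - c(0L, cs)[a])
}

#' Scan one purine tract against an RNA in one frame
#'
#' Slides the RNA along the tract on every alignment diagonal and reports raw
#' candidate alignments: matched-end windows whose running mismatch fraction
#' stays within the error budget, containment-maximal at each mismatch count.
#' With a zero budget this reduces to the maximal perfectly matched runs
#' (matching restarts immediately after each mismatch); with a nonzero budget
#' a window additionally extends across mismatches while the total mismatch
#' rate stays below the threshold, and its error-free sub-runs are also
#' emitted so that later region filtering can retain shorter, lower-error
#' triplexes. For parallel frames the TFO is read 5'->3' along the purine
#' strand; for antiparallel frames it is read 3'->5' against it.
#'
#' Candidates are raw: end-trimming, core-run, minimum-length and redundancy
#' rules are enforced by the filter chain, not here.
#'
#' @param tract One row of [find_purine_tracts()] output (or an equivalent
#'   list).
#' @param rna An RNA `seq_record` or raw string.
#' @param frame Frame name.
#' @param params A [search_params()] object.
#' @param min_report_len Drop raw windows shorter than this (default 1,
#'   i.e. report everything). The orchestrating search passes its minimum
#'   triplex length here, which cannot change the final hit set: windows
#'   below the minimum length are neither reportable nor able to dominate a
#'   longer candidate.
#' @return Candidate data.frame (0-based half-open coordinates; `mask` is the
#'   match mask in TTS 5'->3' purine-strand order, `1` = match).
#' @export
scan_pair <- function(tract, rna, frame, params = search_params(),
                      min_report_len = 1L) {
  rna <- .as_record(rna, "RNA")
  frame <- match.arg(frame, TRIPLEX_FRAMES)
  stopifnot(inherits(params, "search_params"))
  tract <- as.list(tract)
  P <- strsplit(tract$purine_seq, "", fixed = TRUE)[[1L]]
  if (!all(P %in% c("A", "G"))) {
    stop("tract purine_seq must contain only A and G", call. = FALSE)
  }
  R <- strsplit(rna$residues, "", fixed = TRUE)[[1L]]
  n <- length(P)
  m <- length(R)
  antiparallel <- frame_orientation(frame) == "ANTIPARALLEL"
  E <- if (antiparallel) rev(R) else R
  expect <- unname(.frame_third_base[[frame]][P])
  acc <- list(pa = integer(0), pb = integer(0), ea = integer(0),
              eb = integer(0), mism = integer(0), mask = character(0))
  for (delta in seq.int(-(m - 1L), n - 1L)) {
    A0 <- max(0L, delta)
    B0 <- A0 - delta
    L <- min(n - A0, m - B0)
    if (L < min_report_len) next
    v <- expect[(A0 + 1L):(A0 + L)] == E[(B0 + 1L):(B0 + L)]
    w <- .diagonal_windows(v, params$max_error_rate)
    if (is.null(w)) next
    if (min_report_len > 1L) {
      w <- w[w[, "t2"] - w[, "t1"] + 1L >= min_report_len, , drop = FALSE]
      if (!nrow(w)) next
    }
    vstr <- paste(as.integer(v), collapse = "")
    acc$pa <- c(acc$pa, A0 + w[, "t1"] - 1L)   # 0-based purine index
    acc$pb <- c(acc$pb, A0 + w[, "t2"] - 1L)
    acc$ea <- c(acc$ea, B0 + w[, "t1"] - 1L)   # 0-based index into E
    acc$eb <- c(acc$eb, B0 + w[, "t2"] - 1L)
    acc$mism <- c(acc$mism, as.integer(w[, "mism"]))
    acc$mask <- c(acc$mask, substring(vstr, w[, "t1"], w[, "t2"]))
  }
  if (!length(acc$pa)) return(.empty_candidates())
  if (tract$strand == "+") {
    tts0 <- tract$start0 + acc$pa
    tts1 <- tract$start0 + acc$pb + 1L
  } else {
    tts0 <- tract$end0 - 1L - acc$pb
    tts1 <- tract$end0 - acc$pa
  }
  if (antiparallel) {
    rna0 <- m - 1L - acc$eb
    rna1 <- m - acc$ea
  } else {
    rna0 <- acc$ea
    rna1 <- acc$eb + 1L
  }
  out <- data.frame(
    dna_id = tract$dna_id, rna_id = rna$id, strand = tract$strand,
    frame = frame, tts_start0 = tts0, tts_end0 = tts1,
    tfo_start0 = rna0, tfo_end0 = rna1,
    length = acc$pb - acc$pa + 1L, mismatches = acc$mism,
    mask = acc$mask,
    tts_seq = substring(tract$purine_seq, acc$pa + 1L, acc$pb + 1L),
    tfo_seq = substring(rna$residues, rna0 + 1L, rna1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Error rate and G+U content of candidates
#'
#' The error rate is the percentage of triplets in the candidate that violate
#' the frame's pairing code; the G+U percentage is the fraction of G and U
#' bases in the TFO, a composition linked to triplex stability.
#'
#' @param candidates Candidate data.frame (columns `mask`, `tfo_seq`,
#'   `length`).
#' @return The input with columns `error_rate_pct` and `gu_pct` added.
#' @export
compute_stats <- function(candidates) {
  if (!nrow(candidates)) {
    candidates$error_rate_pct <- numeric(0)
    candidates$gu_pct <- numeric(0)
    return(candidates)
  }
  n0 <- nchar(candidates$mask) - nchar(gsub("0", "", candidates$mask, fixed = TRUE))
  gu <- nchar(candidates$tfo_seq) -
    nchar(gsub("[GU]", "", candidates$tfo_seq))
  candidates$error_rate_pct <- 100 * n0 / candidates$length
  candidates$gu_pct <- 100 * gu / candidates$length
  candidates
}

.sort_hits <- function(h) {
  if (!nrow(h)) return(h)
  o <- order(-h$length, h$mismatches, h$tts_start0, h$frame, h$strand,
             h$tfo_start0)
  h <- h[o, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Predict all triplexes between a DNA and an RNA
#'
#' Orchestrates the full prediction: extracts maximal purine tracts on both
#' DNA strands, scans each tract against the RNA under all four canonical
#' Hoogsteen frames, applies the end-trimming / core-run / region-domination /
#' sliding-tie filter chain, and reports the surviving triplexes with their
#' error rate and TFO G+U content.
#'
#' Hits are sorted by length (descending), then error rate (ascending), then
#' TTS start, frame name, strand and TFO start; identical inputs always give
#' identical output.
#'
#' @param dna DNA `seq_record` or raw string (alphabet A/C/G/T).
#' @param rna RNA `seq_record` or raw string (A/C/G/U; T normalized to U).
#' @param params [search_params()].
#' @return A data.frame of class `triplex_hits`, one row per predicted
#'   triplex, with 1-based inclusive coordinates: `tts_start`/`tts_end` on the
#'   DNA plus strand (with `tts_strand` flagging which strand is the purine
#'   strand), `tfo_start`/`tfo_end` on the RNA, plus `frame`, `length`,
#'   `error_rate_pct`, `gu_pct`, `tts_seq` (purine strand 5'->3') and
#'   `tfo_seq` (RNA 5'->3'). Internal columns `mismatches` and `mask` are
#'   retained for downstream checks.
#' @examples
#' hits <- search_triplexes("GGAAGGAAGGAA", "CCUUCCUUCCUU")
#' hits[, c("tts_start", "tts_end", "frame", "length", "error_rate_pct")]
#' @export
search_triplexes <- function(dna, rna, params = search_params()) {
  dna <- .as_record(dna, "DNA")
  rna <- .as_record(rna, "RNA")
  stopifnot(inherits(params, "search_params"))
  tracts <- find_purine_tracts(dna, min_len = params$min_consecutive)
  cands <- .empty_candidates()
  if (nrow(tracts)) {
    pieces <- list()
    for (i in seq_len(nrow(tracts))) {
      for (f in TRIPLEX_FRAMES) {
        pieces[[length(pieces) + 1L]] <-
          scan_pair(tracts[i, ], rna, f, params,
                    min_report_len = params$min_consecutive)
      }
    }
    cands <- do.call(rbind, pieces)
  }
  hits <- apply_candidate_filters(cands, params)
  hits <- compute_stats(hits)
  hits <- .sort_hits(hits)
  out <- data.frame(
    dna_id = hits$dna_id, rna_id = hits$rna_id,
    tts_start = hits$tts_start0 + 1L, tts_end = hits$tts_end0,
    tts_strand = hits$strand,
    tfo_start = hits$tfo_start0 + 1L, tfo_end = hits$tfo_end0,
    frame = hits$frame, length = hits$length,
    error_rate_pct = hits$error_rate_pct, gu_pct = hits$gu_pct,
    tts_seq = hits$tts_seq, tfo_seq = hits$tfo_seq,
    mismatches = hits$mismatches, mask = hits$mask,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- params
  class(out) <- c("triplex_hits", "data.frame")
  out
}
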