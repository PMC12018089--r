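# Redundancy and validity filters that turn raw candidate alignments into the
# reported, non-redundant triplex set. Error-rate comparisons between two
# candidates use integer cross-multiplication (mism_i * len_j vs mism_j *
# len_i), so 20%-boundary decisions never hinge on floating point.

.longest_one_run <- function(mask) {
  vapply(mask, function(mk) {
    m <- gregexpr("1+", mk)[[1L]]
    if (m[1L] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Trim candidates to matched ends
#'
#' Reported triplexes must begin and end with a correctly paired triplet:
#' leading and trailing mismatches are stripped, shrinking the TTS and TFO
#' intervals symmetrically. Candidates whose mask has no match at all are
#' dropped.
#'
#' @param candidates Candidate data.frame (as produced by [scan_pair()]).
#' @return The trimmed candidates.
#' @export
trim_to_matched_ends <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  first1 <- regexpr("1", candidates$mask, fixed = TRUE)
  keep <- first1 != -1L
  candidates <- candidates[keep, , drop = FALSE]
  if (!nrow(candidates)) return(candidates)
  f <- as.integer(regexpr("1", candidates$mask, fixed = TRUE))
  l <- nchar(candidates$mask) -
    as.integer(regexpr("1", vapply(candidates$mask, .rev_chars, character(1L)),
                       fixed = TRUE)) + 1L
  kl <- f - 1L
  kr <- nchar(candidates$mask) - l
  anti <- startsWith(candidates$frame, "ANTI")
  plus <- candidates$strand == "+"
  candidates$tts_start0 <- candidates$tts_start0 + ifelse(plus, kl, kr)
  candidates$tts_end0 <- candidates$tts_end0 - ifelse(plus, kr, kl)
  candidates$tfo_start0 <- candidates$tfo_start0 + ifelse(anti, kr, kl)
  candidates$tfo_end0 <- candidates$tfo_end0 - ifelse(anti, kl, kr)
  candidates$tts_seq <- substring(candidates$tts_seq, f, l)
  candidates$tfo_seq <- substring(candidates$tfo_seq,
                                  ifelse(anti, kr, kl) + 1L,
                                  nchar(candidates$tfo_seq) - ifelse(anti, kl, kr))
  candidates$mask <- substring(candidates$mask, f, l)
  candidates$length <- l - f + 1L
  candidates$mismatches <- candidates$length -
    (nchar(candidates$mask) - nchar(gsub("1", "", candidates$mask, fixed = TRUE)))
  rownames(candidates) <- NULL
  candidates
}

#' Core-run requirement
#'
#' Every valid triplex must contain a run of at least `floor` consecutive
#' correctly paired triplets, irrespective of the frame.
#'
#' @param candidates Candidate data.frame.
#' @param floor Minimum run of consecutive matches (default 7).
#' @return Logical vector, `TRUE` where the requirement is met.
#' @export
passes_core_run <- function(candidates, floor = 7L) {
  if (!nrow(candidates)) return(logical(0))
  .longest_one_run(candidates$mask) >= floor
}

# 50% reciprocal-overlap conflict on both the TTS and the TFO interval,
# measured against the shorter candidate.
.conflicts_with <- function(c_i, cands) {
  ov_tts <- pmax(0L, pmin(c_i$tts_end0, cands$tts_end0) -
                   pmax(c_i$tts_start0, cands$tts_start0))
  ov_tfo <- pmax(0L, pmin(c_i$tfo_end0, cands$tfo_end0) -
                   pmax(c_i$tfo_start0, cands$tfo_start0))
  shorter <- pmin(c_i$length, cands$length)
  (2L * ov_tts >= shorter) & (2L * ov_tfo >= shorter)
}

#' Region-level selection of non-redundant triplexes
#'
#' Within the same TTS/TFO region (candidates whose target and oligo
#' intervals reciprocally overlap by at least half of the shorter candidate),
#' only the longest triplex of a given error rate is retained; a shorter
#' triplex survives only if its error rate is strictly lower than that of
#' every longer triplex in its region. Candidates at distinct positions are
#' never merged, even when their sequences are identical. The result does not
#' depend on input order and the operation is idempotent.
#'
#' @param candidates Candidate data.frame (trimmed, core-run-valid).
#' @return The surviving candidates.
#' @export
select_by_region <- function(candidates) {
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  len <- candidates$length
  mism <- candidates$mismatches
  ts <- candidates$tts_start0; te <- candidates$tts_end0
  fs <- candidates$tfo_start0; fe <- candidates$tfo_end0
  dominated <- logical(n)
  o <- order(-len)  # potential dominators of i all precede it in o
  for (pos in seq_len(n)) {
    i <- o[pos]
    if (pos == 1L) next
    j <- o[seq_len(pos - 1L)]
    j <- j[len[j] > len[i]]
    if (!length(j)) next
    j <- j[mism[j] * len[i] <= mism[i] * len[j]]  # err_j <= err_i, exact
    if (!length(j)) next
    ov_t <- pmin(te[i], te[j]) - pmax(ts[i], ts[j])
    ov_f <- pmin(fe[i], fe[j]) - pmax(fs[i], fs[j])
    dominated[i] <- any(2L * ov_t >= len[i] & 2L * ov_f >= len[i])
  }
  out <- candidates[!dominated, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve continuous sliding ties on repetitive stretches
#'
#' When the same TTS/TFO sequence pair can slide along a repeat, producing a
#' contiguous range of equivalent placements, a unique match is chosen at the
#' midpoint of the longer of the two sequences: the central placement is kept
#' when the number of equivalent placements is odd (both sequences of equal
#' parity), and the two central placements when it is even (mixed parity).
#' Non-repetitive candidates pass through unchanged.
#'
#' @param candidates Candidate data.frame.
#' @return Candidates with sliding ties reduced to their central placements.
#' @export
resolve_slide_ties <- function(candidates) {
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  key <- paste(candidates$frame, candidates$strand, candidates$mask,
               candidates$tts_seq, candidates$tfo_seq, sep = "\r")
  keep <- logical(n)
  for (idx in split(seq_len(n), key)) {
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
      next
    }
    anti <- startsWith(candidates$frame[idx[1L]], "ANTI")
    d <- if (anti) {
      candidates$tts_start0[idx] + candidates$tfo_start0[idx]
    } else {
      candidates$tts_start0[idx] - candidates$tfo_start0[idx]
    }
    if (anyDuplicated(d)) {  # ambiguous double-slide; leave unresolved
      keep[idx] <- TRUE
      next
    }
    o <- order(d)
    idx <- idx[o]
    d <- d[o]
    run_id <- cumsum(c(1L, as.integer(diff(d) != 1L)))
    for (run in split(idx, run_id)) {
      p <- length(run)
      mid <- if (p %% 2L == 1L) (p + 1L) %/% 2L else c(p %/% 2L, p %/% 2L + 1L)
      keep[run[mid]] <- TRUE
    }
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full candidate filter chain
#'
#' Applies, in order: end trimming, validity (core run, minimum length, error
#' budget), region-level domination, and sliding-tie resolution.
#'
#' @param candidates Raw candidate data.frame.
#' @param params [search_params()].
#' @return Valid, non-redundant candidates.
#' @export
apply_candidate_filters <- function(candidates, params = search_params()) {
  if (nrow(candidates)) {
    # trimming only shrinks, so anything already below the minimum length can
    # be discarded before the more expensive steps
    candidates <- candidates[candidates$length >= params$min_consecutive, ,
                             drop = FALSE]
  }
  candidates <- trim_to_matched_ends(candidates)
  if (!nrow(candidates)) return(candidates)
  required_run <- params$min_consecutive
  ok <- passes_core_run(candidates, floor = required_run) &
    candidates$length >= params$min_consecutive &
    candidates$mismatches <= params$max_error_rate * candidates$length + 1e-9
  candidates <- candidates[ok, , drop = FALSE]
  if (!nrow(candidates)) return(candidates)
  dup <- duplicated(candidates[, c("frame", "strand", "tts_start0", "tts_end0",
                                   "tfo_start0", "tfo_end0")])
  candidates <- candidates[!dup, , drop = FALSE]
  candidates <- select_by_region(candidates)
  resolve_slide_ties(candidates)
}
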