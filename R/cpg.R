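#' Parameters for CpG island detection
#'
#' The detector scores successive dinucleotides with a running sum (+17 for
#' CpG, -1 otherwise) and assesses each positive excursion against the
#' classical island criteria: span length greater than 200 bp, GC content
#' over 50%, and observed/expected CpG ratio greater than 0.6 (all strict
#' inequalities).
#'
#' @param cpg_step_score Score increment for a C immediately followed by a G
#'   (default +17).
#' @param other_step_score Score for any other dinucleotide (default -1).
#' @param min_length_bp Exclusive lower bound on island length (default 200).
#' @param min_gc_percent Exclusive lower bound on GC percentage (default 50).
#' @param min_obs_exp Exclusive lower bound on the observed/expected CpG
#'   ratio (default 0.6).
#' @return A `cpg_params` object (list).
#' @export
cpg_params <- function(cpg_step_score = 17, other_step_score = -1,
                       min_length_bp = 200, min_gc_percent = 50,
                       min_obs_exp = 0.6) {
  stopifnot(min_length_bp > 0, min_gc_percent > 0, min_obs_exp > 0)
  structure(
    list(cpg_step_score = cpg_step_score,
         other_step_score = other_step_score,
         min_length_bp = min_length_bp,
         min_gc_percent = min_gc_percent,
         min_obs_exp = min_obs_exp),
    class = "cpg_params"
  )
}

#' Dinucleotide step scores
#'
#' @param seq DNA string or `seq_record`.
#' @param params [cpg_params()].
#' @return Numeric vector of length `nchar(seq) - 1`: step i scores the
#'   dinucleotide at positions i, i+1 (+17 for CG, -1 otherwise at defaults).
#'   Sequences shorter than 2 give an empty vector.
#' @export
dinucleotide_score_steps <- function(seq, params = cpg_params()) {
  seq <- .as_record(seq, "DNA")
  x <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  n <- length(x)
  if (n < 2L) return(numeric(0))
  ifelse(x[-n] == "C" & x[-1L] == "G",
         params$cpg_step_score, params$other_step_score)
}

#' GC content and observed/expected CpG ratio of a span
#'
#' The observed/expected ratio follows the classical island definition:
#' (number of CpG dinucleotides x span length) / (#C x #G), taken as 0 when
#' the span has no C or no G.
#'
#' @param seq DNA string or `seq_record`.
#' @param start,end 1-based inclusive span bounds.
#' @return List with `gc_percent` and `obs_exp_ratio`.
#' @export
island_metrics <- function(seq, start, end) {
  seq <- .as_record(seq, "DNA")
  n_total <- nchar(seq$residues)
  stopifnot(start >= 1L, end <= n_total, end - start + 1L >= 2L)
  s <- substring(seq$residues, start, end)
  N <- nchar(s)
  nC <- N - nchar(gsub("C", "", s, fixed = TRUE))
  nG <- N - nchar(gsub("G", "", s, fixed = TRUE))
  ncg <- length(gregexpr("(?=CG)", s, perl = TRUE)[[1L]])
  if (gregexpr("(?=CG)", s, perl = TRUE)[[1L]][1L] == -1L) ncg <- 0L
  list(
    gc_percent = 100 * (nC + nG) / N,
    obs_exp_ratio = if (nC == 0L || nG == 0L) 0 else ncg * N / (nC * nG)
  )
}

#' Detect CpG islands by running-sum scoring
#'
#' Scans left to right: a candidate span opens at the first positive-scoring
#' step (a CpG), accumulates the running sum, and closes when the sum returns
#' to zero or the sequence ends. The closed span is assessed against the
#' three island criteria (strict inequalities) and reported if it qualifies,
#' after which the scan advances past the island. If the span does not
#' qualify, the scan restarts just after the position where the running sum
#' attained its maximum within the span (or past the span when that maximum
#' sits at the span start), so a qualifying core is not lost inside a failed
#' excursion. The scan is a heuristic: every report satisfies all three
#' criteria, but completeness over all criterion-satisfying substrings is not
#' claimed.
#'
#' @param seq DNA string or `seq_record`.
#' @param params [cpg_params()].
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `length_bp`, `gc_percent`, `obs_exp_ratio`; islands are non-overlapping
#'   and sorted by start.
#' @examples
#' find_cpg_islands(strrep("CG", 125))  # one 250-bp island
#' @export
find_cpg_islands <- function(seq, params = cpg_params()) {
  seq <- .as_record(seq, "DNA")
  steps <- dinucleotide_score_steps(seq, params)
  empty <- data.frame(start = integer(), end = integer(),
                      length_bp = integer(), gc_percent = numeric(),
                      obs_exp_ratio = numeric(), stringsAsFactors = FALSE)
  ns <- length(steps)
  if (!ns) return(empty)
  pos_steps <- which(steps > 0)
  if (!length(pos_steps)) return(empty)
  out <- list()
  p <- 1L
  repeat {
    nxt <- pos_steps[pos_steps >= p]
    if (!length(nxt)) break
    q <- nxt[1L]                       # span opens at base q
    rs <- cumsum(steps[q:ns])
    hit0 <- which(rs <= 0)
    if (length(hit0)) {
      close_rel <- hit0[1L]
    } else {
      close_rel <- ns - q + 1L         # runs to the end of the sequence
    }
    close_step <- q + close_rel - 1L
    span_start <- q
    span_end <- close_step + 1L
    met <- island_metrics(seq, span_start, span_end)
    qualifies <- (span_end - span_start + 1L) > params$min_length_bp &&
      met$gc_percent > params$min_gc_percent &&
      met$obs_exp_ratio > params$min_obs_exp
    if (qualifies) {
      out[[length(out) + 1L]] <- data.frame(
        start = span_start, end = span_end,
        length_bp = span_end - span_start + 1L,
        gc_percent = met$gc_percent, obs_exp_ratio = met$obs_exp_ratio,
        stringsAsFactors = FALSE
      )
      p <- span_end + 1L               # advance past the reported island
    } else {
      j_max <- q + which.max(rs[seq_len(close_rel)]) - 1L
      p <- if (j_max == q) close_step + 1L else j_max + 1L
    }
    if (p > ns) break
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate triplex hits with CpG islands
#'
#' Each hit is paired with the island whose interval overlaps its TTS
#' (distance 0); otherwise with the nearest island and the signed gap in bp
#' (positive when the island lies downstream of the TTS on the plus strand,
#' negative when upstream); otherwise with none.
#'
#' @param hits `triplex_hits` data.frame (1-based `tts_start`/`tts_end`).
#' @param islands Output of [find_cpg_islands()] for the same DNA.
#' @return `hits` with columns `cpg_island` (`"start-end"` or `"."`) and
#'   `cpg_distance_bp` (integer, `NA` when no island exists).
#' @export
annotate_tts_islands <- function(hits, islands) {
  hits$cpg_island <- rep(".", nrow(hits))
  hits$cpg_distance_bp <- rep(NA_integer_, nrow(hits))
  if (!nrow(hits) || is.null(islands) || !nrow(islands)) return(hits)
  for (i in seq_len(nrow(hits))) {
    ts <- hits$tts_start[i]
    te <- hits$tts_end[i]
    ov <- pmin(te, islands$end) - pmax(ts, islands$start) + 1L
    if (any(ov > 0L)) {
      j <- which.max(ov)
      hits$cpg_island[i] <- paste0(islands$start[j], "-", islands$end[j])
      hits$cpg_distance_bp[i] <- 0L
    } else {
      dist <- ifelse(islands$start > te,
                     islands$start - te,        # island downstream
                     -(ts - islands$end))       # island upstream
      j <- which.min(abs(dist))
      hits$cpg_island[i] <- paste0(islands$start[j], "-", islands$end[j])
      hits$cpg_distance_bp[i] <- as.integer(dist[j])
    }
  }
  hits
}
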