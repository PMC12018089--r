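# Deterministic synthetic DNA/RNA generators with planted triplexes and
# planted CpG islands. These define the study conditions used throughout the
# tests: pyrimidine-biased DNA background (70% C/T) so spurious purine tracts
# of tract-hosting length are rare, and fixtures are re-drawn when a
# qualifying hit appears away from the planted locus.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# universal mismatch bases: never a code for the purine base in any frame
.mismatch_base <- c(A = "C", G = "U")

#' Plant a triplex into synthetic sequences
#'
#' Generates a pyrimidine-rich random DNA and a random RNA, embeds a pure
#' purine target tract of length `tts_len` on the DNA plus strand and the
#' frame-consistent TFO (reversed for antiparallel frames) in the RNA, with
#' exactly `n_errors` interior RNA-side mismatches placed so that the first
#' and last triplets stay matched and (by default) a run of at least 7
#' consecutive matches survives. The fixture is re-drawn (deterministically)
#' if the default search reports any hit outside the planted alignment.
#'
#' @param dna_len,rna_len Background sequence lengths (defaults 200, 150).
#' @param tts_len Planted tract length (>= 3; >= 7 for a recoverable hit).
#' @param frame Frame of the planted triplex.
#' @param n_errors Number of interior mismatches (default 0).
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param budget Error-rate guard: `n_errors / tts_len` must not exceed it
#'   (default 0.20). Raise it deliberately to plant over-budget negatives.
#' @param break_runs If `TRUE`, mismatches are instead placed so that no run
#'   of 7 consecutive matches survives (an intended-negative fixture);
#'   `n_errors` must be large enough to cut all runs.
#' @return List with `dna` and `rna` (`seq_record`s) and `truth`: the planted
#'   1-based TTS/TFO intervals, strand, frame, mismatch triplet positions and
#'   expected error rate.
#' @export
plant_triplex <- function(dna_len = 200L, rna_len = 150L, tts_len = 12L,
                          frame = "PARALLEL_PYRIMIDINE", n_errors = 0L,
                          seed = 1L, budget = 0.20, break_runs = FALSE) {
  frame <- match.arg(frame, TRIPLEX_FRAMES)
  tts_len <- as.integer(tts_len)
  n_errors <- as.integer(n_errors)
  if (tts_len < 3L) stop("tts_len must be >= 3", call. = FALSE)
  if (n_errors < 0L) stop("n_errors must be >= 0", call. = FALSE)
  if (n_errors > budget * tts_len + 1e-9) {
    stop(sprintf("infeasible: %d mismatches over %d triplets exceeds the %.0f%% error budget",
                 n_errors, tts_len, 100 * budget), call. = FALSE)
  }
  if (n_errors > max(0L, tts_len - 2L)) {
    stop("too many mismatches for interior placement", call. = FALSE)
  }
  if (break_runs && n_errors < floor(tts_len / 7)) {
    stop("n_errors too small to break every 7-run", call. = FALSE)
  }
  if (dna_len < tts_len + 2L || rna_len < tts_len) {
    stop("background sequences too short for the requested tract", call. = FALSE)
  }
  anti <- frame_orientation(frame) == "ANTIPARALLEL"
  code <- .frame_third_base[[frame]]

  for (attempt in 0:49) {
    fx <- .with_seed((seed + 7919L * attempt) %% .Machine$integer.max, {
      # purine tract with both letters present (avoids homopolymer slides)
      tts <- sample(c("A", "G"), tts_len, replace = TRUE)
      tries <- 0L
      while ((!any(tts == "A") || !any(tts == "G")) && tries < 100L) {
        tts <- sample(c("A", "G"), tts_len, replace = TRUE)
        tries <- tries + 1L
      }
      # mismatch triplet positions (1-based along the TTS)
      mpos <- integer(0)
      if (n_errors > 0L) {
        interior <- 2L:(tts_len - 1L)
        if (break_runs) {
          base <- seq(7L, by = 7L, length.out = floor(tts_len / 7))
          extra <- setdiff(interior, base)
          mpos <- sort(c(base,
                         if (n_errors > length(base)) {
                           sample(extra, n_errors - length(base))
                         } else integer(0)))
          mpos <- mpos[seq_len(n_errors)]
        } else {
          ok <- FALSE
          for (t in 1:1000) {
            cand <- sort(sample(interior, n_errors))
            gaps <- diff(c(0L, cand, tts_len + 1L)) - 1L
            if (max(gaps) >= min(7L, tts_len - n_errors)) {
              mpos <- cand
              ok <- TRUE
              break
            }
          }
          if (!ok) stop("could not place mismatches while preserving a 7-run",
                        call. = FALSE)
        }
      }
      tfo_along_tts <- unname(code[tts])
      tfo_along_tts[mpos] <- unname(.mismatch_base[tts[mpos]])
      tfo <- if (anti) rev(tfo_along_tts) else tfo_along_tts

      # ~70% pyrimidine background with pyrimidine runs capped at 4 and
      # purines only as singletons: no background purine tract (on either
      # strand) can reach the 7-triplet hosting length
      dna_bg <- character(0)
      while (length(dna_bg) < dna_len) {
        dna_bg <- c(dna_bg,
                    sample(c("C", "T"), sample(1:4, 1L), replace = TRUE),
                    sample(c("A", "G"), 1L))
      }
      dna_bg <- dna_bg[seq_len(dna_len)]
      pos_d <- sample(2:(dna_len - tts_len), 1L)  # leave room for flanks
      dna_bg[pos_d - 1L] <- sample(c("C", "T"), 1L)
      dna_bg[pos_d + tts_len] <- sample(c("C", "T"), 1L)
      dna_bg[pos_d:(pos_d + tts_len - 1L)] <- tts

      rna_bg <- sample(c("A", "C", "G", "U"), rna_len, replace = TRUE)
      pos_r <- sample(1:(rna_len - tts_len + 1L), 1L)
      rna_bg[pos_r:(pos_r + tts_len - 1L)] <- tfo

      list(
        dna = dna_record(paste(dna_bg, collapse = ""), id = "synthetic_dna"),
        rna = rna_record(paste(rna_bg, collapse = ""), id = "synthetic_rna"),
        truth = list(
          tts_start = pos_d, tts_end = pos_d + tts_len - 1L,
          tts_strand = "+",
          tfo_start = pos_r, tfo_end = pos_r + tts_len - 1L,
          frame = frame, length = tts_len,
          mismatch_positions = mpos,
          expected_error_pct = 100 * n_errors / tts_len,
          expected_hit = !break_runs &&
            tts_len >= 7L && n_errors <= 0.20 * tts_len + 1e-9
        )
      )
    })
    hits <- search_triplexes(fx$dna, fx$rna, search_params())
    tr <- fx$truth
    if (break_runs) {
      # an intended-negative must yield no hit at all, including chance
      # off-diagonal self-alignments inside the planted region
      if (nrow(hits) == 0L) return(fx)
    } else {
      inside <- !nrow(hits) |
        (hits$tts_start >= tr$tts_start & hits$tts_end <= tr$tts_end &
           hits$tfo_start >= tr$tfo_start & hits$tfo_end <= tr$tfo_end)
      if (all(inside)) return(fx)
    }
  }
  stop("could not generate a fixture free of spurious hits", call. = FALSE)
}

#' Plant a CpG island into a synthetic AT-rich DNA
#'
#' Embeds an alternating-CG segment (which satisfies all three island
#' criteria) in an AT-rich random background. The island is placed in the
#' final portion of the sequence so the running-sum span, which decays only
#' one unit per non-CpG step, closes before the downstream background can
#' dilute the span's GC content below threshold.
#'
#' @param seq_len Total sequence length.
#' @param island_len Planted island length; must exceed 200 bp.
#' @param gc_background Background GC fraction (must be below 0.40).
#' @param seed Integer seed.
#' @return List with `dna` (`seq_record`) and `truth` (planted 1-based
#'   interval and its expected metrics).
#' @export
plant_cpg_island <- function(seq_len = 2000L, island_len = 250L,
                             gc_background = 0.30, seed = 1L) {
  seq_len <- as.integer(seq_len)
  island_len <- as.integer(island_len)
  if (island_len <= 200L) stop("island_len must exceed 200 bp", call. = FALSE)
  if (gc_background >= 0.40) stop("gc_background must be below 0.40", call. = FALSE)
  if (seq_len < island_len + 100L) stop("seq_len too short", call. = FALSE)
  island <- strsplit(strrep("CG", ceiling(island_len / 2)), "", fixed = TRUE)[[1L]]
  island <- island[seq_len(island_len)]
  for (attempt in 0:49) {
    fx <- .with_seed((seed + 104729L * attempt) %% .Machine$integer.max, {
      pg <- gc_background / 2
      bg <- sample(c("A", "T", "C", "G"), seq_len, replace = TRUE,
                   prob = c((1 - gc_background) / 2, (1 - gc_background) / 2,
                            pg, pg))
      # keep the downstream tail short enough that the span closes undiluted
      lo <- max(1L, seq_len - island_len - 250L)
      hi <- seq_len - island_len + 1L
      pos <- if (lo >= hi) hi else sample(lo:hi, 1L)
      bg[pos:(pos + island_len - 1L)] <- island
      met <- island_metrics(paste(island, collapse = ""), 1L, island_len)
      list(
        dna = dna_record(paste(bg, collapse = ""), id = "synthetic_dna"),
        truth = list(start = pos, end = pos + island_len - 1L,
                     length_bp = island_len,
                     gc_percent = met$gc_percent,
                     obs_exp_ratio = met$obs_exp_ratio)
      )
    })
    isl <- find_cpg_islands(fx$dna)
    tr <- fx$truth
    if (!nrow(isl)) next
    ov <- pmin(isl$end, tr$end) - pmax(isl$start, tr$start) + 1L
    good <- any(ov >= 0.9 * tr$length_bp)
    stray <- any(ov <= 0L)
    if (good && !stray) return(fx)
  }
  stop("could not generate a clean island fixture", call. = FALSE)
}
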