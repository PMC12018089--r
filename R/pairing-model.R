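#' Canonical Hoogsteen matching frames
#'
#' The four motif/orientation contexts under which a third (RNA) strand can
#' occupy the major groove of a DNA duplex: the parallel pyrimidine motif, the
#' parallel mixed motif, the antiparallel purine motif and the antiparallel
#' mixed motif. In parallel frames the TFO runs 5'->3' along the purine strand
#' of the duplex; in antiparallel frames it runs 3'->5' against it.
#'
#' @format Character vector of the four frame names.
#' @export
TRIPLEX_FRAMES <- c(
  "PARALLEL_PYRIMIDINE",
  "PARALLEL_MIXED",
  "ANTIPARALLEL_PURINE",
  "ANTIPARALLEL_MIXED"
)

# Third-strand base demanded by each frame for a given purine-strand base.
# Duplex pairs are written pyrimidine:purine (TA = duplex T.A with A on the
# purine strand), so only the purine-strand base is ever consulted.
.frame_third_base <- list(
  PARALLEL_PYRIMIDINE = c(A = "U", G = "C"),  # TA:U, CG:C
  PARALLEL_MIXED      = c(A = "U", G = "G"),  # TA:U, CG:G
  ANTIPARALLEL_PURINE = c(A = "A", G = "G"),  # TA:A, CG:G
  ANTIPARALLEL_MIXED  = c(A = "U", G = "G")   # TA:U, CG:G
)

#' Orientation of a matching frame
#'
#' @param frame Frame name(s), see [TRIPLEX_FRAMES].
#' @return `"PARALLEL"` or `"ANTIPARALLEL"` for each input frame.
#' @export
frame_orientation <- function(frame) {
  frame <- match.arg(frame, TRIPLEX_FRAMES, several.ok = TRUE)
  ifelse(startsWith(frame, "ANTI"), "ANTIPARALLEL", "PARALLEL")
}

#' Base-triplet code tables for the four Hoogsteen frames
#'
#' Returns the allowed (duplex pair : third-strand base) combinations per
#' frame. Each frame defines exactly one third-strand base per duplex pair,
#' and the union over all frames contains exactly the four canonical codes
#' TA:U, CG:G, CG:C and TA:A.
#'
#' @return A data.frame with columns `frame`, `orientation`, `duplex_pair`
#'   (pyrimidine-strand base then purine-strand base, e.g. `"TA"`),
#'   `purine_base`, `third_base` and `code` (e.g. `"TA:U"`).
#' @examples
#' tabs <- build_code_tables()
#' subset(tabs, frame == "PARALLEL_PYRIMIDINE")$code
#' @export
build_code_tables <- function() {
  rows <- lapply(TRIPLEX_FRAMES, function(f) {
    tb <- .frame_third_base[[f]]
    purine <- names(tb)
    data.frame(
      frame = f,
      orientation = frame_orientation(f),
      duplex_pair = ifelse(purine == "A", "TA", "CG"),
      purine_base = purine,
      third_base = unname(tb),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$code <- paste0(out$duplex_pair, ":", out$third_base)
  rownames(out) <- NULL
  out
}

#' Decide whether a base triplet satisfies a frame's code
#'
#' Tests whether the duplex pair implied by a purine-strand base together with
#' an RNA third-strand base is in the frame's code table. The TTS is read off
#' the purine strand only; a pyrimidine (C or T) there is a hard error, never
#' a silent mismatch, because a valid target site is constrained to pure A/G
#' tracts.
#'
#' @param frame One frame name.
#' @param tts_base Purine-strand DNA base(s), `"A"` or `"G"`.
#' @param tfo_base RNA base(s) over `A`, `C`, `G`, `U`.
#' @return Logical vector: `TRUE` where the triplet conforms to the frame.
#' @export
triplet_matches <- function(frame, tts_base, tfo_base) {
  frame <- match.arg(frame, TRIPLEX_FRAMES)
  tts_base <- as.character(tts_base)
  tfo_base <- as.character(tfo_base)
  bad <- !(tts_base %in% c("A", "G"))
  if (any(bad)) {
    stop(
      "non-purine TTS base ", paste(unique(tts_base[bad]), collapse = ", "),
      ": a triplex target site admits only A and G on the purine strand",
      call. = FALSE
    )
  }
  if (!all(tfo_base %in% c("A", "C", "G", "U"))) {
    stop("TFO base must be one of A, C, G, U", call. = FALSE)
  }
  unname(.frame_third_base[[frame]][tts_base] == tfo_base)
}
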