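# Brute-force reference search. Shares only the triplet code tables with the
# production engine; placement enumeration and the filter rules are coded
# independently (literal, quadratic) so the two paths can cross-check each
# other on small inputs.

.bf_filter_region <- function(df) {
  n <- nrow(df)
  if (n <= 1L) return(df)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$length[j] <= df$length[i]) next
      # err_j <= err_i as exact rationals
      if (df$mismatches[j] * df$length[i] > df$mismatches[i] * df$length[j]) next
      ov_t <- min(df$tts_end0[i], df$tts_end0[j]) -
        max(df$tts_start0[i], df$tts_start0[j])
      ov_f <- min(df$tfo_end0[i], df$tfo_end0[j]) -
        max(df$tfo_start0[i], df$tfo_start0[j])
      shorter <- min(df$length[i], df$length[j])
      if (ov_t > 0 && ov_f > 0 && 2 * ov_t >= shorter && 2 * ov_f >= shorter) {
        drop[i] <- TRUE
        break
      }
    }
  }
  df[!drop, , drop = FALSE]
}

.bf_filter_slides <- function(df) {
  n <- nrow(df)
  if (n <= 1L) return(df)
  key <- paste(df$frame, df$strand, df$mask, df$tts_seq, df$tfo_seq,
               sep = "\r")
  sel <- logical(n)
  for (g in unique(key)) {
    idx <- which(key == g)
    if (length(idx) == 1L) {
      sel[idx] <- TRUE
      next
    }
    anti <- startsWith(df$frame[idx[1L]], "ANTI")
    d <- if (anti) df$tts_start0[idx] + df$tfo_start0[idx]
         else df$tts_start0[idx] - df$tfo_start0[idx]
    if (anyDuplicated(d)) {
      sel[idx] <- TRUE
      next
    }
    idx <- idx[order(d)]
    d <- sort(d)
    brk <- c(0L, which(diff(d) != 1L), length(d))
    for (b in seq_len(length(brk) - 1L)) {
      run <- idx[(brk[b] + 1L):brk[b + 1L]]
      p <- length(run)
      if (p %% 2L == 1L) {
        sel[run[(p + 1L) / 2L]] <- TRUE
      } else {
        sel[run[p / 2L]] <- TRUE
        sel[run[p / 2L + 1L]] <- TRUE
      }
    }
  }
  df[sel, , drop = FALSE]
}

#' Brute-force triplex search (verification oracle)
#'
#' Enumerates every combination of frame, DNA strand, TTS start, TFO start
#' and length; keeps the placements whose target window is a pure purine
#' tract, whose ends are matched, whose mismatch count is within the error
#' budget, and which contain the required consecutive-match run at the
#' required minimum length; then applies region-level domination and
#' sliding-tie resolution literally. Intended for testing only; cost is
#' O(n^2 m^2).
#'
#' @param dna,rna Sequences (records or strings), each at most 60 nt.
#' @param params [search_params()].
#' @return A data.frame with the same columns and ordering as
#'   [search_triplexes()].
#' @export
brute_force_triplexes <- function(dna, rna, params = search_params()) {
  dna <- .as_record(dna, "DNA")
  rna <- .as_record(rna, "RNA")
  if (nchar(dna$residues) > 60L || nchar(rna$residues) > 60L) {
    stop("brute-force mode is limited to sequences of at most 60 nt",
         call. = FALSE)
  }
  R <- strsplit(rna$residues, "", fixed = TRUE)[[1L]]
  m <- length(R)
  req <- params$min_consecutive
  rate <- params$max_error_rate
  rows <- list()
  for (strand in c("+", "-")) {
    pur_str <- if (strand == "+") dna$residues else .revcomp_dna(dna$residues)
    P <- strsplit(pur_str, "", fixed = TRUE)[[1L]]
    n <- length(P)
    is_pur <- P %in% c("A", "G")
    cum_np <- c(0L, cumsum(!is_pur))
    for (frame in TRIPLEX_FRAMES) {
      anti <- frame_orientation(frame) == "ANTIPARALLEL"
      E <- if (anti) rev(R) else R
      tb <- .frame_third_base[[frame]]
      ok_mat <- outer(seq_len(n), seq_len(m), function(i, j) {
        is_pur[i] & (unname(tb[P[i]]) == E[j])
      })
      for (delta in seq.int(-(m - 1L), n - 1L)) {
        A0 <- max(0L, delta)
        B0 <- A0 - delta
        L <- min(n - A0, m - B0)
        if (L < req) next
        vi <- (A0 + 1L):(A0 + L)
        vj <- (B0 + 1L):(B0 + L)
        v <- ok_mat[cbind(vi, vj)]
        pur_ok <- is_pur[vi]
        cs_m <- c(0L, cumsum(!v & pur_ok))     # RNA-side mismatches
        cs_p <- c(0L, cumsum(!pur_ok))         # purity violations
        # q[t]: TRUE when a full run of req matches starts at t
        cs_v <- c(0L, cumsum(v))
        tmaxq <- L - req + 1L
        qrun <- (cs_v[(req + 1L):(L + 1L)] - cs_v[seq_len(tmaxq)]) == req
        cq <- c(0L, cumsum(qrun))
        for (a in seq_len(L - req + 1L)) {
          if (!v[a]) next
          for (b in (a + req - 1L):L) {
            if (!v[b]) next
            if (cs_p[b + 1L] - cs_p[a] > 0L) break  # pyrimidine inside TTS
            mism <- cs_m[b + 1L] - cs_m[a]
            len <- b - a + 1L
            if (mism > rate * len + 1e-9) next
            hi <- b - req + 1L
            if (hi < a || (cq[hi + 1L] - cq[a]) == 0L) next  # no req-run
            pa <- A0 + a - 1L
            pb <- A0 + b - 1L
            ea <- B0 + a - 1L
            eb <- B0 + b - 1L
            if (strand == "+") {
              tts0 <- pa; tts1 <- pb + 1L
            } else {
              tts0 <- n - 1L - pb; tts1 <- n - pa
            }
            if (anti) {
              rna0 <- m - 1L - eb; rna1 <- m - ea
            } else {
              rna0 <- ea; rna1 <- eb + 1L
            }
            rows[[length(rows) + 1L]] <- list(
              strand = strand, frame = frame,
              tts_start0 = tts0, tts_end0 = tts1,
              tfo_start0 = rna0, tfo_end0 = rna1,
              length = len, mismatches = mism,
              mask = paste(as.integer(v[a:b]), collapse = ""),
              tts_seq = paste(P[vi[a:b]], collapse = ""),
              tfo_seq = substring(rna$residues, rna0 + 1L, rna1)
            )
          }
        }
      }
    }
  }
  if (!length(rows)) {
    df <- .empty_candidates()
  } else {
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
    df$dna_id <- dna$id
    df$rna_id <- rna$id
  }
  df <- .bf_filter_region(df)
  df <- .bf_filter_slides(df)
  df <- compute_stats(df)
  if (nrow(df)) {
    o <- order(-df$length, df$mismatches, df$tts_start0, df$frame, df$strand,
               df$tfo_start0)
    df <- df[o, , drop = FALSE]
  }
  out <- data.frame(
    dna_id = if (nrow(df)) df$dna_id else character(),
    rna_id = if (nrow(df)) df$rna_id else character(),
    tts_start = df$tts_start0 + 1L, tts_end = df$tts_end0,
    tts_strand = df$strand,
    tfo_start = df$tfo_start0 + 1L, tfo_end = df$tfo_end0,
    frame = df$frame, length = df$length,
    error_rate_pct = df$error_rate_pct, gu_pct = df$gu_pct,
    tts_seq = df$tts_seq, tfo_seq = df$tfo_seq,
    mismatches = df$mismatches, mask = df$mask,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
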