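.read_one_sequence <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty sequence file: ", path, call. = FALSE)
  if (startsWith(trimws(lines[1L]), ">")) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
    if (length(set) > 1L) {
      warning("multiple records in ", path, "; using the first (",
              names(set)[1L], ")", call. = FALSE)
    }
    id <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
    seq_record(as.character(set[[1L]]), id = id, kind = kind)
  } else {
    seq_record(paste(trimws(lines), collapse = ""),
               id = tools::file_path_sans_ext(basename(path)), kind = kind)
  }
}

#' Read the DNA and RNA input sequences
#'
#' Accepts FASTA or single-sequence plain text; sequences are uppercased, RNA
#' `T` is normalized to `U`, and any character outside the accepted alphabet
#' (DNA: A/C/G/T; RNA: A/C/G/U with T accepted) is an error naming the first
#' offending position. Multi-record files produce a warning and use the first
#' record.
#'
#' @param dna_path Path to the DNA sequence (5'->3').
#' @param rna_path Path to the RNA sequence (5'->3'), or `NULL` for
#'   CpG-only runs.
#' @return List with elements `dna` and `rna` (`rna` is `NULL` when
#'   `rna_path` is).
#' @export
read_sequences <- function(dna_path, rna_path = NULL) {
  dna <- .read_one_sequence(dna_path, "DNA")
  rna <- if (is.null(rna_path)) NULL else .read_one_sequence(rna_path, "RNA")
  list(dna = dna, rna = rna)
}

.report_columns <- c(
  "dna_id", "rna_id", "tts_start", "tts_end", "tts_strand", "tfo_start",
  "tfo_end", "frame", "length", "error_rate_pct", "gu_pct", "tts_seq",
  "tfo_seq", "cpg_island", "cpg_distance_bp"
)

#' Write the triplex and CpG island reports
#'
#' Writes `<prefix>.triplexes.tsv` (one row per hit, 1-based inclusive
#' coordinates, numeric columns with 2 decimals), `<prefix>.tts.bed` and
#' `<prefix>.cpg.bed` (0-based half-open BED intervals; the TTS BED carries
#' the purine strand in its strand column). Output is byte-deterministic for
#' fixed input.
#'
#' @param hits `triplex_hits` data.frame (possibly empty).
#' @param islands [find_cpg_islands()] output or `NULL`.
#' @param out_prefix Path prefix for the output files.
#' @param formats Subset of `c("tsv", "bed")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(hits, islands = NULL, out_prefix = "triplexr",
                         formats = c("tsv", "bed")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (is.null(hits)) hits <- search_triplexes("A", "A")[0, ]
  if (!("cpg_island" %in% names(hits))) {
    hits <- annotate_tts_islands(hits, islands)
  }
  paths <- character(0)
  if ("tsv" %in% formats) {
    tsv <- file.path(paste0(out_prefix, ".triplexes.tsv"))
    rows <- data.frame(
      dna_id = hits$dna_id, rna_id = hits$rna_id,
      tts_start = hits$tts_start, tts_end = hits$tts_end,
      tts_strand = hits$tts_strand,
      tfo_start = hits$tfo_start, tfo_end = hits$tfo_end,
      frame = hits$frame, length = hits$length,
      error_rate_pct = sprintf("%.2f", hits$error_rate_pct),
      gu_pct = sprintf("%.2f", hits$gu_pct),
      tts_seq = hits$tts_seq, tfo_seq = hits$tfo_seq,
      cpg_island = hits$cpg_island,
      cpg_distance_bp = ifelse(is.na(hits$cpg_distance_bp), ".",
                               as.character(hits$cpg_distance_bp)),
      stringsAsFactors = FALSE
    )
    con <- file(tsv, open = "wb")
    writeLines(paste(.report_columns, collapse = "\t"), con)
    if (nrow(rows)) {
      writeLines(do.call(paste, c(unname(as.list(rows)), sep = "\t")), con)
    }
    close(con)
    paths <- c(paths, tsv)
  }
  if ("bed" %in% formats) {
    tts_bed <- paste0(out_prefix, ".tts.bed")
    con <- file(tts_bed, open = "wb")
    if (nrow(hits)) {
      writeLines(sprintf("%s\t%d\t%d\tTTS_%d_%s\t%d\t%s",
                         hits$dna_id, hits$tts_start - 1L, hits$tts_end,
                         seq_len(nrow(hits)), hits$frame, hits$length,
                         hits$tts_strand), con)
    }
    close(con)
    cpg_bed <- paste0(out_prefix, ".cpg.bed")
    con <- file(cpg_bed, open = "wb")
    if (!is.null(islands) && nrow(islands)) {
      writeLines(sprintf("%s\t%d\t%d\tCpG_%d\t%d\t+",
                         if (nrow(hits)) hits$dna_id[1L] else "dna",
                         islands$start - 1L, islands$end,
                         seq_len(nrow(islands)), islands$length_bp), con)
    }
    close(con)
    paths <- c(paths, tts_bed, cpg_bed)
  }
  invisible(paths)
}

#' Parse a triplex TSV report back into a hits table
#'
#' @param path Path to a `.triplexes.tsv` file written by [write_report()].
#' @return data.frame with the report columns; numeric fields parsed back,
#'   `"."` decoded to `NA`.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  for (col in c("tts_start", "tts_end", "tfo_start", "tfo_end", "length")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("error_rate_pct", "gu_pct")) df[[col]] <- as.numeric(df[[col]])
  df$cpg_distance_bp <- suppressWarnings(as.integer(df$cpg_distance_bp))
  df
}
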