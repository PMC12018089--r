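#' Validated sequence record
#'
#' A minimal container for one identified, alphabet-validated nucleotide
#' sequence. Residues are stored uppercase; RNA records normalize `T` to `U`
#' on construction. Any other character (including `N`) is a hard error that
#' names the first offending position.
#'
#' @param residues Character scalar, the sequence 5'->3'.
#' @param id Sequence identifier.
#' @param kind `"DNA"` or `"RNA"`.
#' @return An object of class `seq_record`: a list with fields `id`,
#'   `residues` and `kind`.
#' @export
seq_record <- function(residues, id = "seq", kind = c("DNA", "RNA")) {
  kind <- match.arg(kind)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    stop("residues must be a single character string", call. = FALSE)
  }
  residues <- toupper(residues)
  if (kind == "RNA") residues <- chartr("T", "U", residues)
  if (nchar(residues) == 0L) {
    stop("empty ", kind, " sequence", call. = FALSE)
  }
  alphabet <- if (kind == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% alphabet))
  if (length(bad)) {
    stop(
      sprintf(
        "invalid %s character '%s' at position %d (alphabet: %s)",
        kind, chars[bad[1L]], bad[1L], paste(alphabet, collapse = "/")
      ),
      call. = FALSE
    )
  }
  structure(list(id = id, residues = residues, kind = kind),
            class = "seq_record")
}

#' @rdname seq_record
#' @export
dna_record <- function(residues, id = "dna") seq_record(residues, id, "DNA")

#' @rdname seq_record
#' @export
rna_record <- function(residues, id = "rna") seq_record(residues, id, "RNA")

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf("<%s record '%s': %d nt>\n  %s%s\n",
              x$kind, x$id, n, head, if (n > 60L) "..." else ""))
  invisible(x)
}

# coerce raw strings transparently where a record is expected
.as_record <- function(x, kind) {
  if (inherits(x, "seq_record")) {
    if (x$kind != kind) stop("expected a ", kind, " record", call. = FALSE)
    return(x)
  }
  seq_record(x, id = tolower(kind), kind = kind)
}

.revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.rev_chars <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}
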