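# FASTA input/output for protein records.

#' Read a protein multi-FASTA file
#'
#' Loads every entry of a plain or gzip-compressed protein FASTA file
#' (compression is detected from the file content, not the extension) and
#' normalizes it for scanning: sequences are uppercased, whitespace is
#' removed, and a trailing stop symbol `*` is stripped silently. An
#' internal `*` signals a truncated or mistranslated model and raises an
#' error rather than being guessed around, as does any residue outside
#' the 20-letter alphabet plus `X`.
#'
#' @param path Path to a FASTA file (plain text or gzip).
#' @return A [tibble::tibble] with one row per record and columns `id`
#'   (first whitespace-delimited token of the header), `description`
#'   (remainder of the header, possibly empty), and `sequence`
#'   (normalized residue string). Record order follows the file.
#' @seealso [write_fasta()]
#' @examples
#' path <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 a test protein", "mast*"), path)
#' read_fasta(path)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aa <- Biostrings::readBStringSet(path)
  headers <- names(aa)
  if (is.null(headers) || any(is.na(headers))) {
    stop("Malformed FASTA: missing header line(s) in ", path, call. = FALSE)
  }
  seqs <- unname(toupper(as.character(aa)))
  seqs <- gsub("[[:space:]]", "", seqs)
  seqs <- sub("\\*+$", "", seqs)

  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("Malformed FASTA header at record ",
         which(!nzchar(ids))[1L], " of ", path, call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("Duplicate record id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("Empty sequence after normalization for record(s): ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("\\*", seqs, fixed = FALSE)
  if (any(bad)) {
    stop("Internal stop symbol '*' in record(s): ",
         paste(ids[bad], collapse = ", "),
         " (ambiguous truncation; refusing to guess)", call. = FALSE)
  }
  validate_residues(seqs, ids)

  tibble::tibble(id = ids, description = desc, sequence = seqs)
}

# Error on the first character outside the accepted alphabet, naming the
# record and the offending character.
validate_residues <- function(seqs, ids) {
  pattern <- paste0("[^", paste(AA_ALPHABET_X, collapse = ""), "]")
  hit <- regexpr(pattern, seqs)
  bad <- which(hit > 0L)
  if (length(bad) > 0L) {
    i <- bad[1L]
    ch <- substr(seqs[i], hit[i], hit[i])
    stop("Invalid residue '", ch, "' at position ", hit[i],
         " of record ", ids[i],
         " (allowed: 20 standard amino acids plus X)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write protein records to a FASTA file
#'
#' Round-trip property: `read_fasta(write_fasta(x, path))` reproduces the
#' ids, descriptions, and sequences of `x` exactly.
#'
#' @param records Tibble/data frame with columns `id`, `sequence`, and
#'   optionally `description`, as returned by [read_fasta()].
#' @param path Output file path.
#' @param line_width Positive integer; sequence line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (!is.numeric(line_width) || length(line_width) != 1L || line_width < 1) {
    stop("line_width must be a positive integer", call. = FALSE)
  }
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, headers))
  tryCatch(
    Biostrings::writeXStringSet(set, filepath = path,
                                width = as.integer(line_width)),
    error = function(e) {
      stop("Cannot write FASTA to ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  invisible(path)
}
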