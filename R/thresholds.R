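# Every numeric screening criterion lives in one configurable object.

#' Screening thresholds for HRGP discovery
#'
#' Collects every numeric criterion used anywhere in the scanner into a
#' single validated object, so that no rule is hidden in code. All
#' percentage thresholds are applied to unrounded values with `>=`
#' semantics; rounding happens only in reports.
#'
#' @param past_classical_pct Minimum \%PAST (residues P, A, S, T) for the
#'   classical-AGP composition screen. Default 50.
#' @param past_peptide_pct Minimum \%PAST for the AG-peptide screen,
#'   applied only inside the peptide length window. Default 35.
#' @param peptide_len_min,peptide_len_max AG-peptide length window in
#'   residues (inclusive). Defaults 50 and 90.
#' @param pvkcyt_pct Minimum \%PVKCYT (residues P, V, K, C, Y, T) for the
#'   PRP composition screen. Default 45.
#' @param min_sppp Minimum number of SPPP-type repeats (an S followed by
#'   three or more prolines) for the extensin screen. Default 2.
#' @param min_prp_motif Minimum count of PPVX\[KT\] or KKPCPP repeats for
#'   the PRP motif screens. Default 2.
#' @param short_ext_max_len Exclusive upper length bound for a short
#'   extensin. Default 200.
#' @param long_ext_min_len Exclusive lower length bound for a long
#'   chimeric extensin. Default 2000.
#' @param min_agp_dipeptides Minimum total count of the AGP signature
#'   dipeptides (AP, PA, SP, TP, GP, VP) required on the AGP path.
#'   Default 2.
#' @param dispersion_cutoff Fraction of the sequence that the repeat set
#'   must span for the repeats to be called "distributed" rather than
#'   "localized". Default 0.5.
#' @param cterm_window Number of C-terminal residues searched for the
#'   terminal SPPP / SPPPP+Y features. Default 10.
#' @param lysine_window Window size (residues) for the lysine-rich region
#'   heuristic. Default 20.
#' @param lysine_window_pct Minimum \%K inside that window. Default 35.
#' @return An object of class `hrgp_thresholds` (a named list).
#' @examples
#' th <- hrgp_thresholds()
#' th$past_classical_pct
#' hrgp_thresholds(past_classical_pct = 60)
#' @export
hrgp_thresholds <- function(past_classical_pct = 50,
                            past_peptide_pct = 35,
                            peptide_len_min = 50L,
                            peptide_len_max = 90L,
                            pvkcyt_pct = 45,
                            min_sppp = 2L,
                            min_prp_motif = 2L,
                            short_ext_max_len = 200L,
                            long_ext_min_len = 2000L,
                            min_agp_dipeptides = 2L,
                            dispersion_cutoff = 0.5,
                            cterm_window = 10L,
                            lysine_window = 20L,
                            lysine_window_pct = 35) {
  th <- list(
    past_classical_pct = as.numeric(past_classical_pct),
    past_peptide_pct = as.numeric(past_peptide_pct),
    peptide_len_min = as.integer(peptide_len_min),
    peptide_len_max = as.integer(peptide_len_max),
    pvkcyt_pct = as.numeric(pvkcyt_pct),
    min_sppp = as.integer(min_sppp),
    min_prp_motif = as.integer(min_prp_motif),
    short_ext_max_len = as.integer(short_ext_max_len),
    long_ext_min_len = as.integer(long_ext_min_len),
    min_agp_dipeptides = as.integer(min_agp_dipeptides),
    dispersion_cutoff = as.numeric(dispersion_cutoff),
    cterm_window = as.integer(cterm_window),
    lysine_window = as.integer(lysine_window),
    lysine_window_pct = as.numeric(lysine_window_pct)
  )
  validate_thresholds(th)
  structure(th, class = "hrgp_thresholds")
}

validate_thresholds <- function(th) {
  pct <- c("past_classical_pct", "past_peptide_pct", "pvkcyt_pct",
           "lysine_window_pct")
  for (p in pct) {
    v <- th[[p]]
    if (!is.finite(v) || v < 0 || v > 100) {
      stop(p, " must be a percentage in [0, 100], got ", v, call. = FALSE)
    }
  }
  if (th$peptide_len_min > th$peptide_len_max) {
    stop("peptide_len_min must be <= peptide_len_max", call. = FALSE)
  }
  if (!is.finite(th$dispersion_cutoff) ||
      th$dispersion_cutoff <= 0 || th$dispersion_cutoff > 1) {
    stop("dispersion_cutoff must lie in (0, 1]", call. = FALSE)
  }
  counts <- c("min_sppp", "min_prp_motif", "min_agp_dipeptides")
  for (p in counts) {
    if (is.na(th[[p]]) || th[[p]] < 0L) {
      stop(p, " must be a non-negative count", call. = FALSE)
    }
  }
  lens <- c("peptide_len_min", "peptide_len_max", "short_ext_max_len",
            "long_ext_min_len", "cterm_window", "lysine_window")
  for (p in lens) {
    if (is.na(th[[p]]) || th[[p]] < 1L) {
      stop(p, " must be a positive residue count", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.hrgp_thresholds <- function(x, ...) {
  cat("HRGP screening thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a thresholds configuration file
#'
#' Plain `key = value` text format, one setting per line; `#` starts a
#' comment. Unknown keys are rejected so that a typo cannot silently fall
#' back to a default. Missing keys keep their defaults.
#'
#' @param path Path to the configuration file.
#' @return `read_thresholds()` returns an `hrgp_thresholds` object;
#'   `write_thresholds()` returns `path` invisibly.
#' @examples
#' cfg <- tempfile(fileext = ".conf")
#' write_thresholds(hrgp_thresholds(pvkcyt_pct = 40), cfg)
#' read_thresholds(cfg)$pvkcyt_pct
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) {
    stop("Thresholds file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      stop("Malformed thresholds line: '", ln, "'", call. = FALSE)
    }
    key <- trimws(kv[1L])
    if (!key %in% names(formals(hrgp_thresholds))) {
      stop("Unknown threshold key: '", key, "'", call. = FALSE)
    }
    args[[key]] <- as.numeric(trimws(kv[2L]))
  }
  do.call(hrgp_thresholds, args)
}

#' @param thresholds An `hrgp_thresholds` object to serialize.
#' @rdname read_thresholds
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "hrgp_thresholds"))
  writeLines(sprintf("%s = %s", names(thresholds),
                     vapply(thresholds, format, character(1L))), path)
  invisible(path)
}
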