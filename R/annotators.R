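# Pluggable evidence adapters: signal peptide, GPI anchor, protein
# domains, homology. Real predictions come from external tools imported
# as tables; the built-in heuristics are coarse offline stand-ins and
# are always tagged "heuristic" so reports can distinguish them.

#' Construct an external-evidence record for one protein
#'
#' Evidence never hard-gates a family call (receptor-kinase extensins,
#' for example, genuinely lack signal peptides); it refines subclass
#' calls (domain evidence) and is carried into reports as supporting
#' statements. Every item bears a source tag: `"table"` (imported from
#' an external predictor), `"heuristic"` (built-in approximation),
#' `"mock"` (testing), or `"plugin"`.
#'
#' @param sp_flag Logical; signal peptide predicted.
#' @param sp_pos Integer cleavage position (1-based residue index after
#'   which cleavage occurs) or `NA`.
#' @param sp_source Source tag for the signal-peptide call.
#' @param gpi_flag Logical; GPI anchor addition sequence predicted.
#' @param omega_pos Integer omega-site position or `NA`.
#' @param gpi_source Source tag for the GPI call.
#' @param domains Data frame with columns `name`, `start`, `end`,
#'   `source` (0-based half-open spans), or `NULL`.
#' @param homologs Data frame with columns `subject`, `score`, `source`,
#'   or `NULL`.
#' @return A list of class `hrgp_evidence`.
#' @export
evidence <- function(sp_flag = NA, sp_pos = NA_integer_,
                     sp_source = NA_character_,
                     gpi_flag = NA, omega_pos = NA_integer_,
                     gpi_source = NA_character_,
                     domains = NULL, homologs = NULL) {
  if (is.null(domains)) {
    domains <- data.frame(name = character(0), start = integer(0),
                          end = integer(0), source = character(0))
  }
  if (is.null(homologs)) {
    homologs <- data.frame(subject = character(0), score = numeric(0),
                           source = character(0))
  }
  structure(list(
    signal_peptide = list(flag = sp_flag, pos = sp_pos, source = sp_source),
    gpi_anchor = list(flag = gpi_flag, pos = omega_pos, source = gpi_source),
    domains = domains,
    homologs = homologs
  ), class = "hrgp_evidence")
}

#' Import an evidence table
#'
#' Reads a tab-separated evidence table with header columns `id`,
#' `sp_flag`, `sp_pos`, `gpi_flag`, `omega_pos`, `domain`, `dom_start`,
#' `dom_end`, `homolog`, `score`. One row carries at most one domain and
#' one homolog; repeat the id on additional rows to attach more. Empty
#' fields are permitted everywhere except `id`. All imported items are
#' tagged with source `"table"`.
#'
#' @param path Path to the TSV file.
#' @param records Optional record tibble (from [read_fasta()]); when
#'   given, ids absent from it trigger a warning (not an error) and
#'   positions beyond a sequence's length are errors reported with their
#'   line number.
#' @return Named list mapping protein id to [evidence()] objects.
#' @export
load_evidence_table <- function(path, records = NULL) {
  if (!file.exists(path)) {
    stop("Evidence table not found: ", path, call. = FALSE)
  }
  cols <- c("id", "sp_flag", "sp_pos", "gpi_flag", "omega_pos",
            "domain", "dom_start", "dom_end", "homolog", "score")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(list()) # empty file: empty mapping
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c("", "NA"))
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    stop("Evidence table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seqlen <- NULL
  if (!is.null(records)) {
    seqlen <- stats::setNames(nchar(records$sequence), records$id)
  }
  as_flag <- function(x) {
    if (is.na(x)) NA else toupper(x) %in% c("1", "TRUE", "T", "Y", "YES")
  }
  as_pos <- function(x, line, what) {
    if (is.na(x)) return(NA_integer_)
    v <- suppressWarnings(as.integer(x))
    if (is.na(v)) {
      stop("Line ", line, ": non-integer ", what, " '", x, "'",
           call. = FALSE)
    }
    v
  }
  out <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    line <- i + 1L # header is line 1
    id <- row$id
    if (is.na(id) || !nzchar(id)) {
      stop("Line ", line, ": missing protein id", call. = FALSE)
    }
    sp_pos <- as_pos(row$sp_pos, line, "sp_pos")
    omega <- as_pos(row$omega_pos, line, "omega_pos")
    d_start <- as_pos(row$dom_start, line, "dom_start")
    d_end <- as_pos(row$dom_end, line, "dom_end")
    if (!is.null(seqlen)) {
      if (!id %in% names(seqlen)) {
        warning("Line ", line, ": unknown protein id '", id, "'",
                call. = FALSE)
      } else {
        n <- seqlen[[id]]
        for (p in stats::na.omit(c(sp_pos, omega, d_end))) {
          if (p > n) {
            stop("Line ", line, ": position ", p,
                 " outside sequence of length ", n, " for ", id,
                 call. = FALSE)
          }
        }
      }
    }
    ev <- out[[id]]
    if (is.null(ev)) ev <- evidence()
    if (!is.na(row$sp_flag)) {
      ev$signal_peptide <- list(flag = as_flag(row$sp_flag), pos = sp_pos,
                                source = "table")
    }
    if (!is.na(row$gpi_flag)) {
      ev$gpi_anchor <- list(flag = as_flag(row$gpi_flag), pos = omega,
                            source = "table")
    }
    if (!is.na(row$domain)) {
      ev$domains <- rbind(ev$domains, data.frame(
        name = row$domain,
        start = ifelse(is.na(d_start), 0L, d_start),
        end = ifelse(is.na(d_end), 0L, d_end),
        source = "table"))
    }
    if (!is.na(row$homolog)) {
      score <- suppressWarnings(as.numeric(row$score))
      ev$homologs <- rbind(ev$homologs, data.frame(
        subject = row$homolog,
        score = ifelse(is.na(score), NA_real_, score),
        source = "table"))
    }
    out[[id]] <- ev
  }
  out
}

HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Coarse built-in signal-peptide heuristic
#'
#' A deliberately simple secretory-signal approximation for running the
#' pipeline fully offline: the flag is true when the first 30 residues
#' contain a run of at least six consecutive hydrophobic residues
#' (A, C, F, I, L, M, V, W) that begins after at least one non-acidic
#' N-terminal residue. The guessed cleavage position is the end of the
#' run plus three residues. Results are tagged `"heuristic"` and are no
#' substitute for a dedicated signal-peptide predictor; import real
#' predictions with [load_evidence_table()] when available.
#'
#' @inheritParams composition_profile
#' @return List with `flag` (logical), `pos` (1-based cleavage guess or
#'   `NA`), and `source = "heuristic"`. Sequences shorter than 15
#'   residues return `flag = FALSE`.
#' @export
heuristic_signal_peptide <- function(sequence) {
  check_sequence(sequence)
  res <- list(flag = FALSE, pos = NA_integer_, source = "heuristic")
  if (nchar(sequence) < 15L) return(res)
  head30 <- substr(sequence, 1L, 30L)
  pat <- paste0("[", paste(HYDROPHOBIC_SET, collapse = ""), "]{6,}")
  m <- regexpr(pat, head30)
  if (m == -1L || m == 1L) return(res) # need >= 1 N-terminal residue first
  lead <- substr(head30, 1L, m - 1L)
  if (grepl("[DE]", lead)) return(res) # acidic leader disqualifies
  run_end <- as.integer(m) + attr(m, "match.length") - 1L
  pos <- min(run_end + 3L, nchar(sequence))
  list(flag = TRUE, pos = pos, source = "heuristic")
}

SMALL_OMEGA_SET <- c("A", "G", "S", "N", "D", "C")

#' Coarse built-in GPI-anchor heuristic
#'
#' Offline stand-in for a GPI-anchor predictor: the flag is true when at
#' least 8 of the final 15 residues are hydrophobic and a small residue
#' (A, G, S, N, D, C) occurs 15 to 25 positions from the C-terminus (the
#' candidate omega site). Tagged `"heuristic"`; import real predictions
#' when available.
#'
#' @inheritParams composition_profile
#' @return List with `flag`, `pos` (1-based candidate omega position or
#'   `NA`), `source = "heuristic"`. Sequences shorter than 25 residues
#'   return `flag = FALSE`.
#' @export
heuristic_gpi <- function(sequence) {
  check_sequence(sequence)
  res <- list(flag = FALSE, pos = NA_integer_, source = "heuristic")
  n <- nchar(sequence)
  if (n < 25L) return(res)
  tail15 <- strsplit(substr(sequence, n - 14L, n), "", fixed = TRUE)[[1L]]
  if (sum(tail15 %in% HYDROPHOBIC_SET) < 8L) return(res)
  # candidate omega: small residue 15-25 positions from the C-terminus
  cand <- seq(max(1L, n - 24L), n - 14L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hit <- cand[chars[cand] %in% SMALL_OMEGA_SET]
  if (length(hit) == 0L) return(res)
  list(flag = TRUE, pos = hit[1L], source = "heuristic")
}

#' Annotate records with the built-in heuristics
#'
#' Convenience wrapper running [heuristic_signal_peptide()] and
#' [heuristic_gpi()] over a record tibble, producing an evidence map
#' usable by [classify_proteome()]. Heuristic provenance is preserved.
#'
#' @param records Record tibble from [read_fasta()].
#' @return Named list of [evidence()] objects.
#' @export
heuristic_evidence <- function(records) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    s <- records$sequence[i]
    sp <- heuristic_signal_peptide(s)
    gpi <- heuristic_gpi(s)
    evidence(sp_flag = sp$flag, sp_pos = sp$pos, sp_source = sp$source,
             gpi_flag = gpi$flag, omega_pos = gpi$pos,
             gpi_source = gpi$source)
  })
  stats::setNames(out, records$id)
}
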