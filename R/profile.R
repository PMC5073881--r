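# Composition statistics and motif search primitives.
#
# Coordinates are 0-based, half-open everywhere: a span (start, end)
# covers sequence positions start .. end-1.

AA_STANDARD20 <- setdiff(AA_ALPHABET_X, "X")
PAST_SET <- c("P", "A", "S", "T")
PVKCYT_SET <- c("P", "V", "K", "C", "Y", "T")
AGP_DIPEPTIDES <- c("AP", "PA", "SP", "TP", "GP", "VP")

# Class of any standard residue; excludes X so an unknown residue can
# never complete a motif.
RESIDUE_CLASS <- paste0("[", paste(AA_STANDARD20, collapse = ""), "]")

# Fasciclin H1-domain consensus used to recognize fasciclin-like AGPs.
FASCICLIN_PATTERN <-
  "[MALIT]T[VILS][FLCM][CAVT][PVLIS][GSTKRNDPEIV]+[DNS][DSENAGE]+[ASQM]"

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  invisible(sequence)
}

# gregexpr wrapper returning a 0-based half-open span matrix.
motif_spans <- function(sequence, pattern, fixed = FALSE, perl = !fixed) {
  m <- gregexpr(pattern, sequence, fixed = fixed, perl = perl)[[1L]]
  if (m[1L] == -1L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  len <- attr(m, "match.length")
  cbind(start = as.integer(m) - 1L, end = as.integer(m) - 1L + len)
}

#' Amino-acid composition profile of a protein
#'
#' Exact residue tallies on the full-length sequence (including any
#' signal peptide; no mature-chain correction is applied). `X` residues
#' count toward the length denominator but toward no residue-set
#' numerator.
#'
#' @param sequence Normalized protein sequence (single string).
#' @return A list of class `hrgp_composition` with elements `length`,
#'   `residue_fractions` (named over the 20 standard residues plus X,
#'   summing to 1), `pct_past`, and `pct_pvkcyt` (both unrounded
#'   percentages of the full length).
#' @examples
#' composition_profile("PASTGG")$pct_past # 4 of 6 residues
#' @export
composition_profile <- function(sequence) {
  check_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  len <- length(chars)
  counts <- table(factor(chars, levels = AA_ALPHABET_X))
  structure(list(
    length = len,
    residue_fractions = stats::setNames(as.numeric(counts) / len,
                                        AA_ALPHABET_X),
    pct_past = 100 * sum(counts[PAST_SET]) / len,
    pct_pvkcyt = 100 * sum(counts[PVKCYT_SET]) / len
  ), class = "hrgp_composition")
}

# Maximal S+P runs: each S followed by a maximal run of >= 3 prolines.
# Greedy regex matching yields exactly the maximal run per anchor.
sp_run_spans <- function(sequence) {
  spans <- motif_spans(sequence, "SP{3,}")
  cbind(spans, k = if (nrow(spans)) spans[, "end"] - spans[, "start"] - 1L
                  else integer(0))
}

#' Count extensin S+P repeat runs by proline tier
#'
#' Finds every serine followed by a maximal run of `k >= 3` consecutive
#' prolines and tallies the runs by tier: `k = 3` (SP3), `k = 4` (SP4),
#' and `k >= 5` (SP5). Runs with fewer than three prolines are ignored;
#' an anchor is counted once, in its highest applicable tier, so e.g.
#' `SPPPPPPP` contributes a single SP5 run.
#'
#' @inheritParams composition_profile
#' @return Named integer vector `c(sp3, sp4, sp5)`.
#' @examples
#' sp_run_tiers("SPPPSPPPPP") # one SP3 run and one SP5 run
#' @export
sp_run_tiers <- function(sequence) {
  check_sequence(sequence)
  k <- sp_run_spans(sequence)[, "k"]
  c(sp3 = sum(k == 3L), sp4 = sum(k == 4L), sp5 = sum(k >= 5L))
}

#' Count non-overlapping occurrences of a literal motif
#'
#' Left-to-right non-overlapping matching, so `SPPPSPPP` holds two SPPP
#' motifs while `SPPPPPPP` holds only one (a single S anchor).
#'
#' @inheritParams composition_profile
#' @param motif Non-empty literal motif string.
#' @return Integer count.
#' @export
count_motif <- function(sequence, motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    stop("motif must be a non-empty string", call. = FALSE)
  }
  if (!nzchar(sequence)) return(0L)
  nrow(motif_spans(sequence, motif, fixed = TRUE))
}

#' Count PPVX\[KT\] repeats
#'
#' Non-overlapping occurrences of the proline-rich-protein repeat
#' P-P-V-x-(K or T), where x is any standard residue (`X`-unknown is
#' excluded from the wildcard slot).
#'
#' @inheritParams composition_profile
#' @return Integer count.
#' @examples
#' count_ppvxkt("PPVAKPPVGT") # 2
#' @export
count_ppvxkt <- function(sequence) {
  check_sequence(sequence)
  nrow(ppvxkt_spans(sequence))
}

ppvxkt_spans <- function(sequence) {
  motif_spans(sequence, paste0("PPV", RESIDUE_CLASS, "[KT]"))
}

#' Scan for the fasciclin-domain consensus
#'
#' Matches the ten-class fasciclin H1 consensus pattern
#' `[MALIT]T[VILS][FLCM][CAVT][PVLIS][GSTKRNDPEIV]+[DNS][DSENAGE]+[ASQM]`
#' with standard backtracking regular-expression semantics; leftmost
#' non-overlapping matches are reported. A protein is a fasciclin-like
#' AGP candidate if at least one span is found.
#'
#' @inheritParams composition_profile
#' @return Integer matrix with columns `start` and `end` (0-based,
#'   half-open), one row per match; zero rows when there is no match.
#' @examples
#' fasciclin_scan("MTVFCPGDSA")
#' @export
fasciclin_scan <- function(sequence) {
  check_sequence(sequence)
  motif_spans(sequence, FASCICLIN_PATTERN, perl = TRUE)
}

#' Count the AGP signature dipeptides
#'
#' Sliding-window counts of AP, PA, SP, TP, GP, and VP: every position
#' `i` with `sequence[i:i+2]` equal to the dipeptide is counted, so
#' `APAP` holds two AP and one PA. (Hetero-dimers cannot self-overlap,
#' so non-overlapping and sliding-window counts coincide.)
#'
#' @inheritParams composition_profile
#' @return Named integer vector over `c("AP","PA","SP","TP","GP","VP")`.
#' @export
dipeptide_counts <- function(sequence) {
  check_sequence(sequence)
  vapply(AGP_DIPEPTIDES,
         function(d) nrow(motif_spans(sequence, d, fixed = TRUE)),
         integer(1L))
}

dipeptide_spans <- function(sequence) {
  spans <- lapply(AGP_DIPEPTIDES, function(d) {
    motif_spans(sequence, d, fixed = TRUE)
  })
  do.call(rbind, spans)
}

#' Count YXY cross-linking motifs
#'
#' Positions where a tyrosine is followed, two residues later, by
#' another tyrosine; the middle residue may be any standard residue
#' ("X" in the motif name is a wildcard, but an unknown `X` residue does
#' not qualify). Occurrences are counted position-wise, so overlaps
#' count: `YVYVY` holds two.
#'
#' @inheritParams composition_profile
#' @return Integer count.
#' @export
yxy_count <- function(sequence) {
  check_sequence(sequence)
  m <- gregexpr(paste0("(?=Y", RESIDUE_CLASS, "Y)"), sequence,
                perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

yxy_spans <- function(sequence) {
  m <- gregexpr(paste0("(?=Y", RESIDUE_CLASS, "Y)"), sequence,
                perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = as.integer(m) - 1L, end = as.integer(m) + 2L)
}

#' C-terminal repeat features
#'
#' Two flags read near the C-terminus: `cterm_sppp`, true when an SPPP
#' motif starts within the final `window` residues (the hallmark of the
#' PR peptides); and `cterm_sp4or5_plus_y`, true when an SPPPP or SPPPPP
#' motif starts within that window and at least one tyrosine occurs at
#' or after the motif start (a feature of classical extensins).
#'
#' @inheritParams composition_profile
#' @param window Number of C-terminal residues inspected; must be >= 4.
#' @return Named logical vector
#'   `c(cterm_sppp, cterm_sp4or5_plus_y)`.
#' @export
cterm_features <- function(sequence, window = 10L) {
  check_sequence(sequence)
  if (!is.numeric(window) || window < 4L) {
    stop("window must be >= 4 residues", call. = FALSE)
  }
  len <- nchar(sequence)
  lo <- len - as.integer(window) # 0-based start must be >= lo
  starts_of <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), sequence, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  sppp <- starts_of("SPPP")
  sp45 <- starts_of("SPPPP")
  y <- starts_of("Y")
  sp45_y <- any(vapply(sp45, function(s) s >= lo && any(y >= s),
                       logical(1L)))
  c(cterm_sppp = any(sppp >= lo), cterm_sp4or5_plus_y = sp45_y)
}

#' Span fraction and distributed/localized call for a repeat set
#'
#' The dispersion of a set of motif spans is the fraction of the
#' sequence between the first and last matched residue:
#' `(max(end) - min(start)) / length`. Repeats are called "distributed"
#' when the fraction reaches `cutoff`, "localized" otherwise. This makes
#' the qualitative distinction between classical and chimeric family
#' members explicit and configurable.
#'
#' @param spans Integer matrix with columns `start`, `end` (0-based,
#'   half-open); at least one row.
#' @param length Sequence length in residues.
#' @param cutoff Distributed/localized boundary fraction in (0, 1].
#' @return List with `span_fraction` and logical `is_distributed`.
#' @examples
#' repeat_dispersion(rbind(c(10, 14), c(85, 89)), 100)
#' @export
repeat_dispersion <- function(spans, length, cutoff = 0.5) {
  spans <- rbind(spans)
  if (nrow(spans) < 1L) {
    stop("dispersion is undefined without spans", call. = FALSE)
  }
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  frac <- (max(spans[, 2L]) - min(spans[, 1L])) / length
  list(span_fraction = frac, is_distributed = frac >= cutoff)
}

#' Locate a lysine-rich region
#'
#' First fixed-size window whose lysine fraction reaches `pct`\%, used to
#' separate the lysine-rich classical AGPs from the other classical
#' AGPs. This is an explicit heuristic: the subclass is recognized in
#' the literature by sequence inspection rather than by a published
#' numeric rule, so the window and percentage are surfaced here as
#' tunable parameters and the call is flagged as heuristic in reports.
#'
#' @inheritParams composition_profile
#' @param window Window size in residues (>= 5).
#' @param pct Minimum lysine percentage within the window.
#' @return Integer vector `c(start, end)` (0-based, half-open) of the
#'   first qualifying window, or `NULL` when none exists (including when
#'   the sequence is shorter than the window).
#' @export
lysine_rich_region <- function(sequence, window = 20L, pct = 35) {
  check_sequence(sequence)
  if (!is.numeric(window) || window < 5L) {
    stop("window must be >= 5 residues", call. = FALSE)
  }
  window <- as.integer(window)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (window > n) return(NULL)
  isk <- as.integer(chars == "K")
  cs <- c(0L, cumsum(isk))
  # counts of K in windows [i, i+window), i = 0 .. n-window (0-based)
  counts <- cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]
  ok <- which(counts * 100 >= pct * window)
  if (length(ok) == 0L) return(NULL)
  start <- ok[1L] - 1L
  c(start = start, end = start + window)
}

#' Full motif annotation for one protein
#'
#' Runs every motif primitive once and collects the results into a
#' single annotation object used by the classifier and the reports.
#'
#' @inheritParams composition_profile
#' @param thresholds An [hrgp_thresholds()] object supplying the
#'   C-terminal window and lysine-window settings.
#' @return A list of class `hrgp_motifs` with counts (`sp3_count`,
#'   `sp4_count`, `sp5_count`, `sppp_count`, `spppp_count`,
#'   `dipeptide_counts`, `yxy_count`, `ppvxkt_count`, `kkpcpp_count`,
#'   `pplp_count`, `pelpk_count`), C-terminal flags, the lysine-rich
#'   window (or NULL), and 0-based half-open `spans` per named motif
#'   family (`sp_runs`, `dipeptides`, `fasciclin`, `ppvxkt`, `kkpcpp`,
#'   `pplp`, `pelpk`, `yxy`).
#' @export
annotate_motifs <- function(sequence, thresholds = hrgp_thresholds()) {
  check_sequence(sequence)
  sp <- sp_run_spans(sequence)
  tiers <- c(sp3 = sum(sp[, "k"] == 3L),
             sp4 = sum(sp[, "k"] == 4L),
             sp5 = sum(sp[, "k"] >= 5L))
  dip <- dipeptide_counts(sequence)
  spans <- list(
    sp_runs = sp[, c("start", "end"), drop = FALSE],
    dipeptides = dipeptide_spans(sequence),
    fasciclin = fasciclin_scan(sequence),
    ppvxkt = ppvxkt_spans(sequence),
    kkpcpp = motif_spans(sequence, "KKPCPP", fixed = TRUE),
    pplp = motif_spans(sequence, "PPLP", fixed = TRUE),
    pelpk = motif_spans(sequence, "PELPK", fixed = TRUE),
    yxy = yxy_spans(sequence)
  )
  ct <- cterm_features(sequence, thresholds$cterm_window)
  structure(list(
    length = nchar(sequence),
    sp3_count = unname(tiers["sp3"]),
    sp4_count = unname(tiers["sp4"]),
    sp5_count = unname(tiers["sp5"]),
    sppp_count = unname(sum(tiers)),
    spppp_count = unname(tiers["sp4"] + tiers["sp5"]),
    dipeptide_counts = dip,
    dipeptide_total = sum(dip),
    yxy_count = yxy_count(sequence),
    ppvxkt_count = nrow(spans$ppvxkt),
    kkpcpp_count = nrow(spans$kkpcpp),
    pplp_count = nrow(spans$pplp),
    pelpk_count = nrow(spans$pelpk),
    cterm_sppp = unname(ct["cterm_sppp"]),
    cterm_sp4or5_plus_y = unname(ct["cterm_sp4or5_plus_y"]),
    lysine_region = lysine_rich_region(sequence, thresholds$lysine_window,
                                       thresholds$lysine_window_pct),
    spans = spans
  ), class = "hrgp_motifs")
}
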