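# Rule-based classification of screened proteins into the HRGP
# family/subclass taxonomy, with an explicit evidence trail.

HRGP_FAMILIES <- c("AGP", "EXT", "PRP", "HYBRID_AGP_EXT", "NONE")

HRGP_SUBCLASSES <- c(
  "classical AGP", "lysine-rich classical AGP", "AG peptide", "FLA",
  "PAG", "other chimeric AGP",
  "classical EXT", "short EXT", "LRX", "PERK", "FH EXT",
  "long chimeric EXT", "other chimeric EXT",
  "PRP", "PR peptide (PPLP)", "PR peptide (PELPK)", "PR peptide (other)",
  "chimeric PRP", "hybrid AGP/EXT", "unresolved-chimeric", "none"
)

SCREEN_NAMES <- c("PAST50", "PAST35_PEPTIDE", "FASCICLIN", "SPPP2",
                  "PVKCYT45", "PPVXKT2", "KKPCPP2")

#' Run the seven independent composition/motif screens on one protein
#'
#' Each screen fires independently of the others; a protein may fire
#' several. The screens (with their default thresholds) are:
#' \describe{
#'   \item{PAST50}{>= 50\% of residues in \{P, A, S, T\}, any length
#'     (classical-AGP composition screen).}
#'   \item{PAST35_PEPTIDE}{50-90 residues long and >= 35\% PAST
#'     (AG-peptide screen).}
#'   \item{FASCICLIN}{at least one fasciclin-consensus match.}
#'   \item{SPPP2}{at least two S+P(>=3) repeat runs (extensin screen).}
#'   \item{PVKCYT45}{>= 45\% of residues in \{P, V, K, C, Y, T\}
#'     (PRP composition screen).}
#'   \item{PPVXKT2}{at least two PPVX\[KT\] repeats.}
#'   \item{KKPCPP2}{at least two KKPCPP repeats (retained although some
#'     proteomes yield no hits).}
#' }
#' Thresholds are compared with `>=` on unrounded percentages.
#'
#' @param sequence Normalized protein sequence.
#' @param thresholds An [hrgp_thresholds()] object.
#' @param profile,motifs Optional precomputed [composition_profile()] /
#'   [annotate_motifs()] results for this sequence (recomputed when
#'   omitted).
#' @return Character vector: the subset of screens that fired.
#' @export
screen_protein <- function(sequence, thresholds = hrgp_thresholds(),
                           profile = NULL, motifs = NULL) {
  if (is.null(profile)) profile <- composition_profile(sequence)
  if (is.null(motifs)) motifs <- annotate_motifs(sequence, thresholds)
  fired <- character(0)
  if (profile$pct_past >= thresholds$past_classical_pct) {
    fired <- c(fired, "PAST50")
  }
  if (profile$length >= thresholds$peptide_len_min &&
      profile$length <= thresholds$peptide_len_max &&
      profile$pct_past >= thresholds$past_peptide_pct) {
    fired <- c(fired, "PAST35_PEPTIDE")
  }
  if (nrow(motifs$spans$fasciclin) >= 1L) fired <- c(fired, "FASCICLIN")
  if (motifs$sppp_count >= thresholds$min_sppp) fired <- c(fired, "SPPP2")
  if (profile$pct_pvkcyt >= thresholds$pvkcyt_pct) {
    fired <- c(fired, "PVKCYT45")
  }
  if (motifs$ppvxkt_count >= thresholds$min_prp_motif) {
    fired <- c(fired, "PPVXKT2")
  }
  if (motifs$kkpcpp_count >= thresholds$min_prp_motif) {
    fired <- c(fired, "KKPCPP2")
  }
  fired
}

domain_matches <- function(domains, pattern) {
  nrow(domains) > 0L && any(grepl(pattern, domains$name, ignore.case = TRUE))
}

# Dispersion of a span set, or NULL when the set is empty.
span_dispersion <- function(spans, length, cutoff) {
  if (is.null(spans) || nrow(spans) == 0L) return(NULL)
  repeat_dispersion(spans[, c("start", "end"), drop = FALSE], length, cutoff)
}

#' Classify one protein into the HRGP taxonomy
#'
#' Applies the decision workflow to the per-protein screens, repeat
#' dispersion, and optional external evidence:
#' \enumerate{
#'   \item a fasciclin-consensus match makes the protein a fasciclin-like
#'     AGP (FLA) regardless of composition;
#'   \item a protein firing both an AGP composition screen (with the
#'     dipeptide requirement met) and the extensin screen, with its
#'     repeats distributed, is a hybrid AGP/EXT;
#'   \item the extensin path resolves long chimeric EXTs (length above
#'     the long bound), domain-evidenced chimeras (leucine-rich repeat
#'     to LRX, protein kinase to PERK, formin homology to FH EXT), other
#'     chimeras (localized repeats or a non-HRGP domain), short EXTs,
#'     and classical EXTs;
#'   \item the AGP path requires the signature dipeptides, then resolves
#'     plastocyanin AGPs (domain evidence), other chimeric AGPs, AG
#'     peptides (length window), lysine-rich classical AGPs, and
#'     classical AGPs;
#'   \item the PRP path resolves chimeric PRPs (localized repeats), PR
#'     peptides (short, sub-tagged by PPLP/PELPK repeat content), and
#'     PRPs;
#'   \item a protein firing no screen is NONE.
#' }
#' When AGP and PRP screens both fire, a density tie-break decides the
#' path: signature dipeptides without PPVX\[KT\]/KKPCPP repeats argue
#' for AGP, and when both motif systems are dense the protein is flagged
#' `"ambiguous AGP/PRP"` and assigned by the larger length-normalized
#' count. Signal-peptide and GPI evidence are recorded as supporting
#' statements and ambiguity flags only, never as hard gates (receptor
#' kinase extensins legitimately lack signal peptides). Domain-dependent
#' chimeric subclasses degrade to `"unresolved-chimeric"` when no domain
#' evidence is available.
#'
#' @param id Protein identifier (used in the result and consistency
#'   checks).
#' @param sequence Normalized protein sequence.
#' @param thresholds An [hrgp_thresholds()] object.
#' @param evidence An [evidence()] object for this protein, or `NULL`.
#' @param profile,motifs Optional precomputed profile/annotation.
#' @return A list of class `hrgp_classification`: `id`, `family`,
#'   `subclass`, `criteria_fired`, `flags`, `evidence_notes` (data frame
#'   of source/statement pairs), `dispersion` (span fraction of the
#'   family repeat set, or `NA`), plus the `profile` and `motifs` used.
#' @examples
#' classify_protein("toy", strrep("APAPSATPAS", 12))$subclass
#' @export
classify_protein <- function(id, sequence,
                             thresholds = hrgp_thresholds(),
                             evidence = NULL,
                             profile = NULL, motifs = NULL) {
  if (is.null(profile)) profile <- composition_profile(sequence)
  if (is.null(motifs)) motifs <- annotate_motifs(sequence, thresholds)
  if (profile$length != nchar(sequence) ||
      motifs$length != nchar(sequence)) {
    stop("profile/motifs were not derived from this sequence (id ", id, ")",
         call. = FALSE)
  }
  fired <- screen_protein(sequence, thresholds, profile, motifs)
  len <- profile$length
  cutoff <- thresholds$dispersion_cutoff
  flags <- character(0)
  notes <- data.frame(source = character(0), statement = character(0))

  note <- function(source, statement) {
    notes <<- rbind(notes, data.frame(source = source, statement = statement))
  }
  if (!is.null(evidence)) {
    sp <- evidence$signal_peptide
    if (isTRUE(sp$flag)) {
      note(sp$source, sprintf("signal peptide predicted (cleavage %s)",
                              ifelse(is.na(sp$pos), "unknown", sp$pos)))
    } else if (identical(sp$flag, FALSE)) {
      note(sp$source, "no signal peptide predicted")
      flags <- c(flags, "no signal peptide")
    }
    gpi <- evidence$gpi_anchor
    if (isTRUE(gpi$flag)) {
      note(gpi$source, sprintf("GPI anchor addition sequence (omega %s)",
                               ifelse(is.na(gpi$pos), "unknown", gpi$pos)))
    }
    if (nrow(evidence$domains) > 0L) {
      note(evidence$domains$source[1L],
           paste("domains:", paste(unique(evidence$domains$name),
                                   collapse = ", ")))
    }
    if (nrow(evidence$homologs) > 0L) {
      note(evidence$homologs$source[1L],
           paste("homologs:", paste(utils::head(evidence$homologs$subject, 5L),
                                    collapse = ", ")))
    }
  }
  domains <- if (is.null(evidence)) NULL else evidence$domains
  has_domain_info <- !is.null(domains)
  non_hrgp_domain <- has_domain_info && nrow(domains) > 0L

  agp_screen <- any(c("PAST50", "PAST35_PEPTIDE") %in% fired)
  ext_screen <- "SPPP2" %in% fired
  prp_screen <- any(c("PVKCYT45", "PPVXKT2", "KKPCPP2") %in% fired)
  dip_ok <- motifs$dipeptide_total >= thresholds$min_agp_dipeptides

  sp_disp <- span_dispersion(motifs$spans$sp_runs, len, cutoff)
  dip_disp <- span_dispersion(motifs$spans$dipeptides, len, cutoff)
  prp_spans <- rbind(motifs$spans$ppvxkt, motifs$spans$kkpcpp,
                     motifs$spans$pplp, motifs$spans$pelpk)
  prp_disp <- span_dispersion(prp_spans, len, cutoff)

  result <- function(family, subclass, dispersion = NA_real_) {
    structure(list(
      id = id, family = family, subclass = subclass,
      criteria_fired = fired, flags = flags, evidence_notes = notes,
      dispersion = dispersion, profile = profile, motifs = motifs
    ), class = "hrgp_classification")
  }

  # (1) fasciclin consensus wins outright
  if ("FASCICLIN" %in% fired) {
    return(result("AGP", "FLA",
                  span_dispersion(motifs$spans$fasciclin, len, cutoff)$
                    span_fraction))
  }

  # AGP-vs-PRP tie-break (shared P/T make double fires common)
  take_agp <- agp_screen
  if (agp_screen && prp_screen) {
    prp_motifs <- motifs$ppvxkt_count + motifs$kkpcpp_count
    if (dip_ok && prp_motifs == 0L) {
      take_agp <- TRUE
    } else if (dip_ok && prp_motifs >= thresholds$min_prp_motif) {
      flags <- c(flags, "ambiguous AGP/PRP")
      take_agp <- motifs$dipeptide_total >= prp_motifs
    } else {
      take_agp <- FALSE
    }
  }

  # (2) hybrid: both AGP and EXT definitions satisfied, repeats spread
  if (agp_screen && dip_ok && ext_screen &&
      !is.null(sp_disp) && sp_disp$is_distributed &&
      !is.null(dip_disp) && dip_disp$is_distributed) {
    return(result("HYBRID_AGP_EXT", "hybrid AGP/EXT",
                  sp_disp$span_fraction))
  }

  # (3) extensin path
  if (ext_screen) {
    disp <- sp_disp$span_fraction
    if (len > thresholds$long_ext_min_len) {
      return(result("EXT", "long chimeric EXT", disp))
    }
    if (domain_matches(domains, "LRR|leucine[- ]rich")) {
      return(result("EXT", "LRX", disp))
    }
    if (domain_matches(domains, "kinase")) {
      return(result("EXT", "PERK", disp))
    }
    if (domain_matches(domains, "FH2|formin")) {
      return(result("EXT", "FH EXT", disp))
    }
    if (!sp_disp$is_distributed || non_hrgp_domain) {
      if (!has_domain_info && !sp_disp$is_distributed) {
        flags <- c(flags, "chimeric EXT candidate without domain evidence")
        return(result("EXT", "unresolved-chimeric", disp))
      }
      return(result("EXT", "other chimeric EXT", disp))
    }
    if (len < thresholds$short_ext_max_len) {
      return(result("EXT", "short EXT", disp))
    }
    return(result("EXT", "classical EXT", disp))
  }

  # (4) AGP path (requires the signature dipeptides)
  if (agp_screen && take_agp && dip_ok) {
    disp <- dip_disp$span_fraction
    if (domain_matches(domains, "plastocyanin|Cu[_ -]?bind")) {
      return(result("AGP", "PAG", disp))
    }
    if (non_hrgp_domain || !dip_disp$is_distributed) {
      if (!has_domain_info) {
        flags <- c(flags, "chimeric AGP candidate without domain evidence")
        return(result("AGP", "unresolved-chimeric", disp))
      }
      return(result("AGP", "other chimeric AGP", disp))
    }
    if (len >= thresholds$peptide_len_min &&
        len <= thresholds$peptide_len_max) {
      return(result("AGP", "AG peptide", disp))
    }
    if (!is.null(motifs$lysine_region)) {
      flags <- c(flags, "lysine-rich call is heuristic")
      return(result("AGP", "lysine-rich classical AGP", disp))
    }
    return(result("AGP", "classical AGP", disp))
  }

  # (5) PRP path
  if (prp_screen) {
    disp <- if (is.null(prp_disp)) NA_real_ else prp_disp$span_fraction
    localized <- !is.null(prp_disp) && !prp_disp$is_distributed
    if (localized) {
      return(result("PRP", "chimeric PRP", disp))
    }
    if (len <= thresholds$short_ext_max_len) {
      sub <-
        if (motifs$pplp_count > 0L &&
            motifs$pplp_count >= motifs$pelpk_count) {
          "PR peptide (PPLP)"
        } else if (motifs$pelpk_count > 0L) {
          "PR peptide (PELPK)"
        } else {
          "PR peptide (other)"
        }
      return(result("PRP", sub, disp))
    }
    return(result("PRP", "PRP", disp))
  }

  # (6) nothing fired, or gates unmet after firing
  if (length(fired) > 0L) {
    flags <- c(flags,
               paste("screen hit rejected:",
                     paste(fired, collapse = "+"),
                     "without family gates"))
  }
  result("NONE", "none")
}

#' Screen a whole proteome
#'
#' Runs the seven screens over every record and returns, per screen, the
#' exact id set and its cardinality. Sets may overlap: one protein can
#' fire several screens.
#'
#' @param records Record tibble from [read_fasta()].
#' @param thresholds An [hrgp_thresholds()] object.
#' @return List with `sets` (named list of id vectors, one per screen)
#'   and `counts` (named integer vector of set sizes, same order).
#' @export
screen_proteome <- function(records, thresholds = hrgp_thresholds()) {
  sets <- stats::setNames(
    lapply(SCREEN_NAMES, function(s) character(0)), SCREEN_NAMES)
  for (i in seq_len(nrow(records))) {
    fired <- screen_protein(records$sequence[i], thresholds)
    for (s in fired) sets[[s]] <- c(sets[[s]], records$id[i])
  }
  list(sets = sets,
       counts = vapply(sets, length, integer(1L)))
}

#' Classify a whole proteome
#'
#' Applies [classify_protein()] to every record and collects the results
#' in a per-protein inventory tibble (one row per input record, input
#' order preserved). Classification is deterministic: identical records,
#' thresholds, and evidence always give identical output.
#'
#' @param records Record tibble from [read_fasta()].
#' @param thresholds An [hrgp_thresholds()] object.
#' @param evidence Named list mapping protein id to [evidence()]
#'   objects (e.g. from [load_evidence_table()] or
#'   [heuristic_evidence()]), or `NULL`.
#' @return A [tibble::tibble] with columns `id`, `family`, `subclass`,
#'   `criteria_fired` (list column), `flags` (list column), `length`,
#'   `pct_past`, `pct_pvkcyt`, `dipeptides` (AP/PA/SP/TP/GP/VP string),
#'   `sp_tiers` (SP3/SP4/SP5 string), `yxy`, `dispersion`,
#'   `signal_peptide`, `sp_source`, `gpi`, `gpi_source`, and
#'   `evidence_notes` (list column).
#' @export
classify_proteome <- function(records, thresholds = hrgp_thresholds(),
                              evidence = NULL) {
  n <- nrow(records)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- records$id[i]
    ev <- if (is.null(evidence)) NULL else evidence[[id]]
    cl <- classify_protein(id, records$sequence[i], thresholds, ev)
    dip <- cl$motifs$dipeptide_counts
    ev_sp <- if (is.null(ev)) list(flag = NA, source = NA_character_) else
      ev$signal_peptide
    ev_gpi <- if (is.null(ev)) list(flag = NA, source = NA_character_) else
      ev$gpi_anchor
    rows[[i]] <- tibble::tibble(
      id = id,
      family = cl$family,
      subclass = cl$subclass,
      criteria_fired = list(cl$criteria_fired),
      flags = list(cl$flags),
      length = cl$profile$length,
      pct_past = cl$profile$pct_past,
      pct_pvkcyt = cl$profile$pct_pvkcyt,
      dipeptides = paste(dip, collapse = "/"),
      sp_tiers = paste(c(cl$motifs$sp3_count, cl$motifs$sp4_count,
                         cl$motifs$sp5_count), collapse = "/"),
      yxy = cl$motifs$yxy_count,
      dispersion = cl$dispersion,
      signal_peptide = ev_sp$flag,
      sp_source = ev_sp$source,
      gpi = ev_gpi$flag,
      gpi_source = ev_gpi$source,
      evidence_notes = list(cl$evidence_notes)
    )
  }
  do.call(rbind, rows)
}
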