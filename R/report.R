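# Rendering of screen summaries and per-protein inventories, plus the
# run manifest. All rounding happens here, at the presentation layer.

#' Round half up
#'
#' Presentation-layer rounding used for the percentage columns of the
#' inventory (66.5 becomes 67), as opposed to R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Summarize a classification run
#'
#' Per-subclass (and per-family) counts over a finished run. Counts are
#' conserved: the subclass totals, including `none`, sum to the number
#' of classified records; no protein is counted twice.
#'
#' @param results Inventory tibble from [classify_proteome()].
#' @return A [tibble::tibble] with columns `family`, `subclass`, `n`,
#'   covering every subclass observed (including `none`).
#' @export
summarize_results <- function(results) {
  if (nrow(results) == 0L) {
    return(tibble::tibble(family = character(0), subclass = character(0),
                          n = integer(0)))
  }
  agg <- stats::aggregate(list(n = results$id),
                          by = list(family = results$family,
                                    subclass = results$subclass),
                          FUN = length)
  agg <- agg[order(match(agg$family, HRGP_FAMILIES),
                   match(agg$subclass, HRGP_SUBCLASSES)), ]
  tibble::as_tibble(agg)
}

#' Per-screen count summary
#'
#' @param screens Result of [screen_proteome()].
#' @return A [tibble::tibble] with columns `screen` and `n`.
#' @export
summarize_screens <- function(screens) {
  tibble::tibble(screen = names(screens$counts),
                 n = unname(screens$counts))
}

# Flatten list columns for the TSV inventory.
format_inventory <- function(results) {
  tibble::tibble(
    id = results$id,
    family = results$family,
    subclass = results$subclass,
    dipeptides = results$dipeptides,
    pct_past = round_half_up(results$pct_past),
    pct_pvkcyt = round_half_up(results$pct_pvkcyt),
    length = results$length,
    sp_tiers = results$sp_tiers,
    yxy = results$yxy,
    dispersion = ifelse(is.na(results$dispersion), "",
                        sprintf("%.3f", results$dispersion)),
    signal_peptide = flag_with_source(results$signal_peptide,
                                      results$sp_source),
    gpi = flag_with_source(results$gpi, results$gpi_source),
    criteria_fired = vapply(results$criteria_fired, paste,
                            character(1L), collapse = "+"),
    flags = vapply(results$flags, paste, character(1L), collapse = "; "),
    evidence = vapply(results$evidence_notes, function(e) {
      if (nrow(e) == 0L) "" else
        paste(sprintf("[%s] %s", e$source, e$statement), collapse = "; ")
    }, character(1L))
  )
}

flag_with_source <- function(flag, source) {
  out <- ifelse(is.na(flag), "", ifelse(flag, "Y", "N"))
  ifelse(nzchar(out) & !is.na(source), paste0(out, " (", source, ")"), out)
}

#' Write the per-protein inventory as TSV
#'
#' Stable column order, deterministic row order (input order), UTF-8.
#' Percentages are rounded half-up to integers here only; re-running on
#' identical input produces a byte-identical file.
#'
#' @param results Inventory tibble from [classify_proteome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(results, path) {
  tab <- format_inventory(results)
  tryCatch(
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) {
      stop("Cannot write inventory to ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the thresholds, the input checksum, any seed, and the package
#' version, so a run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param thresholds The [hrgp_thresholds()] used.
#' @param input Optional input FASTA path (checksummed when given).
#' @param seed Optional integer seed (synthetic runs).
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, thresholds = hrgp_thresholds(),
                           input = NULL, seed = NULL, extra = NULL) {
  manifest <- list(
    tool = "hrgpscan",
    version = as.character(utils::packageVersion("hrgpscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    thresholds = unclass(thresholds)
  )
  if (!is.null(input)) {
    manifest$input <- list(path = input,
                           md5 = unname(tools::md5sum(input)))
  }
  if (!is.null(seed)) manifest$seed <- seed
  if (!is.null(extra)) manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full scan pipeline on a proteome
#'
#' read -> profile -> screen -> classify -> report: the one-call surface
#' behind the command-line `scan` subcommand. Candidate lists (per
#' screen), the per-protein inventory, the subclass summary, and the
#' manifest are written to `out_dir` when it is given.
#'
#' @param input Path to a protein FASTA file, or a record tibble.
#' @param thresholds An [hrgp_thresholds()] object.
#' @param evidence Named list of [evidence()] objects, or a path to an
#'   evidence TSV, or `NULL`.
#' @param out_dir Output directory (created if missing), or `NULL` to
#'   skip writing.
#' @return List with `records`, `screens`, `results` (inventory tibble),
#'   and `summary`; invisibly when `out_dir` is given.
#' @export
scan_proteome <- function(input, thresholds = hrgp_thresholds(),
                          evidence = NULL, out_dir = NULL) {
  records <- if (is.data.frame(input)) input else read_fasta(input)
  if (is.character(evidence)) {
    evidence <- load_evidence_table(evidence, records)
  }
  screens <- screen_proteome(records, thresholds)
  results <- classify_proteome(records, thresholds, evidence)
  summary <- summarize_results(results)
  out <- list(records = records, screens = screens, results = results,
              summary = summary)
  if (is.null(out_dir)) return(out)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cand <- do.call(rbind, lapply(names(screens$sets), function(s) {
    ids <- screens$sets[[s]]
    if (length(ids) == 0L) NULL else data.frame(screen = s, id = ids)
  }))
  if (is.null(cand)) cand <- data.frame(screen = character(0),
                                        id = character(0))
  utils::write.table(cand, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_inventory(results, file.path(out_dir, "inventory.tsv"))
  utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"), thresholds,
                 input = if (is.character(input)) input else NULL)
  invisible(out)
}
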