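#' The amino-acid alphabet accepted by the scanner
#'
#' The 20 standard residues plus `X` for an unknown residue. `X` counts
#' toward sequence length but never toward a residue-set percentage or a
#' motif match, so an uncertain residue can never push a protein over a
#' screening threshold.
#'
#' @format Character vector of 21 single letters.
#' @export
AA_ALPHABET_X <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)
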