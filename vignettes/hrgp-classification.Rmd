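---
title: "Screening and classifying hydroxyproline-rich glycoproteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and classifying hydroxyproline-rich glycoproteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrgpscan)
```

## The biological problem

Hydroxyproline-rich glycoproteins (HRGPs) are a plant cell-wall protein
superfamily with three families whose members are recognizable from
primary sequence alone, because their post-translational fate (proline
hydroxylation and glycosylation) is dictated by the arrangement of
proline in the backbone:

* **Arabinogalactan-proteins (AGPs)** carry *non-contiguous* prolines in
  signature dipeptides (AP, PA, SP, TP, GP, VP) within a strongly biased
  composition of P, A, S, and T ("PAST").
* **Extensins (EXTs)** carry *contiguous* prolines in SPPP / SPPPP /
  SPPPPP repeats (the SP3/SP4/SP5 tiers) and often tyrosine YXY motifs
  used for intermolecular cross-linking.
* **Proline-rich proteins (PRPs)** show a P, V, K, C, Y, T ("PVKCYT")
  composition bias or carry PPVX[KT] / KKPCPP repeats.

Each family has short forms (AG peptides, short EXTs, PR peptides),
chimeric forms in which an HRGP-like region is fused to an unrelated
domain (fasciclin-like AGPs, plastocyanin AGPs, leucine-rich-repeat
extensins, proline-rich receptor kinases, formin-homology extensins,
chimeric PRPs), and hybrid forms satisfying two family definitions at
once. `hrgpscan` implements the whole screening and rule-based
classification layer: it takes any protein FASTA and produces a
per-protein inventory with an explicit evidence trail.

## The screens

Seven independent screens are applied to every protein
(`screen_protein()`), each governed by a named entry of
`hrgp_thresholds()`:

| screen | rule | default |
|---|---|---|
| PAST50 | %PAST at or above the classical-AGP bound, any length | 50% |
| PAST35_PEPTIDE | %PAST at or above the peptide bound, length within the peptide window | 35%, 50–90 aa |
| FASCICLIN | at least one match of the ten-class fasciclin consensus | 1 |
| SPPP2 | number of S+P(&ge;3) runs | 2 |
| PVKCYT45 | %PVKCYT at or above the PRP bound | 45% |
| PPVXKT2 | PPVX[KT] repeat count | 2 |
| KKPCPP2 | KKPCPP repeat count (kept although some proteomes yield none) | 2 |

Percentages are computed on the **full** sequence, including any signal
peptide, with no mature-chain correction, and thresholds are compared
with `>=` on **unrounded** values. The greater-or-equal convention
matters at the boundary: published inventories include a classical AGP
at exactly the nominal PAST bound, so a strict `>` would lose real
family members. Rounding to integer percentages happens only in the
report layer (`write_inventory()`), half-up, to match the way such
tables are conventionally printed.

Counting conventions, stated once and used everywhere:

* Coordinates are 0-based and half-open.
* An S+P run is an S followed by a *maximal* run of k consecutive
  prolines; k = 3, 4, and &ge;5 feed the SP3/SP4/SP5 tiers. One anchor
  counts once — `SPPPPPPP` is a single SP5 run, and the SPPP screening
  count is the number of anchors with k &ge; 3, so an SPPPPP never
  counts twice. Comparisons on SPPPP repeats use the tier union
  (k &ge; 4).
* Literal motif counts (`count_motif()`) are non-overlapping,
  left-to-right. Dipeptide counts are sliding-window position counts
  (the hetero-dimers cannot self-overlap, so the two conventions
  coincide there). YXY is counted position-wise and may overlap
  (`YVYVY` holds two).
* `X` (unknown residue) counts toward length but never toward a
  composition numerator, a motif match, or the wildcard slots of
  PPVX[KT] and YXY. An uncertain residue can therefore never push a
  protein over a threshold.
* The fasciclin consensus
  `[MALIT]T[VILS][FLCM][CAVT][PVLIS][GSTKRNDPEIV]+[DNS][DSENAGE]+[ASQM]`
  is matched with ordinary backtracking regular-expression semantics,
  leftmost non-overlapping. The test suite checks it against an
  independent backtracking matcher written directly over the class
  lists.

## Distributed versus localized repeats

The distinction between a classical family member and a chimeric one is
whether its repeats occur "throughout the protein" or only in a
localized region. That published criterion is qualitative, so the
package makes it explicit and tunable: the **dispersion** of a repeat
set is the fraction of the sequence between the first and the last
matched residue, `(max end - min start) / length`
(`repeat_dispersion()`), and repeats are called distributed when the
fraction reaches `dispersion_cutoff` (default 0.5). The fraction is
carried into every report row so a reader can re-draw the line without
re-running the scan. A protein whose repeats are localized but for
which no domain evidence is configured is reported as
`unresolved-chimeric` rather than being forced into a named chimeric
subclass.

## The decision workflow

`classify_protein()` applies the rules in a fixed order; every result
carries the screens that fired, ambiguity flags, and the evidence
statements used.

1. A fasciclin-consensus match makes the protein an FLA outright —
   FLAs typically sit below the PAST bound, which is why the consensus
   exists.
2. A protein that satisfies the AGP definition (composition screen plus
   the dipeptide requirement) *and* the EXT definition, with repeats
   distributed, is a **hybrid AGP/EXT**. The dipeptide requirement is
   included here deliberately: the AGP definition is composition *plus*
   dipeptide repeats, and without it any PAST-rich extensin would be
   promoted to hybrid.
3. The EXT path: above the long-chimera length bound (default
   2000 aa) the protein is a long chimeric EXT; domain evidence then
   resolves LRX (leucine-rich repeat), PERK (protein kinase), and FH
   EXT (formin homology); localized repeats or a non-HRGP domain make
   it an (other/unresolved) chimeric EXT; below 200 aa it is a short
   EXT; otherwise a classical EXT.
4. The AGP path requires at least `min_agp_dipeptides` signature
   dipeptides. Plastocyanin domain evidence gives PAG; a non-HRGP
   domain or localized dipeptides give a chimeric AGP; the 50–90 aa
   window gives an AG peptide (taking precedence over the classical
   label, matching published inventories where every 50–90 aa AGP is a
   peptide); a lysine-rich window gives the lysine-rich classical AGP;
   otherwise classical AGP.
5. The PRP path: localized repeats give a chimeric PRP; length at or
   below 200 aa gives a PR peptide, sub-tagged PPLP / PELPK / other by
   repeat content (ties go to PPLP, the more prevalent repeat); longer
   proteins are PRPs. The 200-aa boundary reuses the short-extensin
   length threshold: published PR peptides (97–198 aa) and PRPs
   (214–554 aa) leave a gap that 200 splits cleanly, and housing the
   boundary in an existing threshold keeps every numeric criterion in
   one object.
6. Proteins that fired a screen but failed the family gates stay in the
   output as family `NONE` with an explanatory flag — the automated
   layer surfaces candidates, it does not adjudicate them away.

When the AGP and PRP screens both fire (their residue sets share P and
T, so this is common), a density tie-break decides the path: signature
dipeptides with no PPVX[KT]/KKPCPP repeats argue AGP; when both motif
systems are dense the protein is flagged `ambiguous AGP/PRP` and the
larger count (both are normalized by the same length) assigns the
family. The flag is always kept — the distinction between these
families is genuinely blurry, and downstream curation should see that.

Signal-peptide and GPI-anchor evidence is never a hard gate: PERKs are
real extensins without signal peptides. These predictions are recorded
as supporting statements and ambiguity flags in the report.

## Evidence adapters and the built-in heuristics

Real signal-peptide, GPI, domain, and homology predictions come from
dedicated external tools; `load_evidence_table()` imports their results
from a simple TSV (columns `id`, `sp_flag`, `sp_pos`, `gpi_flag`,
`omega_pos`, `domain`, `dom_start`, `dom_end`, `homolog`, `score`),
tagging every item with source `"table"`. So the pipeline can run fully
offline, `heuristic_signal_peptide()` and `heuristic_gpi()` provide
deliberately coarse approximations (an N-terminal hydrophobic-run rule
and a C-terminal hydrophobic-tail/omega-site rule). They are always
tagged `"heuristic"`, their tags survive into the reports, and no test
or acceptance quantity treats them as equivalent to the real
predictors. Classification output is invariant to the *source tag* of
otherwise identical evidence — provenance is metadata.

## The synthetic proteome generator

`synth_proteome()` exists so that every stage is testable without any
download. For each planted class it builds sequences whose gates hold
by construction — PAST-rich dipeptide blocks for classical AGPs, a
70%-K 20-mer for the lysine-rich class, length-sampled 50–90 aa
peptides at ~40% PAST, an embedded consensus instance for FLAs,
SPPPP/SPPP blocks interleaved evenly (distributed) or confined to the
N-terminus (chimeric) for extensins, PPVEK / PPLP / PELPK repeat blocks
with PVKCYT-rich spacers for the PRP classes (PR peptides get the
C-terminal SPPP), and blocks satisfying both the AGP and EXT
definitions for hybrids. Decoys are drawn uniformly from the twelve
residues outside both composition sets (and lacking T, so the fasciclin
consensus cannot arise); every planted record is verified post hoc by
running the classifier, every decoy by running the screens, with
bounded regeneration on collision. A single integer seed fixes the
output byte-for-byte and the caller's random state is left untouched.

Default study conditions (chosen once): 10 classical AGPs, 4
lysine-rich AGPs, 10 AG peptides, 8 FLAs, 6 classical EXTs, 8 short
EXTs, 5 kinase-type chimeric EXTs, 6 PRPs, 8 PPLP and 4 PELPK PR
peptides, 3 hybrids, and 150 decoys — 222 proteins with the class
ratios loosely shaped like a real dicot HRGP inventory and decoys
dominating, as in a real proteome. These sizes keep the full test suite
and the acceptance script fast while exercising every decision branch.

What the generator deliberately does **not** emulate: realistic
background composition (decoys are flat over a restricted alphabet, so
near-threshold false positives are rarer than in a real proteome),
splice variants, sequencing artifacts (`X` runs, truncations), and
domain architecture beyond the planted motifs. Perfect recovery on
synthetic data therefore demonstrates that the rules are implemented
correctly and are mutually consistent — not that the thresholds are
optimal for any particular organism.

## Numerical and degenerate-input choices

* Thresholds are validated on construction (percentages in [0,100],
  window bounds ordered, dispersion cutoff in (0,1]); unknown keys in a
  config file are errors, so a typo cannot silently revert a setting.
* Empty sequences, internal `*` stop symbols, duplicate ids, and
  residues outside the 20+X alphabet are loud errors at load time;
  a trailing `*` is stripped silently.
* `repeat_dispersion()` is undefined without spans and refuses to be
  called that way; the classifier treats a motif-free PRP composition
  hit as distributed (there is no localization evidence against it).
* The lysine-rich window uses integer cross-multiplication
  (`count * 100 >= pct * window`) so exact boundary cases (7 K in 20 at
  35%) cannot be lost to floating-point rounding.
* PR-peptide sub-tagging ties (a protein with both PPLP and PELPK
  repeats) go to PPLP.

## Known limitations

* The regression against the published poplar screen totals requires
  the pinned Phytozome proteome file, which is license-gated and not
  redistributable with the package; the corresponding test runs the
  full check when the file is supplied locally and reports failure
  otherwise.
* The built-in signal-peptide and GPI heuristics are coarse stand-ins;
  conclusions about secretion or anchoring should rest on imported
  predictions from the dedicated tools.
* The classifier reproduces the *automated* screening and rule layer.
  Published curated inventories additionally use homology searches and
  manual judgment to rescue family members that fail the screens
  (evidence-recruited rows); this package flags ambiguity rather than
  adjudicating it.

## A worked example

```{r example}
ps <- synth_proteome(synth_spec(seed = 7))
run <- scan_proteome(ps$records, hrgp_thresholds(),
                     evidence = synth_mock_evidence(ps))
run$summary
```

All planted families and subclasses are recovered, and the 150 decoys
are reported as `none`:

```{r recovery}
truth <- ps$truth[match(run$results$id, ps$truth$id), ]
mean(run$results$family == truth$family) * 100
mean(run$results$subclass == truth$subclass) * 100
```
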