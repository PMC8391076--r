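---
title: "Charge decoration and like-charge regions in disordered protein sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge decoration and like-charge regions in disordered protein sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrscan)
```

## The model

Intrinsically disordered proteins (IDPs) owe much of their conformational
behaviour to charged residues — not just how many there are (the fractions
`f+` of K/R and `f−` of D/E) but how they are arranged along the chain. FG
nucleoporins, the disordered proteins that form the permeability barrier of
the nuclear pore complex, carry a distinctive arrangement: an extended
subsequence with very few charges, all of them positive, typically near the
N-terminus. `lcrscan` quantifies such arrangements through **like-charge
regions (LCRs)**.

An LCR is a maximal stretch of sequence whose charged residues are all of
one sign. The scanner walks the per-position charge classification
(K, R positive; D, E negative; everything else — including histidine, whose
protonation state we do not model — neutral) and emits one region per
maximal same-sign run of charged positions. Two span conventions exist in
the field's informal descriptions:

* **first-to-last charge** (the default): the span runs from the run's
  first to its last charged residue, inclusive. Trailing neutral residues
  before the next opposite charge are not counted. On
  `KAKGSKTKGDNADQSDP` this yields a positive LCR of length 8 with 4
  charges followed by a negative LCR of length 7 with 3 charges.
* **extend-to-opposite** (`extend_to_opposite = TRUE`): the region
  continues up to, but excluding, the next opposite-sign charge, terminal
  runs running to the sequence end.

The default reproduces the canonical worked example above; the alternative
is provided as an explicit switch and the two are never silently mixed.

```{r}
scan_lcrs(seq_records("ex", "KAKGSKTKGDNADQSDP"))
```

Each LCR carries its **charge content** (charges divided by span length).
Length-1 and length-2 LCRs are always produced by the scanner — this keeps
the conservation invariant that per-sign charge counts sum to the profile
totals — and are removed only by explicit filtering. The conventional
filter keeps LCRs *strictly longer than* 2 residues (`min_length = 2`
means length ≥ 3), matching the "greater than two amino acids" phrasing
used for this kind of analysis.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_length` | 2 (strict) | LCR length filter before ranking, scatter and coverage |
| `lplcr_min_length` | 200 aa | DETECT-mode lpLCR length threshold |
| `lplcr_mode` | `"detect"` | `"detect"` flags only long lpLCRs; `"longest"` takes each protein's longest positive LCR unconditionally |
| `fg_threshold` | 0.15 FG/AA (strict) | FG-Nup candidacy filter on FG-dipeptide density |
| `disorder_threshold` | 0.30 (strict) | FG-Nup candidacy filter on disordered fraction |
| `covered_min_lengths` | 2, 20, 40 | thresholds for the coverage histograms |
| `outlier_threshold` | 200 aa | scatter outlier boundary |

The lpLCR has no single formal definition in the field; two operational
notions are therefore exposed rather than conflated. DETECT answers "does
this protein carry an exceptionally long positive LCR?" and is what the
outlier analyses use; LONGEST answers "which LCR do we remove in the
exclusion re-analysis?" and always exists when a protein has any qualifying
positive LCR. The 200-residue boundary is a parameter, not a hard-coded
conclusion. Candidacy thresholds are strict inequalities, mirroring the
`>` convention of the selection filters.

Rank ties (two positive LCRs of equal length) are broken by start position,
ascending — a deterministic choice where the field's descriptions are
silent.

## Handling of inputs

Coordinates are 1-based inclusive everywhere. Disordered-region annotation
tables are normalised on read: rows are validated (`1 ≤ start ≤ end`,
within the sequence) and overlapping or bookended rows of one protein are
merged into maximal non-overlapping regions (idempotently). Proteins with
several disordered regions are analysed per region by default, preserving
region identity; `extract_regions(..., concatenate = TRUE)` pools them into
one analysis unit per protein when per-protein statistics are preferred.
Ambiguity codes (B, J, O, U, X, Z) are accepted and treated as neutral,
non-F, non-G residues; a strict mode rejects them. Disorder fractions are
computed against the full-protein length when full sequences are supplied;
otherwise the analysed record's own length is the denominator.

FG-motif density counts exact `FG` dipeptides (which cannot self-overlap)
per residue; FxFG/GLFG variants are not counted separately, because the
candidacy filter is defined purely in FG/AA.

## Numerical choices

Boxplot statistics use linear-interpolation quantiles
(`stats::quantile(type = 7)`) and Tukey whiskers (most extreme observations
within 1.5 IQR of the quartiles; outliers beyond). The quartile method is
recorded in each summary's `params` so comparisons can verify parameter
compatibility; `compare_datasets()` refuses summaries computed under
different parameters. Standard deviations are sample (n − 1) by default
with a population option. Dataset comparisons are descriptive only — no
hypothesis tests are attached, since the contrasts of interest are
magnitude contrasts (means, ranges, outlier fractions), not significance
claims.

Degenerate inputs are defined rather than accidental: a chargeless
sequence yields an empty LCR table; a protein whose LCRs all fail the
length filter contributes no scatter point and is omitted from
longest-LCR means; coverage of 100% falls in the closed top histogram bin.

## The synthetic generator

The generator emulates the two charge-architecture archetypes the analysis
contrasts, with full ground truth:

* **DisProt-like** (`disprot_config()`): each position independently
  carries a positive charge with probability `f+ = 0.10`, a negative
  charge with probability `f− = 0.10`, or a neutral residue drawn
  uniformly from the 16 neutral canonical residues; lengths are
  `N(300, 80)` clamped at 30. Independent-per-position placement is the
  simplest model consistent with describing datasets by their charge
  densities; real disordered regions have compositional biases and
  correlations it does not attempt to capture.
* **FG-Nup-like** (`fgnup_config()`): an N-terminal planted lpLCR segment
  (length `N(150, 30)` clamped at 20, positive charges only at density
  0.03) followed by a charge-rich segment with DisProt-like fractions;
  total length `N(450, 60)`. FG dipeptides are written into neutral filler
  pairs until the sequence reaches 0.20 FG/AA — above the 0.15 candidacy
  filter, as real FG Nups are.

Two constructions make the planted truth *exact* rather than approximate:
the planted segment's endpoints are forced to be charged, so the truth span
coincides with the scanner's first-to-last-charge convention; and the
charge-rich segment opens with a negative charge, so the planted span
cannot silently extend into the tail's leading positive charges. Both are
synthetic-design conveniences that make recovery exactly testable — they
are not claims about FG-Nup biology, where the boundary between the two
segments is gradual.

Reproducibility: one global seed drives a per-sequence substream derived
from `(seed, index)`, so datasets are byte-identical across runs and stable
under out-of-order generation.

What passing recovery tests show — and what they do not: on generator
output, the scanner recovers planted spans with zero length bias and unit
overlap, and DETECT-mode false positives on DisProt-like material are rare
(well under 1%). This validates the pipeline's correctness on data matching
its own model assumptions; it does not by itself establish how sharp the
lpLCR/background separation is in real proteomes, where charge placement is
not independent per position.

## Problem sizes

The shipped test suite exercises the scanner against a brute-force
enumerator on 1000 random sequences (lengths 1–300, charge densities
spanning 0–1), recovery on 500 FG-Nup-like sequences with matched 500
DisProt-like controls, and exclusion re-analysis on 200 + 200 sequences —
sizes at which the stochastic checks are stable under their fixed seeds
while the whole suite runs in about a minute.

## Known limitations

* Charge classification is pH-independent; histidine is always neutral and
  phosphomimetic or modified residues are not modelled.
* Disorder annotations are consumed, never predicted; running a disorder
  predictor is out of scope.
* The generator's two-segment construction is an emulation of a
  qualitative description, not an evolutionary or biophysical model of how
  lpLCRs arise.
* Dataset comparison is descriptive; users wanting inferential statements
  should take the per-protein tables and apply their own tests.
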