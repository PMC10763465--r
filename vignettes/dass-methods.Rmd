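---
title: "Methods: defined approaches for skin sensitization in dassr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defined approaches for skin sensitization in dassr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dassr)
```

## Scientific background

Skin sensitization follows a well-characterized adverse outcome pathway:
covalent binding of an electrophilic chemical to skin proteins (key event
1), keratinocyte activation (key event 2), and dendritic-cell activation
(key event 3), culminating in T-cell-mediated allergic contact dermatitis.
Three validated non-animal methods map onto these key events:

* **DPRA** (direct peptide reactivity assay, KE1): percent depletion of
  synthetic cysteine- and lysine-containing peptides. Quantitative
  endpoints: `%Cys`, `%Lys` depletion.
* **KeratinoSens** (KE2): an ARE-Nrf2 luciferase reporter assay, consumed
  here as a binary sensitizer/non-sensitizer call.
* **h-CLAT** (human cell line activation test, KE3): CD86/CD54 induction in
  THP-1 cells; the quantitative endpoint is the minimum induction threshold
  (MIT, µg/mL), the lowest concentration eliciting a positive outcome.

No single assay replaces the in vivo reference tests; *defined approaches*
(DAs) combine them with fixed data interpretation procedures. This package
implements the three internationally harmonized DAs for this endpoint —
2o3, the KE 3/1 sequential testing strategy, and the integrated testing
strategy — exactly as decision rules over harmonized inputs, together with
the surrounding machinery a batch user needs: tabular input in TSV/CSV/XLSX
with all cells treated as text until validated, tolerant column mapping
against a canonical template, machine-readable validation flags,
contingency-table evaluation against reference data, and a seeded synthetic
data generator.

## Decision rules and their constants

All numeric decision constants live in
`inst/extdata/guideline_constants.yaml`, each with units, an explicit
boundary direction, and the guideline document it was transcribed from (the
DPRA and h-CLAT test guidelines and the DA guideline's scoring annex). They
are configuration, not tunables; the file's md5 checksum is embedded in
every ITS rationale trace so a result can always be tied to the exact
tables in force. The test suite contains a second, independently coded
transcription of every table (plain lookup vectors and `findInterval`
calls) and requires cell-for-cell agreement, so a transcription slip in
either copy fails the build rather than shipping.

**DPRA hazard call** (used by 2o3 and STS when no call column is bound):
negative iff mean(%Cys, %Lys) ≤ 6.38; with %Cys only, negative iff
%Cys ≤ 13.89. %Lys alone has no published model and stays missing. Both
boundaries are "≤ threshold → negative", so a mean of exactly 6.38 is
negative.

**STS**: MIT ≤ 10 µg/mL → GHS 1A; any other numeric MIT → 1B; h-CLAT
negative defers to the DPRA call (positive → 1B, negative → NC); h-CLAT
missing → inconclusive (the sequence cannot start). A positive h-CLAT call
without a numeric MIT is a conclusive sensitizer with *inconclusive*
potency — the 1A/1B split requires the quantitative MIT. We restrict the
`1*` notation to ITS, where it is defined by the two-source lookup table.

**ITS component scores**: h-CLAT MIT ≤ 10 → 3, (10, 150] → 2,
(150, 5000] → 1, negative outcome → 0. DPRA mean depletion ≥ 42.47 → 3,
[22.62, 42.47) → 2, [6.38, 22.62) → 1, < 6.38 → 0; Cys-only bands 98.24 /
23.09 / 13.89. In silico: positive → 1, negative → 0; an out-of-domain
prediction is not a usable information source and scores missing. Note the
deliberate asymmetry inherited from the guidelines: a mean depletion of
exactly 6.38 scores ITS point 1 while the DPRA hazard call at the same
value is negative; the two tables use opposite boundary directions and we
transcribe both verbatim rather than harmonizing them.

**ITS totals**: with three sources, 6–7 → 1A, 2–5 → 1B, 0–1 → NC. With two
sources, 6 → 1A, 5 → `1*`, 2–4 → 1B, 1 → inconclusive, 0 → NC. The
two-source cells follow from robustness to the missing source where the
guideline resolves them: a total of 5 is conclusively a sensitizer but
could be 1A or 1B once the third source arrives, and a total of 1 cannot
separate 1B from NC. Fewer than two sources is always inconclusive
("insufficient sources"). Hazard is derived from potency (1A/1B/`1*` →
sensitizer, NC → non-sensitizer).

## Harmonization and precedence

Raw cells are parsed by case-insensitive lexicons (documented in
`?parse_call`, `?parse_mit`). Two derivations are performed: the DPRA mean
and call from quantitative depletion, and the h-CLAT call from the MIT cell
(numeric → positive, negative-outcome token → negative). When a bound user
call column disagrees with the call derived from quantitative data, the
derived call wins and a `CALL_CONFLICT` warning is raised: the quantitative
endpoints are the DAs' primary inputs, and silently preferring a
transcription over the measurement it summarizes would be the wrong
default. Whether a user call should ever override the derivation is
genuinely open; we chose the quantitative side and made the disagreement
visible rather than configurable.

An in silico prediction with unknown applicability-domain status is used
(only an explicit "out" disables it): domain columns are frequently absent
from legacy tables, and treating absence as "out" would silently disable
the source for whole datasets.

## Validation and blocking policy

Every problem is a flag, never an exception: `DUPLICATE_BINDING`,
`MISSING_REQUIRED_COLUMN`, `NON_NUMERIC`, `UNRECOGNIZED_CALL_TOKEN`
(ERROR); `OUT_OF_RANGE`, `EMPTY_CELL`, `TAB_IN_CELL`, `CALL_CONFLICT`
(WARNING). Batch use needs an unattended policy, so severities are fixed:
ERROR cells are masked to missing and block only the (chemical, DA) pairs
whose own inputs they touch and that end inconclusive as a result; WARNING
never blocks. The plausible ranges (depletion in [−100, 100] %, MIT in
(0, 5000] µg/mL, the h-CLAT guideline's testing ceiling) warn rather than
block because the assays' source documents define no rejection ranges;
negative measured depletion is preserved, not clamped. A numeric MIT above
5000 µg/mL still scores in the weakest positive ITS band — the value is
implausible (and flagged) but a positive outcome at some concentration was
observed.

Two deliberate edge choices in input handling: a header-only file parses to
a valid zero-row table (so the data template round-trips through every
format), and only a file with no content at all is an "empty table" error;
and the TSV dialect forbids tabs inside cells (they are flagged and, on
write, replaced by a space) because an unquoted tab-delimited format cannot
represent them.

## The synthetic-data generator

`generate_fixture()` emulates a user upload on the canonical template:
depletions uniform over [−5, 100] % (small negative values occur in real
DPRA runs), MIT log-uniform over (0.1, 5000] µg/mL with a 0.3 probability
of a negative h-CLAT, call columns written consistently with the
quantitative data, independent 5 % per-cell missingness, and Bernoulli(0.5)
calls for endpoints with no quantitative counterpart. Reference columns
follow the consensus of the generated assays (2o3 consensus for hazard, the
ITS category for potency) flipped at a 10 % rate, emulating an imperfect
external reference such as the historical murine assay. Corrupted cells are
injected at a stated rate with every location and expected flag code
recorded in a ledger, which makes validation completeness testable as exact
multiset equality.

Expected predictions are computed by a third routine
(`R/fixture_oracle.R`): a transcription of all decision rules as plain
nested conditionals with its own literal thresholds, sharing no code or
configuration with the engine. End-to-end tests require engine and oracle
to agree on every record, clean or defective.

What the generator does *not* emulate: correlation between assays induced
by true chemical potency (endpoints are sampled independently, so
inter-assay concordance is lower than in real data); borderline-range
variability around assay thresholds; laboratory-specific formatting quirks
beyond the injected defect types. Passing tests therefore demonstrate that
the rules, plumbing, and flag policy are implemented correctly — not that
the DAs are accurate on real chemicals, which is established in the
validation literature behind the guidelines.

## Performance evaluation

Contingency tables are 2×2 (hazard) or 3×3 over GHS 1A/1B/NC (potency).
Inconclusive or blocked predictions, missing references, and — in potency
mode — `1*` predictions are excluded and itemized by reason; counts plus
exclusions always reconcile to the input size. Metrics are accuracy,
sensitivity, specificity, and balanced accuracy for hazard; accuracy and
per-class sensitivity for potency. A zero-denominator ratio is reported as
`NOT_DEFINED`, never as 0. Requesting a potency table for 2o3 is a
structured error, since 2o3 predicts no potency. Inconclusives are excluded
rather than penalized; hiding the exclusion count would misstate
performance, so it is always reported.

## Problem sizes and determinism

The shipped checks run on sizes chosen to exercise every code path well
within a minute or two on one CPU: the full 27-cell 2o3 grid under all 6
argument orderings, a ~1,600-combination ITS grid at every band edge ± ε,
1,000 randomized DPRA draws for STS dominance, 10,000 ordered pairs for ITS
monotonicity, a 500-row 5 %-defect fixture for validation completeness, and
a 1,000-row fixture for end-to-end oracle agreement and byte-identical
reruns. A single integer seed governs all sampling; the generator restores
the session RNG state, and identical specifications produce byte-identical
tables. XLSX files are written by a built-in minimal writer (inline
strings, store-only ZIP, fixed timestamps) so spreadsheet output is also
deterministic.

## Known limitations

* Only the first worksheet of a spreadsheet is read.
* Quoted CSV fields may not span physical lines (assay tables are one
  record per line).
* No KeratinoSens quantitative model (Imax/EC1.5): the DAs consume only the
  KS binary call.
* No borderline-range evaluation of individual assay results, and no
  confidence intervals on performance metrics.
* Alternative information sources (assays analogous to DPRA/KS/h-CLAT) are
  not implemented; the scoring layer is factored so additional sources
  could be added, but the shipped tables are exactly the harmonized ones.
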