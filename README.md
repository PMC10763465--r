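# dassr

Rule-based hazard and potency prediction for chemical skin sensitization
from non-animal test data.

Skin sensitization (allergic contact dermatitis) must be assessed for most
chemical products, and internationally harmonized *defined approaches* (DAs)
now replace the historical animal tests for this endpoint. A DA combines a
fixed set of information sources — in chemico reactivity (DPRA),
keratinocyte activation (KeratinoSens), dendritic-cell activation (h-CLAT),
and structure-based in silico predictions — through a fixed data
interpretation procedure, with no expert-judgment steps. Applying the
procedures by hand across many chemicals is slow and error-prone; `dassr`
applies them mechanically, flags malformed input, and scores predictions
against reference data.

The package is aimed at toxicologists and regulatory scientists who have
per-chemical assay results in a spreadsheet and want reproducible DA calls.

## The three defined approaches

* **2o3 (Two-out-of-Three).** Hazard is the concordant sensitizer /
  non-sensitizer call from at least two of {DPRA, h-CLAT, KeratinoSens},
  independent of assay order. Two discordant results with the third missing
  are inconclusive. 2o3 predicts hazard only.
* **KE 3/1 STS (sequential testing strategy).** h-CLAT first: a positive
  h-CLAT with minimum induction threshold MIT ≤ 10 µg/mL gives UN GHS
  category 1A, MIT > 10 gives 1B, and no further testing is needed. A
  negative h-CLAT defers to the DPRA: positive → 1B, negative → not
  classified (NC).
* **ITS (integrated testing strategy).** Additive scoring: DPRA mean
  %Cys/%Lys depletion scored 0–3 (Cys-only bands when lysine data are
  absent), h-CLAT MIT scored 0–3, in-domain in silico prediction scored
  0–1. The total (0–7) maps to 1A / 1B / NC through separate lookup tables
  for three and for two available sources; the two-source table includes
  `1*` (conclusive sensitizer, unresolved potency) and an inconclusive
  cell. Scoring thresholds are transcribed, with boundary directions and
  citations, in `inst/extdata/guideline_constants.yaml`, and every ITS
  rationale trace records that file's checksum.

DPRA hazard calls are derived from quantitative depletion (mean ≤ 6.38 % →
negative; Cys-only ≤ 13.89 % → negative) when no call column is supplied,
and quantitative data win over a conflicting user call (with a warning
flag).

## Worked example

```r
library(dassr)
tab <- dass_table(
  c("chem_id", "dpra_cys_pct", "dpra_lys_pct", "hclat_mit",
    "ks_call", "insilico_call", "insilico_domain"),
  matrix(c("cinnamal",   "70.9", "57.1", "8.9",      "p", "p", "in",
           "glycerol",   "3.1",  "0.5",  "negative", "n", "n", "in",
           "isoeugenol", "77.6", "27.7", "18.8",     "p", "p", "out"),
         nrow = 3, byrow = TRUE))
res <- run_dass(tab)   # columns auto-mapped from the canonical names
as.data.frame(results_table(res))[, c("chem_id", "calc_dpra_mean_pct",
  "pred_2o3_hazard", "pred_sts_potency", "pred_its_total_score",
  "pred_its_potency")]
```

```
     chem_id calc_dpra_mean_pct pred_2o3_hazard pred_sts_potency pred_its_total_score pred_its_potency
1   cinnamal                 64      Sensitizer               1A                    7               1A
2   glycerol                1.8  Non-sensitizer               NC                    0               NC
3 isoeugenol              52.65      Sensitizer               1B                    5               1*
```

Reading the rows: cinnamal is positive in everything (DPRA mean depletion
64 %, MIT 8.9 ≤ 10 µg/mL), so every DA calls it a strong (1A) sensitizer.
Glycerol is negative throughout. Isoeugenol's in silico prediction is out
of its applicability domain, so ITS runs on two sources; their total of 5
is a conclusive sensitizer whose potency the two-source table cannot
resolve (`1*`), while STS (MIT 18.8 > 10) assigns 1B.

`write_dass_results(res, "out.tsv")` writes the annotated table (input
columns verbatim, `calc_` intermediates, `pred_` columns per DA, and a flag
summary); `.xlsx` output adds the flags as a second worksheet. Validation
flags (`check_bindings()`, `check_values()`) carry machine-readable codes
with ERROR/WARNING severity; ERROR cells block only the affected
(chemical, DA) pairs. `build_contingency()` and `compute_metrics()` score
predictions against reference classifications (accuracy, sensitivity,
specificity, balanced accuracy; exclusions are itemized, and undefined
ratios are reported as `NOT_DEFINED`).

## Command line

```sh
Rscript inst/cli/dass.R template --output template.csv
Rscript inst/cli/dass.R fixture --n 100 --seed 7 --output demo.tsv
Rscript inst/cli/dass.R run --input demo.tsv --da 2o3,sts,its \
    --reference-hazard ref_hazard --output results.tsv
```

Exit status 0 means predictions were written; 2 is a configuration error
(unknown DA, unmapped or duplicated required columns); 1 anything else. A
`results.tsv.log` records the constants checksum, DA selection, and flag
counts. (After installation, use
`system.file("cli/dass.R", package = "dassr")` as the script path.)

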