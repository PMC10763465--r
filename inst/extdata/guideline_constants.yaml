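# Guideline-derived decision constants for the skin sensitization defined
# approaches. Each entry records the value, the boundary direction at the
# threshold, and the source document it was transcribed from. These are
# configuration, not tunables: changing any value changes which guideline
# the package implements. The file's md5 checksum is recorded in every
# prediction's rationale trace.
dpra_hazard_call:
  mean_threshold:
    value: 6.38
    units: "% depletion"
    direction: "mean <= threshold -> negative"
    citation: "OECD TG 442C, DPRA prediction model 1 (Cys+Lys mean depletion)"
  cys_only_threshold:
    value: 13.89
    units: "% depletion"
    direction: "cys <= threshold -> negative"
    citation: "OECD TG 442C, DPRA prediction model 2 (Cys-only depletion)"
sts:
  mit_1a_max:
    value: 10.0
    units: "ug/mL"
    direction: "MIT <= threshold -> GHS 1A, else GHS 1B"
    citation: "KE 3/1 sequential testing strategy (Nukada et al. 2013; US EPA 2018 interim science policy)"
its_scores:
  hclat_mit_bands:
    # lower MIT = higher potency = higher score; a negative h-CLAT scores 0
    upper_edges: [10.0, 150.0, 5000.0]
    scores: [3, 2, 1]
    units: "ug/mL"
    direction: "MIT <= edge -> that score (first matching edge)"
    citation: "OECD GL 497, Annex 2, ITS h-CLAT scoring table"
  dpra_mean_bands:
    lower_edges: [42.47, 22.62, 6.38]
    scores: [3, 2, 1]
    units: "% depletion"
    direction: "mean >= edge -> that score (first matching edge); below all edges -> 0"
    citation: "OECD GL 497, Annex 2, ITS DPRA scoring table (Cys+Lys mean)"
  dpra_cys_only_bands:
    lower_edges: [98.24, 23.09, 13.89]
    scores: [3, 2, 1]
    units: "% depletion"
    direction: "cys >= edge -> that score (first matching edge); below all edges -> 0"
    citation: "OECD GL 497, Annex 2, ITS DPRA scoring table (Cys-only scheme)"
  insilico:
    positive: 1
    negative: 0
    direction: "out-of-domain predictions are not scored (treated as missing)"
    citation: "OECD GL 497, Annex 2, ITS in silico scoring (Derek Nexus / OECD QSAR Toolbox)"
its_prediction:
  three_sources:
    # total score 0-7
    ghs_1a_min: 6
    ghs_1b_min: 2
    direction: "total >= 6 -> 1A; 2 <= total <= 5 -> 1B; total <= 1 -> NC"
    citation: "OECD GL 497, Annex 2, ITS prediction with all three information sources"
  two_sources:
    # total score 0-6; a score of 5 is a conclusive sensitizer whose potency
    # cannot be resolved (1*); a score of 1 cannot separate 1B from NC
    map:
      "6": GHS_1A
      "5": ONE_STAR
      "4": GHS_1B
      "3": GHS_1B
      "2": GHS_1B
      "1": INCONCLUSIVE
      "0": NC
    citation: "OECD GL 497, Annex 2, ITS prediction with two information sources"
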