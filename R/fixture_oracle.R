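# Independent rule oracle used by the synthetic-data generator.
#
# This is a second, self-contained transcription of the defined-approach
# decision rules, written as plain nested conditionals with its own literal
# thresholds. It deliberately shares no code or configuration with the
# engine in defined_approaches.R: the generator attaches expected
# predictions computed here, and the test suite requires the two
# transcriptions to agree case by case before anything ships.

oracle_dpra_call <- function(cys, lys) {
  if (!is.na(cys) && !is.na(lys)) {
    if ((cys + lys) / 2 > 6.38) "POSITIVE" else "NEGATIVE"
  } else if (!is.na(cys)) {
    if (cys > 13.89) "POSITIVE" else "NEGATIVE"
  } else {
    NA_character_
  }
}

oracle_2o3 <- function(dpra, hclat, ks) {
  calls <- c(dpra, hclat, ks)
  calls <- calls[!is.na(calls)]
  if (length(calls) < 2) return("INCONCLUSIVE")
  pos <- sum(calls == "POSITIVE")
  neg <- sum(calls == "NEGATIVE")
  if (pos >= 2) "SENSITIZER"
  else if (neg >= 2) "NON_SENSITIZER"
  else "INCONCLUSIVE"
}

oracle_sts <- function(mit, dpra_call, hclat_call) {
  if (!is.na(mit)) {
    if (mit <= 10) return(list(hazard = "SENSITIZER", potency = "GHS_1A"))
    return(list(hazard = "SENSITIZER", potency = "GHS_1B"))
  }
  if (is.na(hclat_call)) {
    return(list(hazard = "INCONCLUSIVE", potency = "INCONCLUSIVE"))
  }
  if (hclat_call == "POSITIVE") {
    return(list(hazard = "SENSITIZER", potency = "INCONCLUSIVE"))
  }
  if (is.na(dpra_call)) {
    list(hazard = "INCONCLUSIVE", potency = "INCONCLUSIVE")
  } else if (dpra_call == "POSITIVE") {
    list(hazard = "SENSITIZER", potency = "GHS_1B")
  } else {
    list(hazard = "NON_SENSITIZER", potency = "NC")
  }
}

oracle_its_hclat_score <- function(mit, hclat_call) {
  if (!is.na(mit)) {
    if (mit <= 10) 3L
    else if (mit <= 150) 2L
    else 1L
  } else if (!is.na(hclat_call) && hclat_call == "NEGATIVE") {
    0L
  } else {
    NA_integer_
  }
}

oracle_its_dpra_score <- function(cys, lys) {
  if (!is.na(cys) && !is.na(lys)) {
    m <- (cys + lys) / 2
    if (m >= 42.47) 3L
    else if (m >= 22.62) 2L
    else if (m >= 6.38) 1L
    else 0L
  } else if (!is.na(cys)) {
    if (cys >= 98.24) 3L
    else if (cys >= 23.09) 2L
    else if (cys >= 13.89) 1L
    else 0L
  } else {
    NA_integer_
  }
}

oracle_its_insilico_score <- function(call, in_domain) {
  if (!is.na(in_domain) && !in_domain) return(NA_integer_)
  if (is.na(call)) return(NA_integer_)
  if (call == "POSITIVE") 1L else 0L
}

oracle_its <- function(dpra_score, hclat_score, insilico_score) {
  scores <- c(dpra_score, hclat_score, insilico_score)
  available <- scores[!is.na(scores)]
  if (length(available) < 2) {
    return(list(hazard = "INCONCLUSIVE", potency = "INCONCLUSIVE",
                total = NA_integer_, n_sources = length(available)))
  }
  total <- sum(available)
  if (length(available) == 3) {
    potency <- if (total >= 6) "GHS_1A"
               else if (total >= 2) "GHS_1B"
               else "NC"
  } else {
    potency <- if (total == 6) "GHS_1A"
               else if (total == 5) "ONE_STAR"
               else if (total >= 2) "GHS_1B"
               else if (total == 1) "INCONCLUSIVE"
               else "NC"
  }
  hazard <- if (potency %in% c("GHS_1A", "GHS_1B", "ONE_STAR")) "SENSITIZER"
            else if (potency == "NC") "NON_SENSITIZER"
            else "INCONCLUSIVE"
  list(hazard = hazard, potency = potency, total = total,
       n_sources = length(available))
}

# Full per-record oracle over effective (post-masking) typed values.
# values: list with cys, lys (numeric or NA), mit (numeric or NA),
# mit_negative (TRUE when the MIT cell is the negative-outcome token),
# dpra_call_cell, hclat_call_cell, ks_call, insilico_call (calls or NA),
# insilico_in_domain (logical or NA).
oracle_predict_record <- function(v) {
  dpra_call <- oracle_dpra_call(v$cys, v$lys)
  if (is.na(dpra_call)) dpra_call <- v$dpra_call_cell
  hclat_call <- if (!is.na(v$mit)) "POSITIVE"
                else if (isTRUE(v$mit_negative)) "NEGATIVE"
                else v$hclat_call_cell
  out <- list()
  out$TWO_OF_THREE <- list(
    hazard = oracle_2o3(dpra_call, hclat_call, v$ks_call),
    potency = "NOT_APPLICABLE", total = NA_integer_
  )
  sts <- oracle_sts(v$mit, dpra_call, hclat_call)
  out$KE31STS <- list(hazard = sts$hazard, potency = sts$potency,
                      total = NA_integer_)
  its <- oracle_its(
    oracle_its_dpra_score(v$cys, v$lys),
    oracle_its_hclat_score(v$mit, hclat_call),
    oracle_its_insilico_score(v$insilico_call, v$insilico_in_domain)
  )
  out$ITS <- list(hazard = its$hazard, potency = its$potency,
                  total = its$total)
  out
}
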