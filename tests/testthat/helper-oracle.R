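# Test-side oracles: transcriptions of the defined-approach decision rules
# that are coded independently of the package (table lookups via
# findInterval and literal lookup vectors, not the package's configuration
# file or its nested conditionals). The suite requires the package and these
# oracles to agree cell for cell.

# majority vote over non-missing calls; <2 usable or a 1-1 split is
# inconclusive
oracle2o3_vote <- function(calls) {
  tab <- table(factor(calls[!is.na(calls)],
                      levels = c("POSITIVE", "NEGATIVE")))
  if (max(tab) >= 2) {
    if (which.max(tab) == 1) "SENSITIZER" else "NON_SENSITIZER"
  } else {
    "INCONCLUSIVE"
  }
}

# ITS component score lookups
oracleits_hclat <- function(mit, negative = FALSE) {
  if (negative) return(0L)
  if (is.na(mit)) return(NA_integer_)
  # bands (0,10], (10,150], (150, Inf) -> 3, 2, 1
  c(3L, 2L, 1L)[findInterval(mit, c(10, 150), left.open = TRUE) + 1L]
}

oracleits_dpra <- function(cys, lys) {
  if (!is.na(cys) && !is.na(lys)) {
    findInterval((cys + lys) / 2, c(6.38, 22.62, 42.47))
  } else if (!is.na(cys)) {
    findInterval(cys, c(13.89, 23.09, 98.24))
  } else {
    NA_integer_
  }
}

oracleits_insilico <- function(call, in_domain) {
  if (identical(in_domain, FALSE) || is.na(call)) return(NA_integer_)
  c(POSITIVE = 1L, NEGATIVE = 0L)[[call]]
}

ITS3_LOOKUP <- c("NC", "NC", "GHS_1B", "GHS_1B", "GHS_1B", "GHS_1B",
                 "GHS_1A", "GHS_1A")                     # totals 0..7
ITS2_LOOKUP <- c("NC", "INCONCLUSIVE", "GHS_1B", "GHS_1B", "GHS_1B",
                 "ONE_STAR", "GHS_1A")                   # totals 0..6

oracleits_predict <- function(dpra_s, hclat_s, insilico_s) {
  s <- c(dpra_s, hclat_s, insilico_s)
  k <- sum(!is.na(s))
  if (k < 2) return(list(potency = "INCONCLUSIVE", hazard = "INCONCLUSIVE",
                         total = NA_integer_))
  total <- sum(s, na.rm = TRUE)
  potency <- if (k == 3) ITS3_LOOKUP[total + 1] else ITS2_LOOKUP[total + 1]
  hazard <- c(GHS_1A = "SENSITIZER", GHS_1B = "SENSITIZER",
              ONE_STAR = "SENSITIZER", NC = "NON_SENSITIZER",
              INCONCLUSIVE = "INCONCLUSIVE")[[potency]]
  list(potency = potency, hazard = hazard, total = total)
}

# brute-force contingency/metrics recount
oracle_recount <- function(pred, ref, classes) {
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(predicted = classes, reference = classes))
  excluded <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] %in% classes && !is.na(ref[i]) && ref[i] %in% classes) {
      counts[pred[i], ref[i]] <- counts[pred[i], ref[i]] + 1L
    } else {
      excluded <- excluded + 1L
    }
  }
  list(counts = counts, excluded = excluded)
}

# grid of calls for exhaustive 2o3 checks
CALL_GRID <- expand.grid(
  dpra = c("POSITIVE", "NEGATIVE", NA),
  hclat = c("POSITIVE", "NEGATIVE", NA),
  ks = c("POSITIVE", "NEGATIVE", NA),
  stringsAsFactors = FALSE
)

# representative + boundary MIT inputs (band edges and just past them)
MIT_CASES <- list(
  list(mit = NA_real_, negative = TRUE),
  list(mit = NA_real_, negative = FALSE),
  list(mit = 0.5, negative = FALSE), list(mit = 10, negative = FALSE),
  list(mit = 10.0001, negative = FALSE), list(mit = 75, negative = FALSE),
  list(mit = 150, negative = FALSE), list(mit = 150.0001, negative = FALSE),
  list(mit = 4999, negative = FALSE), list(mit = 5000, negative = FALSE)
)

# (cys, lys) pairs hitting every DPRA band edge +/- eps for both schemes
DPRA_CASES <- local({
  eps <- 1e-4
  means <- c(0, 6.38 - eps, 6.38, 22.62 - eps, 22.62, 42.47 - eps, 42.47, 90)
  cysonly <- c(0, 13.89 - eps, 13.89, 23.09 - eps, 23.09, 98.24 - eps,
               98.24, 100)
  c(lapply(means, function(m) list(cys = m, lys = m)),
    lapply(cysonly, function(cc) list(cys = cc, lys = NA_real_)),
    list(list(cys = NA_real_, lys = NA_real_),
         list(cys = NA_real_, lys = 50)))
})

INSILICO_CASES <- expand.grid(call = c("POSITIVE", "NEGATIVE", NA),
                              in_domain = c(TRUE, FALSE, NA),
                              stringsAsFactors = FALSE)
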