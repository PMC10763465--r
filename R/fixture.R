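# Synthetic assay tables with known ground truth. The generator emulates a
# user upload on the canonical template: quantitative endpoints drawn from
# the assays' operational ranges, call columns written consistently with the
# quantitative data, independent per-cell missingness, and (optionally)
# deliberately corrupted cells recorded in a defect ledger so validation
# completeness is testable as exact multiset equality.

#' Specification for a synthetic fixture table
#'
#' @param n_chemicals Number of rows (chemicals).
#' @param seed Integer seed; identical specs generate identical tables.
#' @param missingness_rate Independent probability that any one assay cell is
#'   empty (default 0.05, a low but realistic incidence of untested
#'   endpoints).
#' @param defect_rate Fraction of assay cells corrupted after generation
#'   (default 0); every injected defect is recorded in the ledger.
#' @param p_hclat_negative Probability that the h-CLAT is negative (no MIT;
#'   default 0.3). Positive MITs are log-uniform over (0.1, 5000] ug/mL.
#' @param p_call_positive Bernoulli rate for call endpoints that have no
#'   quantitative counterpart in the row (default 0.5). Depletions are
#'   uniform over \[-5, 100\] %.
#' @param p_insilico_out_of_domain Probability that the in silico prediction
#'   is outside its applicability domain (default 0.05).
#' @param ref_flip_rate Probability that a reference classification disagrees
#'   with the consensus of the generated assay results (default 0.1),
#'   emulating an imperfect external reference such as the LLNA.
#' @return A `dass_fixture_spec` list.
#' @export
fixture_spec <- function(n_chemicals, seed,
                         missingness_rate = 0.05,
                         defect_rate = 0,
                         p_hclat_negative = 0.3,
                         p_call_positive = 0.5,
                         p_insilico_out_of_domain = 0.05,
                         ref_flip_rate = 0.1) {
  rates <- c(missingness_rate, defect_rate, p_hclat_negative,
             p_call_positive, p_insilico_out_of_domain, ref_flip_rate)
  stopifnot(n_chemicals >= 0, all(rates >= 0 & rates <= 1))
  structure(list(
    n_chemicals = as.integer(n_chemicals), seed = as.integer(seed),
    missingness_rate = missingness_rate, defect_rate = defect_rate,
    p_hclat_negative = p_hclat_negative, p_call_positive = p_call_positive,
    p_insilico_out_of_domain = p_insilico_out_of_domain,
    ref_flip_rate = ref_flip_rate
  ), class = "dass_fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

fmt_depletion <- function(x) sprintf("%.2f", x)
fmt_mit <- function(x) sprintf("%g", signif(x, 3))

#' Generate a synthetic assay table with known expected predictions
#'
#' Produces a table on the canonical template headers, the expected
#' prediction of every defined approach for every record (computed by an
#' independent transcription of the decision rules, not by the prediction
#' engine), and a ledger of every deliberately injected defect.
#'
#' Reference columns (`ref_hazard`, `ref_potency`) are filled from the
#' consensus of the generated assay results (2o3 consensus for hazard, ITS
#' category for potency) and then flipped at `ref_flip_rate` to emulate an
#' imperfect external reference.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `table` (a [dass_table]), `expected` (data frame:
#'   `row`, `chem_id`, `da`, `hazard`, `potency`, `its_total`, `blocked`),
#'   `defects` (data frame ledger: `row`, `column_index`, `column_name`,
#'   `endpoint`, `code`, `severity`), and `spec`.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_spec(5, seed = 1))
#' fx$table
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "dass_fixture_spec"))
  with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  n <- spec$n_chemicals
  headers <- unname(DASS_TEMPLATE_HEADERS)
  col_of <- stats::setNames(seq_along(DASS_ENDPOINTS),
                            names(DASS_TEMPLATE_HEADERS))
  body <- matrix("", nrow = n, ncol = length(headers))
  if (n == 0) {
    return(list(table = dass_table(headers, body),
                expected = empty_expected(), defects = empty_ledger(),
                spec = spec))
  }
  miss <- function() stats::runif(n) < spec$missingness_rate
  # quantitative endpoints
  cys <- round(stats::runif(n, -5, 100), 2)
  lys <- round(stats::runif(n, -5, 100), 2)
  mit <- signif(10^stats::runif(n, log10(0.1), log10(5000)), 3)
  mit[mit > 5000] <- 5000
  hclat_neg <- stats::runif(n) < spec$p_hclat_negative
  cys[miss()] <- NA
  lys[miss()] <- NA
  mit_missing <- miss()
  # calls consistent with the quantitative data where it exists
  dpra_call <- vapply(seq_len(n), function(i) {
    d <- oracle_dpra_call(cys[i], lys[i])
    if (is.na(d)) {
      if (stats::runif(1) < spec$p_call_positive) "POSITIVE" else "NEGATIVE"
    } else d
  }, character(1))
  hclat_call <- ifelse(hclat_neg, "NEGATIVE", "POSITIVE")
  ks_call <- ifelse(stats::runif(n) < spec$p_call_positive,
                    "POSITIVE", "NEGATIVE")
  insilico_call <- ifelse(stats::runif(n) < spec$p_call_positive,
                          "POSITIVE", "NEGATIVE")
  out_dom <- stats::runif(n) < spec$p_insilico_out_of_domain
  dpra_call_missing <- miss()
  hclat_call_missing <- miss()
  ks_missing <- miss()
  insilico_missing <- miss()
  domain_missing <- miss()

  cell <- function(x, missing) ifelse(missing | is.na(x), "", x)
  body[, col_of["CHEM_ID"]] <- sprintf("chem_%04d", seq_len(n))
  body[, col_of["DPRA_CYS_PCT"]] <- cell(ifelse(is.na(cys), NA,
                                                fmt_depletion(cys)), FALSE)
  body[, col_of["DPRA_LYS_PCT"]] <- cell(ifelse(is.na(lys), NA,
                                                fmt_depletion(lys)), FALSE)
  body[, col_of["DPRA_CALL"]] <- cell(tolower(dpra_call), dpra_call_missing)
  body[, col_of["HCLAT_MIT"]] <- cell(ifelse(hclat_neg, "negative",
                                             fmt_mit(mit)), mit_missing)
  body[, col_of["HCLAT_CALL"]] <- cell(tolower(hclat_call),
                                       hclat_call_missing)
  body[, col_of["KS_CALL"]] <- cell(tolower(ks_call), ks_missing)
  body[, col_of["INSILICO_CALL"]] <- cell(tolower(insilico_call),
                                          insilico_missing)
  body[, col_of["INSILICO_DOMAIN"]] <- cell(ifelse(out_dom, "out", "in"),
                                            domain_missing)

  # references: consensus of the clean full record, then noise
  clean_vals <- lapply(seq_len(n), function(i) list(
    cys = cys[i], lys = lys[i],
    mit = if (hclat_neg[i] || mit_missing[i]) NA_real_ else mit[i],
    mit_negative = hclat_neg[i] && !mit_missing[i],
    dpra_call_cell = if (dpra_call_missing[i]) NA_character_ else dpra_call[i],
    hclat_call_cell = if (hclat_call_missing[i]) NA_character_
                      else hclat_call[i],
    ks_call = if (ks_missing[i]) NA_character_ else ks_call[i],
    insilico_call = if (insilico_missing[i]) NA_character_
                    else insilico_call[i],
    insilico_in_domain = if (domain_missing[i]) NA else !out_dom[i]
  ))
  consensus <- lapply(clean_vals, oracle_predict_record)
  flip <- stats::runif(n) < spec$ref_flip_rate
  ref_haz <- vapply(seq_len(n), function(i) {
    h <- consensus[[i]]$TWO_OF_THREE$hazard
    if (h == "INCONCLUSIVE") return("")
    pos <- h == "SENSITIZER"
    if (flip[i]) pos <- !pos
    if (pos) "sensitizer" else "non-sensitizer"
  }, character(1))
  flip_pot <- stats::runif(n) < spec$ref_flip_rate
  ref_pot <- vapply(seq_len(n), function(i) {
    p <- consensus[[i]]$ITS$potency
    if (!p %in% c("GHS_1A", "GHS_1B", "NC")) return("")
    if (flip_pot[i]) {
      p <- switch(p, GHS_1A = "GHS_1B", GHS_1B = "NC", NC = "GHS_1B")
    }
    c(GHS_1A = "1A", GHS_1B = "1B", NC = "NC")[[p]]
  }, character(1))
  body[, col_of["REFERENCE_HAZARD"]] <- ref_haz
  body[, col_of["REFERENCE_POTENCY"]] <- ref_pot

  # defect injection, recorded in the ledger
  defectable <- c("DPRA_CYS_PCT", "DPRA_LYS_PCT", "DPRA_CALL", "HCLAT_MIT",
                  "HCLAT_CALL", "KS_CALL", "INSILICO_CALL", "INSILICO_DOMAIN")
  cells <- expand.grid(row = seq_len(n),
                       endpoint = defectable, stringsAsFactors = FALSE)
  n_defects <- round(spec$defect_rate * nrow(cells))
  ledger <- empty_ledger()
  if (n_defects > 0) {
    pick <- sample(nrow(cells), n_defects)
    for (j in pick) {
      row <- cells$row[j]
      key <- cells$endpoint[j]
      ci <- col_of[[key]]
      numeric_key <- key %in% c("DPRA_CYS_PCT", "DPRA_LYS_PCT", "HCLAT_MIT")
      kind <- if (numeric_key && stats::runif(1) < 0.3) "range" else "token"
      if (kind == "range") {
        body[row, ci] <- if (key == "HCLAT_MIT") "9999" else "250"
        code <- "OUT_OF_RANGE"; sev <- "WARNING"
      } else if (numeric_key) {
        body[row, ci] <- "abc"
        code <- "NON_NUMERIC"; sev <- "ERROR"
      } else {
        body[row, ci] <- "maybe"
        code <- "UNRECOGNIZED_CALL_TOKEN"; sev <- "ERROR"
      }
      ledger <- rbind(ledger, data.frame(
        row = row, column_index = ci, column_name = headers[ci],
        endpoint = key, code = code, severity = sev,
        stringsAsFactors = FALSE))
    }
    ledger <- ledger[order(ledger$column_index, ledger$row), , drop = FALSE]
    rownames(ledger) <- NULL
  }

  # expected predictions over effective (post-defect) values
  expected <- vector("list", n)
  for (i in seq_len(n)) {
    v <- clean_vals[[i]]
    defs <- ledger[ledger$row == i, , drop = FALSE]
    for (j in seq_len(nrow(defs))) {
      key <- defs$endpoint[j]
      code <- defs$code[j]
      if (code == "OUT_OF_RANGE") {
        val <- as.numeric(body[i, col_of[[key]]])
        if (key == "DPRA_CYS_PCT") v$cys <- val
        if (key == "DPRA_LYS_PCT") v$lys <- val
        if (key == "HCLAT_MIT") { v$mit <- val; v$mit_negative <- FALSE }
      } else {
        if (key == "DPRA_CYS_PCT") v$cys <- NA_real_
        if (key == "DPRA_LYS_PCT") v$lys <- NA_real_
        if (key == "HCLAT_MIT") { v$mit <- NA_real_; v$mit_negative <- FALSE }
        if (key == "DPRA_CALL") v$dpra_call_cell <- NA_character_
        if (key == "HCLAT_CALL") v$hclat_call_cell <- NA_character_
        if (key == "KS_CALL") v$ks_call <- NA_character_
        if (key == "INSILICO_CALL") v$insilico_call <- NA_character_
        if (key == "INSILICO_DOMAIN") v$insilico_in_domain <- NA
      }
    }
    pred <- oracle_predict_record(v)
    err_keys <- defs$endpoint[defs$severity == "ERROR"]
    expected[[i]] <- do.call(rbind, lapply(DASS_DAS, function(da) {
      p <- pred[[da]]
      blocked <- p$hazard == "INCONCLUSIVE" &&
        any(err_keys %in% DA_INPUT_ENDPOINTS[[da]])
      data.frame(row = i, chem_id = body[i, col_of[["CHEM_ID"]]], da = da,
                 hazard = p$hazard, potency = p$potency,
                 its_total = as.integer(p$total), blocked = blocked,
                 stringsAsFactors = FALSE)
    }))
  }
  list(table = dass_table(headers, body),
       expected = do.call(rbind, expected),
       defects = ledger, spec = spec)
}

empty_ledger <- function() {
  data.frame(row = integer(0), column_index = integer(0),
             column_name = character(0), endpoint = character(0),
             code = character(0), severity = character(0),
             stringsAsFactors = FALSE)
}

empty_expected <- function() {
  data.frame(row = integer(0), chem_id = character(0), da = character(0),
             hazard = character(0), potency = character(0),
             its_total = integer(0), blocked = logical(0),
             stringsAsFactors = FALSE)
}
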