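# The three defined approaches. Each predictor returns a one-row data frame
# ("DA prediction"): da, hazard, potency, its_total, its_source_count, and a
# rationale trace of the rule path taken.

da_prediction <- function(da, hazard, potency, rationale,
                          its_total = NA_integer_,
                          its_source_count = NA_integer_) {
  data.frame(da = da, hazard = hazard, potency = potency,
             its_total = as.integer(its_total),
             its_source_count = as.integer(its_source_count),
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Two-out-of-Three (2o3) hazard prediction
#'
#' Hazard is the concordant call of at least two of the three assays (DPRA,
#' h-CLAT, KeratinoSens), independent of assay order. With only two
#' non-missing, discordant calls, or with fewer than two calls, the chemical
#' cannot be classified. 2o3 predicts no GHS potency.
#'
#' @param dpra,hclat,ks Calls: `"POSITIVE"`, `"NEGATIVE"`, or `NA` (missing).
#' @return A one-row prediction data frame; `hazard` is `"SENSITIZER"`,
#'   `"NON_SENSITIZER"`, or `"INCONCLUSIVE"`; `potency` is always
#'   `"NOT_APPLICABLE"`.
#' @export
#' @examples
#' predict_2o3("POSITIVE", "POSITIVE", "NEGATIVE")$hazard
predict_2o3 <- function(dpra, hclat, ks) {
  calls <- c(dpra, hclat, ks)
  n_pos <- sum(calls == "POSITIVE", na.rm = TRUE)
  n_neg <- sum(calls == "NEGATIVE", na.rm = TRUE)
  if (n_pos >= 2) {
    hazard <- "SENSITIZER"
    why <- sprintf("%d of 3 assays positive", n_pos)
  } else if (n_neg >= 2) {
    hazard <- "NON_SENSITIZER"
    why <- sprintf("%d of 3 assays negative", n_neg)
  } else {
    hazard <- "INCONCLUSIVE"
    why <- if (n_pos + n_neg <= 1) "insufficient sources"
           else "two available assays discordant"
  }
  da_prediction("TWO_OF_THREE", hazard, "NOT_APPLICABLE",
                paste0("2o3: ", why))
}

#' KE 3/1 sequential testing strategy (STS) prediction
#'
#' h-CLAT results are evaluated first: a positive h-CLAT concludes the
#' assessment (GHS 1A when MIT is at or below 10 ug/mL, else 1B) with no
#' further testing. A negative h-CLAT defers to the DPRA call: positive
#' gives GHS 1B, negative gives NC. Without an h-CLAT result the sequence
#' cannot start and the result is inconclusive. A positive h-CLAT call
#' without a numeric MIT gives a conclusive sensitizer hazard with
#' inconclusive potency (potency requires the quantitative MIT).
#'
#' @param hclat_mit Numeric MIT in ug/mL, or `NA`.
#' @param dpra DPRA call: `"POSITIVE"`, `"NEGATIVE"`, or `NA`.
#' @param hclat_call h-CLAT call used when `hclat_mit` is `NA`:
#'   `"NEGATIVE"` marks a negative assay outcome, `"POSITIVE"` a positive
#'   outcome whose MIT was not provided, `NA` a missing assay.
#' @return A one-row prediction data frame.
#' @export
#' @examples
#' predict_sts(5, NA)[, c("hazard", "potency")]
predict_sts <- function(hclat_mit, dpra, hclat_call = NULL) {
  if (is.null(hclat_call)) {
    hclat_call <- if (!is.na(hclat_mit)) "POSITIVE" else NA_character_
  }
  m <- dass_constants()$sts$mit_1a_max$value
  if (!is.na(hclat_mit)) {
    pot <- if (hclat_mit <= m) "GHS_1A" else "GHS_1B"
    return(da_prediction("KE31STS", "SENSITIZER", pot,
      sprintf("STS: h-CLAT positive (MIT %g <=/> %g ug/mL); no further testing",
              hclat_mit, m)))
  }
  if (!is.na(hclat_call) && hclat_call == "POSITIVE") {
    return(da_prediction("KE31STS", "SENSITIZER", "INCONCLUSIVE",
      "STS: h-CLAT positive without numeric MIT; potency unresolved"))
  }
  if (is.na(hclat_call)) {
    return(da_prediction("KE31STS", "INCONCLUSIVE", "INCONCLUSIVE",
      "STS: h-CLAT missing; sequence cannot start"))
  }
  # h-CLAT negative: DPRA decides
  if (is.na(dpra)) {
    da_prediction("KE31STS", "INCONCLUSIVE", "INCONCLUSIVE",
                  "STS: h-CLAT negative, DPRA missing")
  } else if (dpra == "POSITIVE") {
    da_prediction("KE31STS", "SENSITIZER", "GHS_1B",
                  "STS: h-CLAT negative, DPRA positive")
  } else {
    da_prediction("KE31STS", "NON_SENSITIZER", "NC",
                  "STS: h-CLAT negative, DPRA negative")
  }
}

#' ITS score for the h-CLAT MIT
#'
#' Lower MIT (higher potency) scores higher: MIT at or below 10 ug/mL scores
#' 3, above 10 up to 150 scores 2, above 150 scores 1; a negative h-CLAT
#' scores 0.
#'
#' @param hclat_mit Numeric MIT in ug/mL or `NA`.
#' @param hclat_call Used when `hclat_mit` is `NA`: `"NEGATIVE"` scores 0,
#'   anything else is missing.
#' @return Integer score 0-3, or `NA` (missing source).
#' @export
score_its_hclat <- function(hclat_mit, hclat_call = NULL) {
  if (is.na(hclat_mit)) {
    if (!is.null(hclat_call) && !is.na(hclat_call) && hclat_call == "NEGATIVE") {
      return(0L)
    }
    return(NA_integer_)
  }
  if (hclat_mit <= 0) stop("MIT must be positive", call. = FALSE)
  b <- dass_constants()$its_scores$hclat_mit_bands
  for (i in seq_along(b$upper_edges)) {
    if (hclat_mit <= b$upper_edges[[i]]) return(as.integer(b$scores[[i]]))
  }
  # a numeric (positive) MIT beyond the last band edge still scores in the
  # weakest positive band; the value was range-flagged at validation
  as.integer(b$scores[[length(b$scores)]])
}

#' ITS score for DPRA depletion
#'
#' With both peptides, the mean of %Cys and %Lys depletion is scored on the
#' two-value band table (42.47/22.62/6.38 -> 3/2/1, below 6.38 -> 0). With
#' %Cys only, the Cys-only band table applies (98.24/23.09/13.89). %Lys
#' alone has no scheme and yields a missing score.
#'
#' @param cys_pct,lys_pct Numeric percent depletion or `NA`.
#' @return A list with integer `score` (0-3 or `NA`) and `scheme` (one of
#'   `"TWO_VALUE_DPRA"`, `"CYS_ONLY_DPRA"`, `"NO_DPRA"`).
#' @export
#' @examples
#' score_its_dpra(60, 40)
score_its_dpra <- function(cys_pct, lys_pct) {
  k <- dass_constants()$its_scores
  band <- function(x, tab) {
    for (i in seq_along(tab$lower_edges)) {
      if (x >= tab$lower_edges[[i]]) return(as.integer(tab$scores[[i]]))
    }
    0L
  }
  if (!is.na(cys_pct) && !is.na(lys_pct)) {
    list(score = band(dpra_mean(cys_pct, lys_pct), k$dpra_mean_bands),
         scheme = "TWO_VALUE_DPRA")
  } else if (!is.na(cys_pct)) {
    list(score = band(cys_pct, k$dpra_cys_only_bands),
         scheme = "CYS_ONLY_DPRA")
  } else {
    list(score = NA_integer_, scheme = "NO_DPRA")
  }
}

#' ITS score for the in silico prediction
#'
#' A positive structural prediction scores 1, a negative one 0. Predictions
#' outside the model's applicability domain are not usable information
#' sources and yield a missing score.
#'
#' @param call `"POSITIVE"`, `"NEGATIVE"`, or `NA`.
#' @param in_domain `TRUE`, `FALSE`, or `NA` (unknown domain status is taken
#'   as in-domain).
#' @return Integer 0, 1, or `NA`.
#' @export
score_its_insilico <- function(call, in_domain = NA) {
  if (!is.na(in_domain) && !in_domain) return(NA_integer_)
  if (is.na(call)) return(NA_integer_)
  k <- dass_constants()$its_scores$insilico
  if (call == "POSITIVE") as.integer(k$positive) else as.integer(k$negative)
}

#' ITS hazard and potency prediction from component scores
#'
#' Sums the available component scores and looks the total up in the
#' prediction table matching the number of available sources. With all three
#' sources, totals 6-7 give GHS 1A, 2-5 give 1B, and 0-1 give NC. With two
#' sources, 6 gives 1A, 5 gives `ONE_STAR` (conclusive sensitizer,
#' inconclusive potency), 2-4 give 1B, 1 is inconclusive, and 0 gives NC.
#' Fewer than two sources is inconclusive.
#'
#' @param dpra_score,hclat_score,insilico_score Component scores (integer or
#'   `NA` for a missing source), from [score_its_dpra()],
#'   [score_its_hclat()], and [score_its_insilico()].
#' @param scheme DPRA scoring scheme label carried into the rationale.
#' @return A one-row prediction data frame with `its_total` and
#'   `its_source_count` populated.
#' @export
#' @examples
#' predict_its(3, 3, 1)[, c("potency", "its_total")]
predict_its <- function(dpra_score, hclat_score, insilico_score,
                        scheme = NULL) {
  scores <- c(dpra = dpra_score, hclat = hclat_score,
              insilico = insilico_score)
  avail <- !is.na(scores)
  n_sources <- sum(avail)
  trace_scheme <- if (is.null(scheme)) "" else paste0(", DPRA scheme ", scheme)
  if (n_sources < 2) {
    return(da_prediction("ITS", "INCONCLUSIVE", "INCONCLUSIVE",
      paste0("ITS: insufficient sources (", n_sources, " of 3 available)",
             trace_scheme)))
  }
  total <- sum(scores[avail])
  k <- dass_constants()$its_prediction
  if (n_sources == 3) {
    pot <- if (total >= k$three_sources$ghs_1a_min) "GHS_1A"
           else if (total >= k$three_sources$ghs_1b_min) "GHS_1B"
           else "NC"
  } else {
    pot <- k$two_sources$map[[as.character(total)]]
  }
  hazard <- switch(pot,
    GHS_1A = , GHS_1B = , ONE_STAR = "SENSITIZER",
    NC = "NON_SENSITIZER",
    INCONCLUSIVE = "INCONCLUSIVE"
  )
  da_prediction("ITS", hazard, pot,
    paste0("ITS: total score ", total, " from ", n_sources, " sources (",
           paste0(names(scores)[avail], "=", scores[avail], collapse = ", "),
           ")", trace_scheme, "; constants md5 ", dass_constants_checksum()),
    its_total = total, its_source_count = n_sources)
}

# --- pipeline ---------------------------------------------------------------

# Blocking policy: an ERROR flag masks the cell (harmonization), and a
# (chemical, DA) pair is reported BLOCKED -- instead of inconclusive -- when
# the DA could not reach a conclusive call AND one of its input endpoints
# carries an ERROR flag on that row. DAs whose inputs are clean are never
# blocked by another DA's defective column (block minimality).
row_blocked_das <- function(flags, row, das) {
  err <- error_cells(flags)
  err <- err[err$row == row, , drop = FALSE]
  if (!nrow(err)) return(character(0))
  das[vapply(das, function(da) {
    any(err$endpoint %in% DA_INPUT_ENDPOINTS[[da]])
  }, logical(1))]
}

predict_record <- function(record, da) {
  switch(da,
    TWO_OF_THREE = predict_2o3(record$dpra_call, record$hclat_call,
                               record$ks_call),
    KE31STS = predict_sts(record$hclat_mit, record$dpra_call,
                          record$hclat_call),
    ITS = {
      d <- score_its_dpra(record$cys_pct, record$lys_pct)
      h <- score_its_hclat(record$hclat_mit, record$hclat_call)
      s <- score_its_insilico(record$insilico_call, record$insilico_in_domain)
      p <- predict_its(d$score, h, s, scheme = d$scheme)
      p$its_dpra_score <- d$score
      p$its_hclat_score <- h
      p$its_insilico_score <- s
      p
    },
    stop("unknown DA: ", da, call. = FALSE)
  )
}

#' Run the selected defined approaches over a table
#'
#' The full interpretation pipeline: binds columns (given or auto-mapped),
#' validates bindings and cell values, harmonizes rows into per-chemical
#' records, and applies each selected DA. ERROR flags block prediction only
#' for the affected (chemical, DA) pairs; a DA whose required columns are
#' not bound at all is blocked for every record.
#'
#' @param table A [dass_table].
#' @param selected_das Character vector, subset of [DASS_DAS]. Default all
#'   three.
#' @param map A `dass_column_map`; default auto-maps canonical headers.
#' @return A `dass_results` object: list with `table` (the input),
#'   `records` (harmonized data frame), `predictions` (long data frame, one
#'   row per record x DA, with `blocked` and `rationale`), `flags`, `map`,
#'   `selected_das`, and `constants_md5`.
#' @export
#' @examples
#' tab <- dass_table(c("dpra_call", "hclat_call", "ks_call"),
#'                   matrix(c("p", "p", "n"), nrow = 1))
#' res <- run_dass(tab, "TWO_OF_THREE")
#' res$predictions$hazard
run_dass <- function(table, selected_das = DASS_DAS, map = NULL) {
  stopifnot(inherits(table, "dass_table"))
  selected_das <- match.arg(selected_das, DASS_DAS, several.ok = TRUE)
  if (is.null(map)) map <- auto_map_columns(table)
  binding_flags <- check_bindings(map, selected_das, table)
  value_flags <- if (length(map)) check_values(table, map) else new_flags()
  h <- harmonize_records(table, map, bind_flags(binding_flags, value_flags))
  records <- h$records
  flags <- h$flags

  # DAs whose bindings are unsatisfiable are blocked wholesale
  unbound_das <- Filter(function(da) {
    msgs <- flags$message[flags$code == "MISSING_REQUIRED_COLUMN"]
    any(startsWith(msgs, paste0(da, " ")))
  }, selected_das)
  idx <- unclass(map)
  dup_keys <- names(map)[idx %in% unique(idx[duplicated(idx)])]

  preds <- vector("list", nrow(records) * length(selected_das))
  i <- 0
  for (r in seq_len(nrow(records))) {
    rec <- records[r, , drop = FALSE]
    blocked_here <- row_blocked_das(flags, r, selected_das)
    for (da in selected_das) {
      i <- i + 1
      if (da %in% unbound_das ||
          any(dup_keys %in% DA_INPUT_ENDPOINTS[[da]])) {
        p <- da_prediction(da, "INCONCLUSIVE",
                           if (da == "TWO_OF_THREE") "NOT_APPLICABLE"
                           else "INCONCLUSIVE",
                           paste0(da, ": blocked (column bindings invalid)"))
        p$blocked <- TRUE
      } else {
        p <- predict_record(rec, da)
        p$blocked <- da %in% blocked_here && p$hazard == "INCONCLUSIVE"
        if (p$blocked) {
          p$rationale <- paste0(p$rationale,
                                "; blocked by ERROR flag(s) on this row")
        }
      }
      p$row <- r
      p$chem_id <- rec$chem_id
      preds[[i]] <- p
    }
  }
  predictions <- if (length(preds)) do.call(rbind_fill, preds) else
    data.frame(da = character(0), hazard = character(0),
               potency = character(0), its_total = integer(0),
               its_source_count = integer(0), rationale = character(0),
               blocked = logical(0), row = integer(0),
               chem_id = character(0), stringsAsFactors = FALSE)
  structure(
    list(table = table, records = records, predictions = predictions,
         flags = flags, map = map, selected_das = selected_das,
         constants_md5 = dass_constants_checksum()),
    class = "dass_results"
  )
}

# rbind for data frames whose column sets differ (ITS rows carry scores)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[cols]
  }))
}

#' @export
print.dass_results <- function(x, ...) {
  cat("<dass_results> ", nrow(x$records), " chemicals, DAs: ",
      paste(x$selected_das, collapse = ", "), "\n", sep = "")
  cat(nrow(x$flags), " flag(s), ", sum(x$predictions$blocked),
      " blocked prediction(s)\n", sep = "")
  invisible(x)
}

# display tokens for output tables
render_hazard <- function(hazard, blocked) {
  out <- c(SENSITIZER = "Sensitizer", NON_SENSITIZER = "Non-sensitizer",
           INCONCLUSIVE = "Inconclusive")[hazard]
  out[blocked] <- "Blocked"
  unname(out)
}

render_potency <- function(potency, blocked) {
  out <- c(GHS_1A = "1A", GHS_1B = "1B", NC = "NC", ONE_STAR = "1*",
           INCONCLUSIVE = "Inconclusive",
           NOT_APPLICABLE = "Not applicable")[potency]
  out[blocked] <- "Blocked"
  unname(out)
}

num_text <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else format(v, trim = TRUE, scientific = FALSE)
  }, character(1))
}

call_text <- function(x) {
  out <- unname(c(POSITIVE = "Positive", NEGATIVE = "Negative")[x])
  out[is.na(out)] <- ""
  out
}

#' Annotated output table for a results object
#'
#' Builds the downloadable results table: every input column verbatim,
#' harmonized/calculated intermediates (prefix `calc_`), one hazard/potency
#' column pair per executed DA (prefix `pred_`), ITS component scores when
#' ITS was run, and a flag-summary column (`flags`). Column roles are
#' machine-readable from these header prefixes.
#'
#' @param results A `dass_results` object.
#' @return A [dass_table].
#' @export
results_table <- function(results) {
  stopifnot(inherits(results, "dass_results"))
  tab <- results$table
  rec <- results$records
  header <- tab$header
  body <- tab$body
  add_col <- function(name, values) {
    header <<- c(header, name)
    body <<- cbind(body, values)
  }
  add_col("calc_dpra_mean_pct", num_text(rec$dpra_mean_pct))
  add_col("calc_dpra_call", call_text(rec$dpra_call))
  add_col("calc_hclat_call", call_text(rec$hclat_call))
  for (da in results$selected_das) {
    p <- results$predictions[results$predictions$da == da, , drop = FALSE]
    p <- p[order(p$row), , drop = FALSE]
    tag <- c(TWO_OF_THREE = "2o3", KE31STS = "sts", ITS = "its")[[da]]
    add_col(paste0("pred_", tag, "_hazard"), render_hazard(p$hazard, p$blocked))
    add_col(paste0("pred_", tag, "_potency"),
            render_potency(p$potency, p$blocked))
    if (da == "ITS") {
      add_col("pred_its_dpra_score", num_text(p$its_dpra_score))
      add_col("pred_its_hclat_score", num_text(p$its_hclat_score))
      add_col("pred_its_insilico_score", num_text(p$its_insilico_score))
      add_col("pred_its_total_score", num_text(p$its_total))
    }
  }
  add_col("flags", flag_summary_column(results$flags, nrow(rec)))
  dass_table(header, body)
}

#' Write annotated results
#'
#' Serializes the annotated results table to a tab-delimited or Excel file.
#' Re-reading the TSV reproduces every cell's text exactly. For XLSX, flags
#' are written to a second worksheet; for TSV, use [write_dass_flags()] for
#' the sidecar.
#'
#' @param results A `dass_results` object.
#' @param path Output path.
#' @param format `"TSV"` or `"XLSX"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_dass_results <- function(results, path, format = NULL) {
  stopifnot(inherits(results, "dass_results"))
  format <- if (is.null(format)) infer_format(path) else toupper(format)
  format <- match.arg(format, c("TSV", "XLSX"))
  out <- results_table(results)
  if (format == "TSV") {
    write_dass_table(out, path, "TSV")
  } else {
    fl <- results$flags
    fl_body <- as.matrix(fl)
    fl_body[is.na(fl_body)] <- ""
    write_minimal_xlsx(list(
      Results = list(header = out$header, body = out$body),
      Flags = list(header = names(fl), body = fl_body)
    ), path)
  }
  invisible(path)
}
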