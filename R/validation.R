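# Validation flags: machine-readable descriptions of formatting and
# consistency problems at a (column, row) location. ERROR flags block
# prediction for the affected (chemical, DA) pairs only; WARNING flags never
# block. Flags are deterministic and ordered by column index, then row index.

FLAG_CODES <- c("DUPLICATE_BINDING", "MISSING_REQUIRED_COLUMN", "NON_NUMERIC",
                "OUT_OF_RANGE", "UNRECOGNIZED_CALL_TOKEN", "EMPTY_CELL",
                "TAB_IN_CELL", "CALL_CONFLICT")

new_flags <- function(endpoint = character(0), column_name = character(0),
                      column_index = integer(0), row = integer(0),
                      code = character(0), severity = character(0),
                      message = character(0)) {
  stopifnot(all(code %in% FLAG_CODES), all(severity %in% c("ERROR", "WARNING")))
  structure(
    data.frame(endpoint = endpoint, column_name = column_name,
               column_index = as.integer(column_index), row = as.integer(row),
               code = code, severity = severity, message = message,
               stringsAsFactors = FALSE),
    class = c("dass_flags", "data.frame")
  )
}

flag_row <- function(endpoint, column_name, column_index, row, code, severity,
                     message) {
  new_flags(endpoint, column_name, column_index, row, code, severity, message)
}

bind_flags <- function(...) {
  out <- do.call(rbind, Filter(Negate(is.null), list(...)))
  if (is.null(out)) out <- new_flags()
  class(out) <- c("dass_flags", "data.frame")
  sort_flags(out)
}

sort_flags <- function(flags) {
  ord <- order(is.na(flags$column_index), flags$column_index,
               is.na(flags$row), flags$row, flags$code)
  out <- flags[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.dass_flags <- function(x, ...) {
  cat("<dass_flags> ", nrow(x), " flag(s)",
      if (nrow(x)) paste0(" (", sum(x$severity == "ERROR"), " ERROR)"), "\n",
      sep = "")
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

# Requirement sets: per DA, a list of information sources, each satisfiable
# by any one of the listed alternative endpoints. 2o3 needs a call (given or
# derivable) from DPRA, h-CLAT, and KS; STS needs the h-CLAT and DPRA
# sources; ITS scores quantitative DPRA depletion, the h-CLAT MIT, and the
# in silico call, and can run on any two of the three.
DA_REQUIREMENTS <- list(
  TWO_OF_THREE = list(
    kind = "all",
    sources = list(
      DPRA  = c("DPRA_CALL", "DPRA_CYS_PCT"),
      hCLAT = c("HCLAT_CALL", "HCLAT_MIT"),
      KS    = "KS_CALL"
    )
  ),
  KE31STS = list(
    kind = "all",
    sources = list(
      hCLAT = c("HCLAT_MIT", "HCLAT_CALL"),
      DPRA  = c("DPRA_CALL", "DPRA_CYS_PCT")
    )
  ),
  ITS = list(
    kind = "at_least_two",
    sources = list(
      DPRA      = "DPRA_CYS_PCT",
      hCLAT     = "HCLAT_MIT",
      in_silico = "INSILICO_CALL"
    )
  )
)

#' Check column bindings against the selected defined approaches
#'
#' Emits `DUPLICATE_BINDING` (ERROR) when one column is bound to two or more
#' endpoints, and `MISSING_REQUIRED_COLUMN` (ERROR) for each information
#' source a selected DA cannot satisfy from the bindings. A source with
#' alternative endpoints (e.g. a DPRA call column vs quantitative depletion
#' columns) is satisfied when any one alternative is bound. ITS requires at
#' least two of its three sources; when fewer are bound, every unbound ITS
#' source is flagged.
#'
#' @param map A `dass_column_map`.
#' @param selected_das Character vector of DA identifiers (subset of
#'   [DASS_DAS]).
#' @param table Optional [dass_table]; when given, flags carry the bound
#'   column names.
#' @return A `dass_flags` data frame (zero rows when all requirements hold).
#' @export
check_bindings <- function(map, selected_das, table = NULL) {
  selected_das <- match.arg(selected_das, DASS_DAS, several.ok = TRUE)
  flags <- list()
  colname <- function(key) {
    if (!is.null(table) && key %in% names(map)) table$header[map[[key]]]
    else DASS_TEMPLATE_HEADERS[[key]]
  }
  # duplicate bindings: one column index under several endpoints
  if (length(map)) {
    tab <- split(names(map), unclass(map))
    for (idx in names(tab)) {
      keys <- tab[[idx]]
      if (length(keys) > 1) {
        flags[[length(flags) + 1]] <- flag_row(
          endpoint = keys[1], column_name = colname(keys[1]),
          column_index = as.integer(idx), row = NA_integer_,
          code = "DUPLICATE_BINDING", severity = "ERROR",
          message = paste0("column ", idx, " is bound to multiple endpoints: ",
                           paste(keys, collapse = ", "))
        )
      }
    }
  }
  for (da in selected_das) {
    req <- DA_REQUIREMENTS[[da]]
    satisfied <- vapply(req$sources, function(alts) any(alts %in% names(map)),
                        logical(1))
    missing_sources <-
      if (req$kind == "all") names(req$sources)[!satisfied]
      else if (sum(satisfied) < 2) names(req$sources)[!satisfied]
      else character(0)
    for (src in missing_sources) {
      alts <- req$sources[[src]]
      flags[[length(flags) + 1]] <- flag_row(
        endpoint = alts[1], column_name = NA_character_,
        column_index = NA_integer_, row = NA_integer_,
        code = "MISSING_REQUIRED_COLUMN", severity = "ERROR",
        message = paste0(da, " requires the ", src, " source; bind one of: ",
                         paste(tolower(DASS_TEMPLATE_HEADERS[alts]),
                               collapse = ", "))
      )
    }
  }
  do.call(bind_flags, flags)
}

NUMERIC_ENDPOINTS <- c("DPRA_CYS_PCT", "DPRA_LYS_PCT", "HCLAT_MIT")
CALL_ENDPOINTS <- c("DPRA_CALL", "HCLAT_CALL", "KS_CALL", "INSILICO_CALL",
                    "REFERENCE_HAZARD")

is_decimal <- function(x) {
  grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", trimws(x))
}

#' Check cell values in bound columns
#'
#' Validates every cell of every bound column against the endpoint's data and
#' formatting requirements:
#' * numeric endpoints (`dpra_cys_pct`, `dpra_lys_pct`, `hclat_mit`) must
#'   parse as decimal numbers (`NON_NUMERIC`, ERROR); `hclat_mit`
#'   additionally accepts a negative-outcome token (`n`, `neg`, `negative`,
#'   `inf`);
#' * depletion percentages outside \[-100, 100\] and MIT outside (0, 5000\]
#'   give `OUT_OF_RANGE` (WARNING; the assays' operational ranges);
#' * call endpoints must parse via the call lexicon
#'   (`UNRECOGNIZED_CALL_TOKEN`, ERROR), the applicability-domain column via
#'   the in/out lexicon, and reference potency via the GHS category lexicon;
#' * empty cells give `EMPTY_CELL` (WARNING; treated as missing downstream);
#' * cells containing tab characters give `TAB_IN_CELL` (WARNING; tabs are
#'   forbidden inside cells of the tab-delimited dialect).
#'
#' @param table A [dass_table].
#' @param map A `dass_column_map` with at least one binding.
#' @return A `dass_flags` data frame ordered by column index then row index.
#' @export
check_values <- function(table, map) {
  stopifnot(inherits(table, "dass_table"))
  if (!length(map)) stop("column map has no bindings", call. = FALSE)
  flags <- list()
  add <- function(key, col_idx, rows, code, severity, msg) {
    if (!length(rows)) return()
    flags[[length(flags) + 1]] <<- new_flags(
      endpoint = rep(key, length(rows)),
      column_name = rep(table$header[col_idx], length(rows)),
      column_index = rep(col_idx, length(rows)),
      row = rows, code = rep(code, length(rows)),
      severity = rep(severity, length(rows)),
      message = paste0(msg, " (row ", rows, ")")
    )
  }
  for (key in names(map)) {
    col_idx <- map[[key]]
    cells <- trimws(table$body[, col_idx])
    lower <- tolower(cells)
    empty <- !nzchar(cells) | lower %in% MISSING_TOKENS
    add(key, col_idx, which(grepl("\t", table$body[, col_idx], fixed = TRUE)),
        "TAB_IN_CELL", "WARNING", "cell contains a tab character")
    add(key, col_idx, which(empty), "EMPTY_CELL", "WARNING",
        "empty cell; value treated as missing")
    present <- which(!empty)
    if (!length(present)) next
    val <- cells[present]
    lo <- lower[present]
    if (key %in% c("DPRA_CYS_PCT", "DPRA_LYS_PCT")) {
      num_ok <- is_decimal(val)
      add(key, col_idx, present[!num_ok], "NON_NUMERIC", "ERROR",
          paste0("value must be a decimal % depletion"))
      num <- suppressWarnings(as.numeric(val[num_ok]))
      oor <- num < -100 | num > 100
      add(key, col_idx, present[num_ok][oor], "OUT_OF_RANGE", "WARNING",
          "depletion outside the plausible range [-100, 100] %")
    } else if (key == "HCLAT_MIT") {
      neg <- lo %in% MIT_NEGATIVE_TOKENS
      num_ok <- is_decimal(val)
      add(key, col_idx, present[!neg & !num_ok], "NON_NUMERIC", "ERROR",
          "value must be a decimal MIT in ug/mL or a negative-outcome token")
      num <- suppressWarnings(as.numeric(val[!neg & num_ok]))
      oor <- num <= 0 | num > 5000
      add(key, col_idx, present[!neg & num_ok][oor], "OUT_OF_RANGE", "WARNING",
          "MIT outside the h-CLAT testing range (0, 5000] ug/mL")
    } else if (key %in% CALL_ENDPOINTS) {
      bad <- !(lo %in% c(POSITIVE_TOKENS, NEGATIVE_TOKENS))
      add(key, col_idx, present[bad], "UNRECOGNIZED_CALL_TOKEN", "ERROR",
          "value is not a recognized positive/negative call token")
    } else if (key == "INSILICO_DOMAIN") {
      bad <- !(lo %in% c(DOMAIN_IN_TOKENS, DOMAIN_OUT_TOKENS))
      add(key, col_idx, present[bad], "UNRECOGNIZED_CALL_TOKEN", "ERROR",
          "value is not a recognized in/out applicability-domain token")
    } else if (key == "REFERENCE_POTENCY") {
      bad <- !(lo %in% unlist(POTENCY_TOKENS))
      add(key, col_idx, present[bad], "UNRECOGNIZED_CALL_TOKEN", "ERROR",
          "value is not a recognized GHS potency category (1A, 1B, NC)")
    }
    # CHEM_ID: free text, nothing further to check
  }
  do.call(bind_flags, flags)
}

# ERROR flags at (row, endpoint) granularity, for blocking decisions.
error_cells <- function(flags) {
  flags[flags$severity == "ERROR" & !is.na(flags$row), , drop = FALSE]
}

#' Serialize flags to a TSV sidecar
#'
#' @param flags A `dass_flags` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dass_flags <- function(flags, path) {
  utils::write.table(flags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# One-line-per-row summary used for the flag-summary output column.
flag_summary_column <- function(flags, n_rows) {
  out <- character(n_rows)
  cellf <- flags[!is.na(flags$row), , drop = FALSE]
  if (nrow(cellf)) {
    by_row <- split(paste0(cellf$code, ":", cellf$column_name), cellf$row)
    for (r in names(by_row)) {
      out[as.integer(r)] <- paste(by_row[[r]], collapse = "; ")
    }
  }
  out
}
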