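# Harmonization: translate validated raw cells into standardized calls and
# calculated quantitative inputs for the DA engine. All lexicons are
# case-insensitive and applied after whitespace trimming.

POSITIVE_TOKENS <- c("p", "pos", "positive", "1", "a", "active", "sensitizer")
NEGATIVE_TOKENS <- c("n", "neg", "negative", "0", "i", "inactive",
                     "non-sensitizer")
MISSING_TOKENS  <- c("", "na", "n/a", "nan")
MIT_NEGATIVE_TOKENS <- c("n", "neg", "negative", "inf")
DOMAIN_IN_TOKENS  <- c("1", "true", "t", "yes", "y", "in", "in domain", "id")
DOMAIN_OUT_TOKENS <- c("0", "false", "f", "no", "out", "out of domain", "od")
POTENCY_TOKENS <- list(
  GHS_1A = c("1a", "ghs 1a", "cat 1a"),
  GHS_1B = c("1b", "ghs 1b", "cat 1b"),
  NC     = c("nc", "not classified", "non-sensitizer")
)

#' Parse a binary assay call
#'
#' Translates a raw cell into a standardized call. Recognized positive
#' tokens: `p, pos, positive, 1, a, active, sensitizer`; negative tokens:
#' `n, neg, negative, 0, i, inactive, non-sensitizer`; missing tokens:
#' empty, `na`, `n/a`, `nan`. Unrecognized tokens are flagged by
#' [check_values()] upstream and never reach prediction; here they fall back
#' to `NA` (missing).
#'
#' @param raw Character vector of raw cell text.
#' @return Character vector over `"POSITIVE"`, `"NEGATIVE"`, `NA` (missing).
#' @export
#' @examples
#' parse_call(c("Positive", "0", "NA"))
parse_call <- function(raw) {
  x <- tolower(trimws(as.character(raw)))
  out <- rep(NA_character_, length(x))
  out[x %in% POSITIVE_TOKENS] <- "POSITIVE"
  out[x %in% NEGATIVE_TOKENS] <- "NEGATIVE"
  out
}

#' Parse an h-CLAT minimum induction threshold cell
#'
#' @param raw Character vector of raw cell text.
#' @return A list with numeric vector `mit` (`NA` unless a decimal value) and
#'   character vector `call` (`"POSITIVE"` for a numeric MIT, `"NEGATIVE"`
#'   for a negative-outcome token `n`/`neg`/`negative`/`inf`, `NA` missing).
#' @export
#' @examples
#' parse_mit(c("10", "negative", ""))
parse_mit <- function(raw) {
  x <- tolower(trimws(as.character(raw)))
  mit <- rep(NA_real_, length(x))
  call <- rep(NA_character_, length(x))
  neg <- x %in% MIT_NEGATIVE_TOKENS
  call[neg] <- "NEGATIVE"
  num <- !neg & is_decimal(x)
  mit[num] <- as.numeric(x[num])
  call[num] <- "POSITIVE"
  list(mit = mit, call = call)
}

parse_domain <- function(raw) {
  x <- tolower(trimws(as.character(raw)))
  out <- rep(NA, length(x))
  out[x %in% DOMAIN_IN_TOKENS] <- TRUE
  out[x %in% DOMAIN_OUT_TOKENS] <- FALSE
  out
}

parse_potency_class <- function(raw) {
  x <- tolower(trimws(as.character(raw)))
  out <- rep(NA_character_, length(x))
  for (cls in names(POTENCY_TOKENS)) out[x %in% POTENCY_TOKENS[[cls]]] <- cls
  out
}

#' Mean DPRA depletion
#'
#' Arithmetic mean of %Cysteine and %Lysine depletion; negative measured
#' depletions participate unmodified.
#'
#' @param cys_pct,lys_pct Numeric vectors of percent depletion.
#' @return Numeric vector of mean percent depletion.
#' @export
dpra_mean <- function(cys_pct, lys_pct) (cys_pct + lys_pct) / 2

#' Derive a DPRA hazard call from quantitative depletion
#'
#' Applies the DPRA prediction models: with both peptides, the chemical is
#' negative when mean depletion is at or below the two-value threshold
#' (6.38%); with %Cys only, negative at or below the Cys-only threshold
#' (13.89%). %Lys alone supports no published model and yields missing.
#'
#' @param cys_pct,lys_pct Numeric vectors (`NA` = missing).
#' @return Character vector over `"POSITIVE"`, `"NEGATIVE"`, `NA`.
#' @export
#' @examples
#' derive_dpra_call(c(0, 50, NA), c(0, NA, 20))
derive_dpra_call <- function(cys_pct, lys_pct) {
  k <- dass_constants()$dpra_hazard_call
  t_mean <- k$mean_threshold$value
  t_cys <- k$cys_only_threshold$value
  n <- max(length(cys_pct), length(lys_pct))
  cys_pct <- rep_len(cys_pct, n)
  lys_pct <- rep_len(lys_pct, n)
  out <- rep(NA_character_, n)
  both <- !is.na(cys_pct) & !is.na(lys_pct)
  out[both] <- ifelse(dpra_mean(cys_pct[both], lys_pct[both]) > t_mean,
                      "POSITIVE", "NEGATIVE")
  cys_only <- !is.na(cys_pct) & is.na(lys_pct)
  out[cys_only] <- ifelse(cys_pct[cys_only] > t_cys, "POSITIVE", "NEGATIVE")
  out
}

# Effective cell values: ERROR-flagged cells are masked to missing before
# interpretation, so defective input can never silently become a prediction.
masked_cells <- function(table, map, key, flags) {
  cells <- map_column(table, map, key)
  if (is.null(cells)) return(NULL)
  err <- error_cells(flags)
  bad <- err$row[err$endpoint == key & err$column_index == map[[key]]]
  cells[bad] <- ""
  cells
}

#' Harmonize a raw table into per-chemical records
#'
#' Produces one record per row with standardized calls and calculated
#' inputs: the mean DPRA depletion, a DPRA call derived from quantitative
#' depletion, and an h-CLAT call derived from the MIT. ERROR-flagged cells
#' are treated as missing. When a bound user call column disagrees with the
#' call derived from quantitative data, the derived call wins and a
#' `CALL_CONFLICT` warning flag is raised (quantitative endpoints are the
#' DAs' primary inputs).
#'
#' @param table A [dass_table].
#' @param map A `dass_column_map`.
#' @param flags A `dass_flags` data frame, usually
#'   `bind_flags(check_bindings(...), check_values(...))`; pass the result of
#'   [check_values()] at minimum.
#' @return A list with `records` (data frame, one row per chemical; columns
#'   `chem_id`, `cys_pct`, `lys_pct`, `dpra_mean_pct`, `dpra_call`,
#'   `hclat_mit`, `hclat_call`, `ks_call`, `insilico_call`,
#'   `insilico_in_domain`, `ref_hazard`, `ref_potency`) and `flags` (the
#'   input flags plus any conflict warnings).
#' @export
harmonize_records <- function(table, map, flags = NULL) {
  stopifnot(inherits(table, "dass_table"))
  if (is.null(flags)) flags <- new_flags()
  n <- nrow(table$body)
  num_or_na <- function(key) {
    cells <- masked_cells(table, map, key, flags)
    if (is.null(cells)) return(rep(NA_real_, n))
    x <- trimws(cells)
    x[tolower(x) %in% MISSING_TOKENS] <- NA
    out <- rep(NA_real_, n)
    ok <- !is.na(x) & is_decimal(x)
    out[ok] <- as.numeric(x[ok])
    out
  }
  call_or_na <- function(key) {
    cells <- masked_cells(table, map, key, flags)
    if (is.null(cells)) return(rep(NA_character_, n))
    parse_call(cells)
  }
  cys <- num_or_na("DPRA_CYS_PCT")
  lys <- num_or_na("DPRA_LYS_PCT")
  mean_pct <- ifelse(!is.na(cys) & !is.na(lys), dpra_mean(cys, lys), NA_real_)
  derived_dpra <- derive_dpra_call(cys, lys)
  user_dpra <- call_or_na("DPRA_CALL")

  mit_cells <- masked_cells(table, map, "HCLAT_MIT", flags)
  if (is.null(mit_cells)) {
    mit <- rep(NA_real_, n)
    derived_hclat <- rep(NA_character_, n)
  } else {
    parsed <- parse_mit(mit_cells)
    mit <- parsed$mit
    derived_hclat <- parsed$call
  }
  user_hclat <- call_or_na("HCLAT_CALL")

  conflicts <- list()
  resolve <- function(derived, user, key) {
    out <- ifelse(!is.na(derived), derived, user)
    clash <- which(!is.na(derived) & !is.na(user) & derived != user)
    if (length(clash) && key %in% names(map)) {
      conflicts[[length(conflicts) + 1]] <<- new_flags(
        endpoint = rep(key, length(clash)),
        column_name = rep(table$header[map[[key]]], length(clash)),
        column_index = rep(map[[key]], length(clash)),
        row = clash, code = rep("CALL_CONFLICT", length(clash)),
        severity = rep("WARNING", length(clash)),
        message = paste0("user-supplied call ", user[clash],
                         " disagrees with the call derived from quantitative",
                         " data (", derived[clash], "); derived call kept",
                         " (row ", clash, ")")
      )
    }
    out
  }
  dpra_call <- resolve(derived_dpra, user_dpra, "DPRA_CALL")
  hclat_call <- resolve(derived_hclat, user_hclat, "HCLAT_CALL")

  chem_cells <- map_column(table, map, "CHEM_ID")
  chem_id <- if (is.null(chem_cells)) paste0("row_", seq_len(n))
             else ifelse(nzchar(trimws(chem_cells)), trimws(chem_cells),
                         paste0("row_", seq_len(n)))
  dom_cells <- masked_cells(table, map, "INSILICO_DOMAIN", flags)
  pot_cells <- masked_cells(table, map, "REFERENCE_POTENCY", flags)

  records <- data.frame(
    chem_id = chem_id,
    cys_pct = cys, lys_pct = lys, dpra_mean_pct = mean_pct,
    dpra_call = dpra_call,
    hclat_mit = mit, hclat_call = hclat_call,
    ks_call = call_or_na("KS_CALL"),
    insilico_call = call_or_na("INSILICO_CALL"),
    insilico_in_domain = if (is.null(dom_cells)) rep(NA, n)
                         else parse_domain(dom_cells),
    ref_hazard = call_or_na("REFERENCE_HAZARD"),
    ref_potency = if (is.null(pot_cells)) rep(NA_character_, n)
                  else parse_potency_class(pot_cells),
    stringsAsFactors = FALSE
  )
  list(records = records, flags = do.call(bind_flags, c(list(flags), conflicts)))
}
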