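# Package-level state: guideline constants loaded once per session from the
# human-readable configuration file shipped with the package.
the <- new.env(parent = emptyenv())

#' Endpoint keys recognized by the package
#'
#' The closed set of endpoint identifiers that user columns can be bound to.
#' Each defined approach declares which subset it requires.
#'
#' @format A character vector of 11 endpoint keys.
#' @export
DASS_ENDPOINTS <- c(
  "CHEM_ID",
  "DPRA_CYS_PCT", "DPRA_LYS_PCT", "DPRA_CALL",
  "HCLAT_MIT", "HCLAT_CALL",
  "KS_CALL",
  "INSILICO_CALL", "INSILICO_DOMAIN",
  "REFERENCE_HAZARD", "REFERENCE_POTENCY"
)

#' Canonical template column names, one per endpoint key
#'
#' @format Named character vector mapping endpoint keys to the canonical
#'   header names used by [dass_template()] and recognized by
#'   [auto_map_columns()].
#' @export
DASS_TEMPLATE_HEADERS <- c(
  CHEM_ID           = "chem_id",
  DPRA_CYS_PCT      = "dpra_cys_pct",
  DPRA_LYS_PCT      = "dpra_lys_pct",
  DPRA_CALL         = "dpra_call",
  HCLAT_MIT         = "hclat_mit",
  HCLAT_CALL        = "hclat_call",
  KS_CALL           = "ks_call",
  INSILICO_CALL     = "insilico_call",
  INSILICO_DOMAIN   = "insilico_domain",
  REFERENCE_HAZARD  = "ref_hazard",
  REFERENCE_POTENCY = "ref_potency"
)

#' Defined approach identifiers
#' @format Character vector of the three DA identifiers.
#' @export
DASS_DAS <- c("TWO_OF_THREE", "KE31STS", "ITS")

# Enumerations used throughout. Hazard and potency levels are ordered for
# display; INCONCLUSIVE/NOT_APPLICABLE are terminal markers, not classes.
HAZARD_LEVELS  <- c("SENSITIZER", "NON_SENSITIZER", "INCONCLUSIVE")
POTENCY_LEVELS <- c("GHS_1A", "GHS_1B", "NC", "ONE_STAR", "INCONCLUSIVE",
                    "NOT_APPLICABLE")

# Endpoints each DA consumes (used for flag blocking and binding checks).
DA_INPUT_ENDPOINTS <- list(
  TWO_OF_THREE = c("DPRA_CYS_PCT", "DPRA_LYS_PCT", "DPRA_CALL",
                   "HCLAT_MIT", "HCLAT_CALL", "KS_CALL"),
  KE31STS      = c("DPRA_CYS_PCT", "DPRA_LYS_PCT", "DPRA_CALL",
                   "HCLAT_MIT", "HCLAT_CALL"),
  ITS          = c("DPRA_CYS_PCT", "DPRA_LYS_PCT",
                   "HCLAT_MIT", "INSILICO_CALL", "INSILICO_DOMAIN")
)

.onLoad <- function(libname, pkgname) {
  path <- system.file("extdata", "guideline_constants.yaml", package = pkgname,
                      lib.loc = libname)
  the$constants_path <- path
  the$constants <- yaml::read_yaml(path)
  the$constants_md5 <- unname(tools::md5sum(path))
}

#' Guideline decision constants
#'
#' Returns the decision thresholds and scoring tables used by the defined
#' approaches, as loaded from the package's human-readable configuration
#' file. Each constant carries its boundary direction and the guideline
#' document it was transcribed from.
#'
#' @return A nested list of constants (see
#'   `system.file("extdata", "guideline_constants.yaml", package = "dassr")`).
#' @export
#' @examples
#' dass_constants()$sts$mit_1a_max$value
dass_constants <- function() {
  if (is.null(the$constants)) .onLoad(NULL, "dassr")
  the$constants
}

#' Checksum of the constants file
#'
#' The md5 checksum of the guideline constants file, recorded in every
#' prediction's rationale trace so results are traceable to the exact
#' decision tables in force.
#'
#' @return A length-1 character string (md5 hex digest).
#' @export
dass_constants_checksum <- function() {
  if (is.null(the$constants_md5)) .onLoad(NULL, "dassr")
  the$constants_md5
}
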