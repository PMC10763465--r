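# Performance evaluation: contingency tables of DA predictions against
# user-supplied reference classifications, with exclusions itemized (a
# contingency table needs resolved classes on both axes; hiding exclusions
# would misstate performance).

HAZARD_CLASSES  <- c("SENSITIZER", "NON_SENSITIZER")
POTENCY_CLASSES <- c("GHS_1A", "GHS_1B", "NC")

#' Cross-tabulate predictions against reference classes
#'
#' Hazard tables are 2x2 over sensitizer/non-sensitizer; potency tables are
#' 3x3 over GHS 1A/1B/NC. Records with an inconclusive or blocked prediction
#' or a missing reference are excluded and itemized by reason; in potency
#' mode, `ONE_STAR` predictions (conclusive hazard, unresolved potency) are
#' excluded under their own reason.
#'
#' @param predictions Data frame of predictions for one DA (rows of
#'   `dass_results$predictions`), or the `dass_results` object itself with
#'   `da` naming the DA to evaluate.
#' @param references Character vector aligned with the prediction rows:
#'   hazard calls (`"POSITIVE"`/`"NEGATIVE"`, or sensitizer-class tokens) in
#'   HAZARD mode, potency classes (`"GHS_1A"`, `"GHS_1B"`, `"NC"`) in
#'   POTENCY mode. `NA` is a missing reference.
#' @param mode `"HAZARD"` or `"POTENCY"`.
#' @param da When `predictions` is a `dass_results` object: which DA to
#'   evaluate.
#' @return A `dass_contingency` object: list with `counts` (predicted x
#'   reference matrix), `excluded` (named integer vector by reason), `mode`,
#'   and `n` (records supplied).
#' @export
#' @examples
#' p <- data.frame(hazard = c("SENSITIZER", "NON_SENSITIZER"),
#'                 potency = "NOT_APPLICABLE", da = "TWO_OF_THREE",
#'                 blocked = FALSE)
#' build_contingency(p, c("POSITIVE", "NEGATIVE"), "HAZARD")$counts
build_contingency <- function(predictions, references,
                              mode = c("HAZARD", "POTENCY"), da = NULL) {
  mode <- match.arg(mode)
  if (inherits(predictions, "dass_results")) {
    stopifnot(!is.null(da))
    predictions <- predictions$predictions[
      predictions$predictions$da == da, , drop = FALSE]
    predictions <- predictions[order(predictions$row), , drop = FALSE]
  }
  n <- nrow(predictions)
  stopifnot(length(references) == n)
  if (mode == "POTENCY" && any(predictions$da == "TWO_OF_THREE")) {
    stop("The 2o3 DA does not predict GHS potency", call. = FALSE)
  }
  blocked <- if ("blocked" %in% names(predictions)) predictions$blocked
             else rep(FALSE, n)
  if (mode == "HAZARD") {
    pred <- predictions$hazard
    ref <- normalize_hazard_reference(references)
    classes <- HAZARD_CLASSES
    inconclusive <- pred == "INCONCLUSIVE"
    one_star <- rep(FALSE, n)
  } else {
    pred <- predictions$potency
    ref <- ifelse(references %in% POTENCY_CLASSES, references, NA_character_)
    classes <- POTENCY_CLASSES
    one_star <- pred == "ONE_STAR"
    inconclusive <- pred %in% c("INCONCLUSIVE", "NOT_APPLICABLE") & !one_star
  }
  excl_reason <- rep(NA_character_, n)
  excl_reason[is.na(ref)] <- "missing reference"
  excl_reason[inconclusive] <- "inconclusive prediction"
  excl_reason[one_star] <- "potency unresolved (1*)"
  excl_reason[blocked] <- "blocked by validation errors"
  keep <- is.na(excl_reason)
  counts <- table(factor(pred[keep], levels = classes),
                  factor(ref[keep], levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(predicted = classes, reference = classes))
  excluded <- table(excl_reason[!keep])
  excluded <- stats::setNames(as.integer(excluded), names(excluded))
  structure(list(counts = counts, excluded = excluded, mode = mode, n = n),
            class = "dass_contingency")
}

normalize_hazard_reference <- function(x) {
  out <- ifelse(x %in% c("POSITIVE", "SENSITIZER"), "SENSITIZER",
         ifelse(x %in% c("NEGATIVE", "NON_SENSITIZER", "NC"),
                "NON_SENSITIZER", NA_character_))
  out
}

#' @export
print.dass_contingency <- function(x, ...) {
  cat("<dass_contingency> mode ", x$mode, ", n = ", x$n, "\n", sep = "")
  print(x$counts)
  if (length(x$excluded)) {
    cat("excluded:\n")
    for (r in names(x$excluded)) cat("  ", r, ": ", x$excluded[[r]], "\n",
                                     sep = "")
  }
  invisible(x)
}

#' Summary metrics for a contingency table
#'
#' For 2x2 hazard tables: accuracy, sensitivity, specificity, and balanced
#' accuracy (the mean of sensitivity and specificity). For 3x3 potency
#' tables: accuracy and per-class sensitivity. Ratios with a zero
#' denominator are reported as `NA` and printed as `NOT_DEFINED`, never as
#' zero.
#'
#' @param table A `dass_contingency` object.
#' @return A `dass_metrics` object: list with `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_accuracy` (2x2) or `accuracy` and named
#'   `class_sensitivity` (3x3), plus `n_evaluated` and `n_excluded`.
#' @export
compute_metrics <- function(table) {
  stopifnot(inherits(table, "dass_contingency"))
  m <- table$counts
  total <- sum(m)
  if (total == 0) stop("no evaluable records", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    mode = table$mode,
    accuracy = sum(diag(m)) / total,
    n_evaluated = total,
    n_excluded = sum(table$excluded)
  )
  if (table$mode == "HAZARD") {
    tp <- m["SENSITIZER", "SENSITIZER"]
    fn <- m["NON_SENSITIZER", "SENSITIZER"]
    tn <- m["NON_SENSITIZER", "NON_SENSITIZER"]
    fp <- m["SENSITIZER", "NON_SENSITIZER"]
    out$sensitivity <- ratio(tp, tp + fn)
    out$specificity <- ratio(tn, tn + fp)
    out$balanced_accuracy <-
      if (is.na(out$sensitivity) || is.na(out$specificity)) NA_real_
      else (out$sensitivity + out$specificity) / 2
  } else {
    out$class_sensitivity <- vapply(colnames(m), function(cls) {
      ratio(m[cls, cls], sum(m[, cls]))
    }, numeric(1))
  }
  structure(out, class = "dass_metrics")
}

metric_text <- function(x) {
  if (is.na(x)) "NOT_DEFINED" else sprintf("%.3f", x)
}

#' @export
print.dass_metrics <- function(x, ...) {
  cat("<dass_metrics> mode ", x$mode, "\n", sep = "")
  cat("  n evaluated: ", x$n_evaluated, ", excluded: ", x$n_excluded, "\n",
      sep = "")
  cat("  accuracy: ", metric_text(x$accuracy), "\n", sep = "")
  if (x$mode == "HAZARD") {
    cat("  sensitivity: ", metric_text(x$sensitivity), "\n", sep = "")
    cat("  specificity: ", metric_text(x$specificity), "\n", sep = "")
    cat("  balanced accuracy: ", metric_text(x$balanced_accuracy), "\n",
        sep = "")
  } else {
    for (cls in names(x$class_sensitivity)) {
      cat("  sensitivity (", cls, "): ",
          metric_text(x$class_sensitivity[[cls]]), "\n", sep = "")
    }
  }
  invisible(x)
}

# Serialize a contingency table + metrics into a small text table (used by
# the CLI performance section and the XLSX performance sheet).
performance_section <- function(contingency, metrics, label) {
  m <- contingency$counts
  rows <- list(c("section", label, "", ""))
  rows[[length(rows) + 1]] <- c("", "", paste0("ref_", colnames(m)))
  for (r in rownames(m)) {
    rows[[length(rows) + 1]] <- c("counts", paste0("pred_", r),
                                  as.character(m[r, ]))
  }
  for (reason in names(contingency$excluded)) {
    rows[[length(rows) + 1]] <- c("excluded", reason,
                                  as.character(contingency$excluded[[reason]]),
                                  "")
  }
  mt <- function(name, v) c("metric", name, metric_text(v), "")
  rows[[length(rows) + 1]] <- c("metric", "n_evaluated",
                                as.character(metrics$n_evaluated), "")
  rows[[length(rows) + 1]] <- c("metric", "n_excluded",
                                as.character(metrics$n_excluded), "")
  rows[[length(rows) + 1]] <- mt("accuracy", metrics$accuracy)
  if (metrics$mode == "HAZARD") {
    rows[[length(rows) + 1]] <- mt("sensitivity", metrics$sensitivity)
    rows[[length(rows) + 1]] <- mt("specificity", metrics$specificity)
    rows[[length(rows) + 1]] <- mt("balanced_accuracy",
                                   metrics$balanced_accuracy)
  } else {
    for (cls in names(metrics$class_sensitivity)) {
      rows[[length(rows) + 1]] <- mt(paste0("sensitivity_", cls),
                                     metrics$class_sensitivity[[cls]])
    }
  }
  width <- max(lengths(rows))
  t(vapply(rows, function(r) { length(r) <- width; r[is.na(r)] <- ""; r },
           character(width)))
}
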