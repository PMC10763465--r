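#' Raw assay tables
#'
#' A `dass_table` holds one uploaded (or generated) per-chemical table with
#' every cell kept as text. No interpretation happens at this layer:
#' validation must see the user's literal input to produce faithful flags.
#'
#' @param header Character vector of column names (trimmed, non-empty;
#'   duplicates preserved verbatim).
#' @param body Character matrix with `length(header)` columns (may have zero
#'   rows). Recycled/padded cells are empty strings.
#' @param source_format One of `"TSV"`, `"CSV"`, `"XLSX"`, or `NA` for tables
#'   built in memory.
#' @return An object of class `dass_table`.
#' @export
dass_table <- function(header, body = NULL, source_format = NA_character_) {
  header <- trimws(as.character(header))
  if (any(!nzchar(header))) {
    stop("empty column name in header (column ",
         paste(which(!nzchar(header)), collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(body)) {
    body <- matrix(character(0), nrow = 0, ncol = length(header))
  }
  if (!is.matrix(body)) body <- as.matrix(body)
  storage.mode(body) <- "character"
  body[is.na(body)] <- ""
  if (ncol(body) != length(header)) {
    stop("body has ", ncol(body), " columns but header has ", length(header),
         call. = FALSE)
  }
  structure(
    list(header = header, body = unname(body), source_format = source_format),
    class = "dass_table"
  )
}

#' @export
print.dass_table <- function(x, ...) {
  cat("<dass_table> ", nrow(x$body), " rows x ", length(x$header),
      " columns (", if (is.na(x$source_format)) "in-memory" else x$source_format,
      ")\n", sep = "")
  cat("columns:", paste(x$header, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.dass_table <- function(x, ...) {
  df <- as.data.frame(x$body, stringsAsFactors = FALSE)
  names(df) <- x$header
  df
}

#' @export
dim.dass_table <- function(x) c(nrow(x$body), length(x$header))

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tsv = "TSV", txt = "TSV", tab = "TSV",
    csv = "CSV",
    xlsx = "XLSX",
    stop("cannot infer table format from extension ", sQuote(ext),
         " of ", sQuote(path), "; pass `format`", call. = FALSE)
  )
}

#' Read a per-chemical assay table
#'
#' Reads tab-delimited, comma-delimited, or Excel (xlsx) files into a
#' [dass_table], keeping every cell as text. The first row is the header;
#' leading/trailing whitespace is trimmed from header names. Short rows are
#' padded with empty cells (flagged downstream as empty values where bound).
#' For spreadsheets only the first worksheet is read and all cell values are
#' rendered to text. A header-only file parses to a zero-row table (so the
#' data template round-trips); a file with no content at all is an error.
#'
#' @param path Path to the file.
#' @param format Optional format override: `"TSV"`, `"CSV"`, or `"XLSX"`.
#'   Default infers from the extension (`.tsv`/`.txt` = TSV, `.csv` = CSV,
#'   `.xlsx` = XLSX).
#' @return A [dass_table].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("chem_id,dpra_call", "chem-1,positive"), tf)
#' read_dass_table(tf)
read_dass_table <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop("cannot read table: file not found: ", sQuote(path), call. = FALSE)
  }
  format <- if (is.null(format)) infer_format(path) else toupper(format)
  format <- match.arg(format, c("TSV", "CSV", "XLSX"))
  if (format == "XLSX") {
    return(read_table_xlsx(path))
  }
  lines <- readLines(path, warn = FALSE)
  bad <- which(!validUTF8(lines))
  if (length(bad)) {
    stop("undecodable bytes in ", sQuote(path), " at line ", bad[1],
         call. = FALSE)
  }
  # drop trailing blank lines (editors commonly add them)
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 1) {
    stop("empty table: ", sQuote(path), " has no rows", call. = FALSE)
  }
  if (format == "TSV") {
    cells <- strsplit(lines, "\t", fixed = TRUE)
  } else {
    cells <- parse_csv_lines(lines)
  }
  header <- trimws(cells[[1]])
  ncols <- length(header)
  body <- t(vapply(cells[-1], function(r) {
    length(r) <- ncols           # pad short rows; NA -> "" in constructor
    r[is.na(r)] <- ""
    if (length(r) > ncols) r <- r[seq_len(ncols)]
    r
  }, character(ncols)))
  if (ncols == 1) body <- matrix(body, ncol = 1)
  dass_table(header, body, source_format = format)
}

# RFC-4180-style CSV split: double quotes delimit fields, "" escapes a quote.
# Quoted fields may not span physical lines here (assay tables are one
# record per line).
parse_csv_lines <- function(lines) {
  lapply(lines, function(line) {
    scan(text = line, what = character(), sep = ",", quote = "\"",
         quiet = TRUE, strip.white = FALSE, na.strings = character(0),
         blank.lines.skip = FALSE)
  })
}

read_table_xlsx <- function(path) {
  cells <- readxl::read_excel(path, sheet = 1, col_names = FALSE,
                              col_types = "text",
                              .name_repair = "minimal")
  m <- as.matrix(cells)
  m[is.na(m)] <- ""
  if (nrow(m) < 1) {
    stop("empty table: ", sQuote(path), " has no rows", call. = FALSE)
  }
  dass_table(trimws(m[1, ]), m[-1, , drop = FALSE], source_format = "XLSX")
}

#' Canonical data template
#'
#' An empty-bodied table whose header holds the canonical column name for
#' each endpoint key. Data prepared on this template is auto-mapped by
#' [auto_map_columns()] with no manual column selection.
#'
#' @return A [dass_table] with 11 columns and zero rows.
#' @export
#' @examples
#' dass_template()$header
dass_template <- function() {
  dass_table(unname(DASS_TEMPLATE_HEADERS))
}

normalize_header <- function(x) gsub("[ _-]", "", tolower(trimws(x)))

#' Bind table columns to endpoint keys by header name
#'
#' Matches header names against the canonical template names
#' (case-insensitively; space, hyphen, and underscore are equivalent).
#' Unmatched endpoint keys remain unbound; completeness is judged per
#' selected defined approach by [check_bindings()], not here. If a canonical
#' name matches several headers the leftmost is bound and a note is attached.
#'
#' @param table A [dass_table].
#' @return A `dass_column_map`: named integer vector of 1-based column
#'   indices keyed by endpoint, with a `notes` attribute listing duplicate
#'   header candidates.
#' @export
#' @examples
#' auto_map_columns(dass_template())
auto_map_columns <- function(table) {
  stopifnot(inherits(table, "dass_table"))
  norm <- normalize_header(table$header)
  bindings <- integer(0)
  notes <- character(0)
  for (key in DASS_ENDPOINTS) {
    target <- normalize_header(DASS_TEMPLATE_HEADERS[[key]])
    hits <- which(norm == target)
    if (length(hits) >= 1) {
      bindings[[key]] <- hits[1]
      if (length(hits) > 1) {
        notes <- c(notes, paste0(
          key, ": headers ", paste(sQuote(table$header[hits]), collapse = ", "),
          " all match; leftmost (column ", hits[1], ") bound"))
      }
    }
  }
  dass_column_map(bindings, notes = notes)
}

#' Construct a column map
#'
#' @param bindings Named integer vector: endpoint key -> 1-based column index.
#'   Keys must belong to [DASS_ENDPOINTS]. May be partial or empty.
#' @param notes Character vector of informational notes (e.g. duplicate
#'   header candidates seen during auto-mapping).
#' @return A `dass_column_map`.
#' @export
dass_column_map <- function(bindings = integer(0), notes = character(0)) {
  bindings <- vapply(bindings, as.integer, integer(1))
  unknown <- setdiff(names(bindings), DASS_ENDPOINTS)
  if (length(unknown)) {
    stop("unknown endpoint key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(bindings < 1)) stop("column indices must be >= 1", call. = FALSE)
  structure(bindings, notes = notes, class = "dass_column_map")
}

#' @export
print.dass_column_map <- function(x, ...) {
  cat("<dass_column_map>\n")
  if (!length(x)) {
    cat("  (no bindings)\n")
  } else {
    for (k in names(x)) cat("  ", format(k, width = 18), "-> column ", x[[k]], "\n", sep = "")
  }
  for (n in attr(x, "notes")) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

# Column value accessor: bound column of a table for an endpoint, or NULL.
map_column <- function(table, map, key) {
  if (!key %in% names(map)) return(NULL)
  table$body[, map[[key]]]
}

sanitize_tsv_cell <- function(x) gsub("[\t\r\n]", " ", x)

#' Write a raw table
#'
#' Serializes a [dass_table] to TSV, CSV, or XLSX. TSV uses no quoting
#' dialect: tab or newline characters inside cells are replaced by a space
#' (such cells are flagged by [check_values()] beforehand).
#'
#' @param table A [dass_table].
#' @param path Output path.
#' @param format `"TSV"`, `"CSV"`, or `"XLSX"`; default inferred from the
#'   extension of `path`.
#' @return `path`, invisibly.
#' @export
write_dass_table <- function(table, path, format = NULL) {
  stopifnot(inherits(table, "dass_table"))
  format <- if (is.null(format)) infer_format(path) else toupper(format)
  format <- match.arg(format, c("TSV", "CSV", "XLSX"))
  if (format == "TSV") {
    rows <- apply(rbind(table$header, table$body), 1, function(r) {
      paste(sanitize_tsv_cell(r), collapse = "\t")
    })
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(rows, con, sep = "\n", useBytes = TRUE)
  } else if (format == "CSV") {
    df <- as.data.frame(table)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    sheets <- list(Data = list(header = table$header, body = table$body))
    write_minimal_xlsx(sheets, path)
  }
  invisible(path)
}
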