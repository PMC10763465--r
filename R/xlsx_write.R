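# Minimal XLSX writer.
#
# An .xlsx file is a ZIP archive of XML parts. This writer emits the smallest
# conforming workbook: all cells are inline strings (no shared-string table,
# no styles), one worksheet per sheet, ZIP entries stored uncompressed with
# fixed timestamps so identical inputs give byte-identical files.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

sheet_xml <- function(header, body) {
  all_rows <- rbind(header, body)
  row_xml <- apply(all_rows, 1, function(r) {
    cells <- paste0(
      "<c t=\"inlineStr\"><is><t xml:space=\"preserve\">",
      xml_escape(enc2utf8(r)),
      "</t></is></c>",
      collapse = ""
    )
    paste0("<row>", cells, "</row>")
  })
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<worksheet xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\">",
    "<sheetData>", paste(row_xml, collapse = ""), "</sheetData></worksheet>"
  )
}

# CRC-32 of a raw vector, recovered from the trailer of a gzip stream
# (RFC 1952: the last 8 bytes are CRC32 then ISIZE, little-endian).
crc32_raw <- function(r) {
  g <- memCompress(r, type = "gzip")
  n <- length(g)
  g[(n - 7):(n - 4)]
}

int_le <- function(x, width) {
  as.raw(bitwAnd(vapply(0:(width - 1), function(i) {
    floor(x / 2^(8 * i))
  }, numeric(1)), 255))
}

# Store-only ZIP archive with fixed DOS timestamps (1980-01-01 00:00).
zip_store <- function(entries, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- vector("list", length(entries))
  pos <- 0L
  dos_time <- int_le(0, 2)
  dos_date <- int_le(33, 2)  # day 1, month 1, year 1980
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[[i]] <- crc32_raw(data)
    local_header <- c(
      int_le(0x04034b50, 4), int_le(20, 2), int_le(0, 2), int_le(0, 2),
      dos_time, dos_date, crcs[[i]],
      int_le(length(data), 4), int_le(length(data), 4),
      int_le(length(name), 2), int_le(0, 2)
    )
    offsets[i] <- pos
    writeBin(c(local_header, name, data), con)
    pos <- pos + length(local_header) + length(name) + length(data)
  }
  cd_start <- pos
  cd_len <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    central <- c(
      int_le(0x02014b50, 4), int_le(20, 2), int_le(20, 2), int_le(0, 2),
      int_le(0, 2), dos_time, dos_date, crcs[[i]],
      int_le(length(data), 4), int_le(length(data), 4),
      int_le(length(name), 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
      int_le(0, 2), int_le(0, 4), int_le(offsets[i], 4)
    )
    writeBin(c(central, name), con)
    cd_len <- cd_len + length(central) + length(name)
  }
  eocd <- c(
    int_le(0x06054b50, 4), int_le(0, 2), int_le(0, 2),
    int_le(length(entries), 2), int_le(length(entries), 2),
    int_le(cd_len, 4), int_le(cd_start, 4), int_le(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}

# sheets: named list; each element is list(header = chr, body = chr matrix)
write_minimal_xlsx <- function(sheets, path) {
  n <- length(sheets)
  stopifnot(n >= 1, !is.null(names(sheets)))
  content_types <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/content-types\">",
    "<Default Extension=\"rels\" ContentType=\"application/vnd.openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Override PartName=\"/xl/workbook.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml\"/>",
    paste0("<Override PartName=\"/xl/worksheets/sheet", seq_len(n),
           ".xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml\"/>",
           collapse = ""),
    "</Types>"
  )
  root_rels <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument\" Target=\"xl/workbook.xml\"/>",
    "</Relationships>"
  )
  workbook <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<workbook xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\" ",
    "xmlns:r=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships\">",
    "<sheets>",
    paste0("<sheet name=\"", xml_escape(names(sheets)), "\" sheetId=\"",
           seq_len(n), "\" r:id=\"rId", seq_len(n), "\"/>", collapse = ""),
    "</sheets></workbook>"
  )
  wb_rels <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    paste0("<Relationship Id=\"rId", seq_len(n),
           "\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet\" Target=\"worksheets/sheet",
           seq_len(n), ".xml\"/>", collapse = ""),
    "</Relationships>"
  )
  entries <- list()
  entries[["[Content_Types].xml"]] <- charToRaw(content_types)
  entries[["_rels/.rels"]] <- charToRaw(root_rels)
  entries[["xl/workbook.xml"]] <- charToRaw(workbook)
  entries[["xl/_rels/workbook.xml.rels"]] <- charToRaw(wb_rels)
  for (i in seq_len(n)) {
    entries[[paste0("xl/worksheets/sheet", i, ".xml")]] <-
      charToRaw(sheet_xml(sheets[[i]]$header, sheets[[i]]$body))
  }
  zip_store(entries, path)
}
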