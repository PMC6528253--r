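# A minimal .xlsx writer used only to exercise the workbook-reading path in
# tests: spreadsheets are written as stored (uncompressed) ZIP members with
# inline-string cells. Not a general xlsx implementation.

crc32_table <- local({
  poly <- -306674912L # 0xEDB88320 as a signed 32-bit integer
  vapply(0:255, function(ch) {
    r <- as.integer(ch)
    for (k in 1:8) {
      r <- if (bitwAnd(r, 1L) != 0L) bitwXor(bitwShiftR(r, 1L), poly) else bitwShiftR(r, 1L)
    }
    r
  }, integer(1))
})

crc32 <- function(bytes) {
  crc <- -1L # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

write_stored_zip <- function(path, files) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  offsets <- integer(length(files))
  sizes <- integer(length(files))
  crcs <- integer(length(files))
  pos <- 0L
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- charToRaw(files[[i]])
    offsets[i] <- pos
    sizes[i] <- length(data)
    crcs[i] <- crc32(data)
    w32(0x04034b50); w16(20); w16(0); w16(0); w16(0); w16(0)
    w32(crcs[i]); w32(sizes[i]); w32(sizes[i])
    w16(length(name)); w16(0)
    writeBin(name, con); writeBin(data, con)
    pos <- pos + 30L + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    w32(0x02014b50); w16(20); w16(20); w16(0); w16(0); w16(0); w16(0)
    w32(crcs[i]); w32(sizes[i]); w32(sizes[i])
    w16(length(name)); w16(0); w16(0); w16(0); w16(0); w32(0)
    w32(offsets[i])
    writeBin(name, con)
    pos <- pos + 46L + length(name)
  }
  w32(0x06054b50); w16(0); w16(0); w16(length(files)); w16(length(files))
  w32(pos - cd_start); w32(cd_start); w16(0)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

sheet_xml <- function(m) {
  ns <- "http://schemas.openxmlformats.org/spreadsheetml/2006/main"
  rows <- vapply(seq_len(nrow(m)), function(i) {
    cells <- vapply(seq_len(ncol(m)), function(j) {
      v <- m[i, j]
      if (is.na(v) || v == "") return("")
      # spreadsheet refs are column-letter + row-number
      ref <- platefit::well_label(j - 1L, i - 1L)
      sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref, xml_escape(v))
    }, character(1))
    sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
  }, character(1))
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    sprintf('<worksheet xmlns="%s"><sheetData>', ns),
    paste(rows, collapse = ""),
    "</sheetData></worksheet>"
  )
}

# ... : named character matrices, one per sheet
write_minimal_xlsx <- function(path, ...) {
  sheets <- list(...)
  stopifnot(length(sheets) >= 1L, !is.null(names(sheets)))
  idx <- seq_along(sheets)
  sheet_tags <- paste(sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>', names(sheets), idx, idx
  ), collapse = "")
  rel_tags <- paste(sprintf(
    paste0('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/',
           'officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>'),
    idx, idx
  ), collapse = "")
  override_tags <- paste(sprintf(
    paste0('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType=',
           '"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>'),
    idx
  ), collapse = "")
  files <- c(
    "[Content_Types].xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType=',
      '"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      override_tags, "</Types>"
    ),
    "_rels/.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/',
      'officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
      "</Relationships>"
    ),
    "xl/workbook.xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
      'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
      "<sheets>", sheet_tags, "</sheets></workbook>"
    ),
    "xl/_rels/workbook.xml.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      rel_tags, "</Relationships>"
    )
  )
  sheet_files <- setNames(
    vapply(sheets, sheet_xml, character(1)),
    sprintf("xl/worksheets/sheet%d.xml", idx)
  )
  write_stored_zip(path, c(files, sheet_files))
}
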