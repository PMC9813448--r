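# Minimal OOXML spreadsheet writer.
#
# Writes multi-sheet .xlsx workbooks with inline strings, plain numbers
# and date-formatted cells -- the three cell kinds the exchange formats
# here need. Output is byte-deterministic for identical input (fixed
# member timestamps), which the fixture generator relies on. Reading is
# done with readxl; this writer exists only because no spreadsheet writer
# ships with the package's dependency set.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

col_letter <- function(i) {
  out <- ""
  while (i > 0) {
    r <- (i - 1L) %% 26L
    out <- paste0(LETTERS[r + 1L], out)
    i <- (i - 1L) %/% 26L
  }
  out
}

# one worksheet: header row from names(df); column cell kind from column
# class (Date -> date cell, numeric -> number, else inline string);
# NA / empty-string cells are omitted
sheet_xml <- function(df) {
  nr <- nrow(df)
  nc <- ncol(df)
  rows <- character(nr + 1L)
  hdr <- vapply(seq_len(nc), function(j) {
    sprintf('<c r="%s1" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            col_letter(j), xml_escape(names(df)[j]))
  }, character(1))
  rows[1] <- paste0('<row r="1">', paste(hdr, collapse = ""), "</row>")
  is_date <- vapply(df, function(col) inherits(col, "Date"), logical(1))
  is_num <- vapply(df, is.numeric, logical(1)) & !is_date
  for (i in seq_len(nr)) {
    cells <- character(0)
    for (j in seq_len(nc)) {
      v <- df[[j]][i]
      if (is.na(v) || (!is_date[j] && !is_num[j] && !nzchar(as.character(v)))) next
      ref <- paste0(col_letter(j), i + 1L)
      cells <- c(cells, if (is_date[j]) {
        # 1900 date system: serial days since 1899-12-30
        sprintf('<c r="%s" s="1"><v>%d</v></c>', ref,
                as.integer(unclass(v)) + 25569L)
      } else if (is_num[j]) {
        sprintf('<c r="%s"><v>%s</v></c>', ref,
                format(v, scientific = FALSE, trim = TRUE, digits = 15))
      } else {
        sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
                ref, xml_escape(as.character(v)))
      })
    }
    rows[i + 1L] <- paste0(sprintf('<row r="%d">', i + 1L),
                           paste(cells, collapse = ""), "</row>")
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"><sheetData>',
         paste(rows, collapse = ""), "</sheetData></worksheet>")
}

#' Write a minimal xlsx workbook
#'
#' @param sheets named list of data frames; list names become sheet names,
#'   column names the header row. `Date` columns become native date cells,
#'   numeric columns number cells, everything else text. `NA` and empty
#'   strings produce empty cells.
#' @param path output path.
#' @return `path`, invisibly. Byte-identical output for identical input.
#' @export
write_xlsx_minimal <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1L, !is.null(names(sheets)))
  n <- length(sheets)
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(tmp, "_rels"))
  dir.create(file.path(tmp, "xl", "_rels"))

  put <- function(rel, text) {
    con <- file(file.path(tmp, rel), open = "wb")
    on.exit(close(con))
    writeLines(text, con, useBytes = TRUE)
  }

  put("[Content_Types].xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    "</Types>"))
  put(file.path("_rels", ".rels"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"))
  put(file.path("xl", "workbook.xml"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = ""),
    "</sheets></workbook>"))
  put(file.path("xl", "_rels", "workbook.xml.rels"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
            n + 1L),
    "</Relationships>"))
  put(file.path("xl", "styles.xml"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font/></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf numFmtId="0"/></cellStyleXfs>',
    # style 1 = built-in date format; readxl detects it as a date cell
    '<cellXfs count="2"><xf numFmtId="0" xfId="0"/><xf numFmtId="14" xfId="0" applyNumberFormat="1"/></cellXfs>',
    "</styleSheet>"))
  for (i in seq_len(n)) {
    put(file.path("xl", "worksheets", sprintf("sheet%d.xml", i)),
        sheet_xml(as.data.frame(sheets[[i]])))
  }

  files <- list.files(tmp, recursive = TRUE, all.files = TRUE, no.. = TRUE,
                      full.names = TRUE)
  Sys.setFileTime(files, as.POSIXct("2020-01-01 00:00:00", tz = "UTC"))
  # anchor before the working directory changes for zipping
  path <- file.path(normalizePath(dirname(path), mustWork = TRUE), basename(path))
  if (file.exists(path)) unlink(path)
  old <- setwd(tmp)
  on.exit(setwd(old), add = TRUE)
  zip::zip(path, list.files(tmp, recursive = TRUE, all.files = TRUE, no.. = TRUE),
           include_directories = FALSE)
  invisible(path)
}

# read one sheet with every cell coerced to text: strings stay strings,
# numbers lose no precision, date cells become ISO dates; NA -> ""
read_sheet_text <- function(path, sheet) {
  cells <- suppressMessages(readxl::read_excel(
    path, sheet = sheet, col_types = "list",
    .name_repair = "unique"))
  out <- lapply(cells, function(col) {
    vapply(col, function(v) {
      if (is.null(v) || length(v) == 0L || all(is.na(v))) ""
      else if (inherits(v, c("POSIXct", "Date"))) format(v, "%Y-%m-%d")
      else if (is.numeric(v)) num_to_str(v)
      else str_trim(as.character(v))
    }, character(1))
  })
  names(out) <- names(cells)
  tibble::as_tibble(out)
}
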