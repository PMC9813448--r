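# The exchange formats.
#
# Input: a two-sheet workbook -- first sheet "Locations" (eleven fixed
# columns, only plot/row/plant or alternatively the accession name
# obligatory), second sheet "Traits" (five fixed columns). Accepted
# containers: .xlsx, legacy .xls (read-only), or a CSV pair
# <name>_locations.csv + <name>_traits.csv.
#
# Output: one table, one row per location in field-book order, with all
# input location columns verbatim, two remarks columns, then one column
# per descriptor. Excel output stores dates as native date cells; CSV
# stores ISO-8601 and follows the common dialect (comma, double-quote
# quoting, UTF-8).

TRAIT_SHEET_HEADERS <- c("shortcut", "description", "type", "values", "remark")
REMARK_HEADERS <- c("location info", "plant note")

is_spreadsheet <- function(path) grepl("\\.(xlsx|xls)$", path, ignore.case = TRUE)

csv_pair <- function(path) {
  stem <- sub("(_locations)?\\.csv$", "", path, ignore.case = TRUE)
  list(locations = paste0(stem, "_locations.csv"),
       traits = paste0(stem, "_traits.csv"))
}

read_csv_text <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE,
                  show_col_types = FALSE, name_repair = "minimal")
}

# pad/trim a text table to exactly n columns
fit_columns <- function(tab, n) {
  if (ncol(tab) > n) tab <- tab[, seq_len(n)]
  while (ncol(tab) < n) tab[[paste0("pad", ncol(tab) + 1L)]] <- ""
  tab
}

drop_empty_rows <- function(tab) {
  if (nrow(tab) == 0L) return(tab)
  keep <- apply(tab, 1, function(r) any(nzchar(str_trim(r))))
  tab[keep, , drop = FALSE]
}

#' Read an input workbook into a field book
#'
#' Parses the Locations and Traits sheets, validates every location row
#' (invalid rows are reported with their sheet row numbers and excluded),
#' parses all descriptors (unknown type codes and duplicate shortcuts
#' abort the import), and returns a session with an empty observation
#' matrix and the cursor at the first location / first selected
#' descriptor. Sheets are identified by name (`Locations` / `Traits`,
#' case-insensitive) when present, else by position (first / second).
#'
#' @param path `.xlsx`/`.xls` workbook, or a CSV pair addressed by either
#'   member or the common stem (`<name>_locations.csv` / `<name>_traits.csv`).
#' @param options,registry passed to [fieldbook()].
#' @return a `fieldbook`; the attribute `import_report` lists header
#'   warnings and skipped invalid rows.
#' @export
read_input <- function(path, options = list(), registry = bbch_bootstrap_registry()) {
  if (is_spreadsheet(path)) {
    if (!file.exists(path)) {
      stop_io(sprintf("input workbook '%s' does not exist", path),
              subclass = "pheno_missing_file")
    }
    sheets <- readxl::excel_sheets(path)
    if (length(sheets) < 2L) {
      stop_validation("input workbook needs two sheets (Locations, Traits)",
                      subclass = "pheno_missing_sheet")
    }
    li <- match("locations", tolower(str_trim(sheets)))
    ti <- match("traits", tolower(str_trim(sheets)))
    if (is.na(li)) li <- 1L
    if (is.na(ti)) ti <- 2L
    loc_tab <- read_sheet_text(path, li)
    trait_tab <- read_sheet_text(path, ti)
  } else {
    pair <- csv_pair(path)
    for (f in unlist(pair)) {
      if (!file.exists(f)) {
        stop_io(sprintf("input file '%s' does not exist", f),
                subclass = "pheno_missing_file")
      }
    }
    loc_tab <- read_csv_text(pair$locations)
    trait_tab <- read_csv_text(pair$traits)
  }

  report <- list(header_warnings = character(0),
                 invalid_locations = tibble::tibble(row = integer(0),
                                                    reason = character(0)))

  # -- locations sheet
  loc_headers <- str_trim(names(loc_tab))
  merged <- length(loc_headers) >= 4L &&
    grepl("accession name and number", tolower(loc_headers[4]))
  if (merged && ncol(loc_tab) == length(LOCATION_FIELDS) - 1L) {
    # merged "accession name and number" column: value kept as the name
    loc_tab <- tibble::add_column(loc_tab, ..accnum = "", .after = 4L)
  } else {
    mism <- which(tolower(loc_headers[seq_len(min(length(loc_headers), 11L))]) !=
                    LOCATION_HEADERS[seq_len(min(length(loc_headers), 11L))])
    if (length(mism) || length(loc_headers) != 11L) {
      w <- sprintf("Locations header differs from the expected '%s'",
                   paste(LOCATION_HEADERS, collapse = ", "))
      warning(w, call. = FALSE)
      report$header_warnings <- c(report$header_warnings, w)
    }
  }
  loc_tab <- fit_columns(loc_tab, length(LOCATION_FIELDS))
  names(loc_tab) <- LOCATION_FIELDS
  for (f in LOCATION_FIELDS) loc_tab[[f]] <- str_trim(loc_tab[[f]])
  nonempty <- apply(loc_tab, 1, function(r) any(nzchar(r)))
  sheet_rows <- which(nonempty) + 1L   # +1: header row
  loc_tab <- loc_tab[nonempty, , drop = FALSE]

  verdicts <- lapply(seq_len(nrow(loc_tab)), function(i) validate_location(loc_tab[i, ]))
  ok <- vapply(verdicts, `[[`, logical(1), "valid")
  if (any(!ok)) {
    bad <- tibble::tibble(
      row = sheet_rows[!ok],
      reason = vapply(verdicts[!ok], `[[`, character(1), "reason"))
    report$invalid_locations <- bad
    warning(sprintf("skipping %d invalid location row(s): %s", nrow(bad),
                    paste(sprintf("row %d (%s)", bad$row, bad$reason), collapse = "; ")),
            call. = FALSE)
  }
  loc_tab <- loc_tab[ok, , drop = FALSE]
  if (nrow(loc_tab) == 0L) {
    stop_validation("input contains no valid location rows",
                    subclass = "pheno_no_locations")
  }

  # -- traits sheet
  trait_headers <- str_trim(tolower(names(trait_tab)))
  if (!identical(trait_headers[seq_len(min(5L, length(trait_headers)))],
                 TRAIT_SHEET_HEADERS[seq_len(min(5L, length(trait_headers)))]) ||
      length(trait_headers) != 5L) {
    w <- sprintf("Traits header differs from the expected '%s'",
                 paste(TRAIT_SHEET_HEADERS, collapse = ", "))
    warning(w, call. = FALSE)
    report$header_warnings <- c(report$header_warnings, w)
  }
  trait_tab <- fit_columns(trait_tab, 5L)
  names(trait_tab) <- c("shortcut", "description", "type", "values", "remark")
  trait_tab <- drop_empty_rows(trait_tab)
  if (nrow(trait_tab) == 0L) {
    stop_validation("input contains no descriptors", subclass = "pheno_no_descriptors")
  }
  desc_rows <- vector("list", nrow(trait_tab))
  for (i in seq_len(nrow(trait_tab))) {
    desc_rows[[i]] <- withCallingHandlers(
      tryCatch(
        trait_descriptor(trait_tab$shortcut[i], trait_tab$description[i],
                         trait_tab$type[i], trait_tab$values[i],
                         trait_tab$remark[i]),
        pheno_validation_error = function(e) {
          stop_validation(sprintf("Traits sheet row %d: %s", i + 1L, conditionMessage(e)),
                          subclass = class(e)[1])
        }),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  descriptors <- do.call(rbind, desc_rows)

  book <- fieldbook(loc_tab, descriptors, options = options, registry = registry)
  attr(book, "import_report") <- report
  book
}

# assemble the output table: list(text = all-character df, typed = df with
# native column types for spreadsheet output)
output_table <- function(book) {
  n <- nrow(book$locations)
  loc <- as.data.frame(book$locations, stringsAsFactors = FALSE)
  names(loc) <- LOCATION_HEADERS
  rem_loc <- rem_plant <- character(n)
  for (i in seq_len(n)) {
    r <- book$remarks[[as.character(i)]]
    if (!is.null(r)) {
      rem_loc[i] <- r$location_info
      rem_plant[i] <- r$plant_note
    }
  }
  text_df <- loc
  text_df[[REMARK_HEADERS[1]]] <- rem_loc
  text_df[[REMARK_HEADERS[2]]] <- rem_plant
  typed_df <- text_df
  for (k in seq_len(nrow(book$descriptors))) {
    d <- book$descriptors[k, ]
    cells <- lapply(seq_len(n), function(i) get_observation(book, i, d$shortcut))
    text_col <- vapply(cells, serialize_observation, character(1))
    typed_col <- if (d$type == TRAIT_TYPES[["measured_value"]]) {
      vapply(cells, function(o) if (is.null(o)) NA_real_ else o$value, numeric(1))
    } else if (d$type == TRAIT_TYPES[["date"]]) {
      as.Date(vapply(cells, function(o) if (is.null(o)) NA_character_ else iso_date(o$value),
                     character(1)))
    } else {
      text_col
    }
    text_df[[d$shortcut]] <- text_col
    typed_df[[d$shortcut]] <- typed_col
  }
  list(text = text_df, typed = typed_df)
}

#' Write the output table of a session
#'
#' One row per location in field-book order: the eleven location columns
#' verbatim (including the hidden database-key), the two remarks columns,
#' then one column per descriptor. Unrecorded cells stay empty;
#' multi-valued ratings are joined with `","`. Excel output stores dates
#' as native date cells, CSV as ISO-8601 text.
#'
#' @param book a `fieldbook`.
#' @param path output path.
#' @param format `"xlsx"` or `"csv"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_output <- function(book, path,
                         format = if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "xlsx") {
  format <- match.arg(format, c("xlsx", "csv"))
  tabs <- output_table(book)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0L) {
    stop_io(sprintf("cannot write to '%s'", dir), subclass = "pheno_unwritable")
  }
  if (format == "csv") {
    readr::write_csv(tabs$text, path, na = "")
  } else {
    write_xlsx_minimal(list(Results = tabs$typed), path)
  }
  invisible(path)
}

#' Restore observations from an output file
#'
#' Re-reads a file produced by [write_output()] against the matching field
#' book (same locations and descriptor list), re-validating every
#' non-empty cell through [validate_value()]. Cells that fail validation
#' are not stored; they are collected -- with their raw value -- in the
#' `validation_report` attribute and summarized in a warning.
#'
#' @param path output file (`.xlsx` or `.csv`).
#' @param book the `fieldbook` the file belongs to.
#' @return the book with observations and remarks restored.
#' @export
read_output <- function(path, book) {
  if (!file.exists(path)) {
    stop_io(sprintf("output file '%s' does not exist", path),
            subclass = "pheno_missing_file")
  }
  tab <- if (is_spreadsheet(path)) read_sheet_text(path, 1L) else read_csv_text(path)
  nloc_cols <- length(LOCATION_FIELDS)
  want <- nloc_cols + 2L + nrow(book$descriptors)
  if (ncol(tab) != want) {
    stop_validation(
      sprintf("output file has %d columns; expected %d (%d location + 2 remarks + %d descriptors)",
              ncol(tab), want, nloc_cols, nrow(book$descriptors)),
      subclass = "pheno_output_mismatch")
  }
  got_shortcuts <- str_trim(names(tab)[(nloc_cols + 3L):ncol(tab)])
  if (!identical(got_shortcuts, book$descriptors$shortcut)) {
    stop_validation("descriptor columns do not match the field book's descriptor list",
                    subclass = "pheno_output_mismatch")
  }
  if (nrow(tab) != nrow(book$locations)) {
    stop_validation(sprintf("output file has %d data rows; the field book has %d locations",
                            nrow(tab), nrow(book$locations)),
                    subclass = "pheno_output_mismatch")
  }
  for (i in seq_len(nrow(tab))) {
    key_file <- str_trim(unlist(tab[i, 1:4], use.names = FALSE))
    key_book <- unlist(book$locations[i, c("plot", "row", "plant", "accession_name")],
                       use.names = FALSE)
    if (!identical(key_file, key_book)) {
      stop_validation(sprintf("row %d does not match the field book's location order", i + 1L),
                      subclass = "pheno_output_mismatch")
    }
  }

  book$observations <- list()
  book$remarks <- list()
  failures <- list()
  for (i in seq_len(nrow(tab))) {
    li <- str_trim(tab[[nloc_cols + 1L]][i])
    pn <- str_trim(tab[[nloc_cols + 2L]][i])
    if (nzchar(li) || nzchar(pn)) {
      book$remarks[[as.character(i)]] <- list(location_info = li, plant_note = pn)
    }
    for (k in seq_len(nrow(book$descriptors))) {
      raw <- str_trim(tab[[nloc_cols + 2L + k]][i])
      if (!nzchar(raw)) next
      d <- book$descriptors[k, ]
      obs <- tryCatch(
        validate_value(d, raw, multiple = book$options$multiple_selection,
                       registry = book$registry,
                       strict = book$options$strict_rating),
        pheno_validation_error = function(e) e)
      if (inherits(obs, "observation")) {
        book$observations[[obs_key(i, d$shortcut)]] <- obs
      } else {
        failures[[length(failures) + 1L]] <-
          tibble::tibble(location_index = i, shortcut = d$shortcut,
                         value = raw, message = conditionMessage(obs))
      }
    }
  }
  report <- if (length(failures)) do.call(rbind, failures) else
    tibble::tibble(location_index = integer(0), shortcut = character(0),
                   value = character(0), message = character(0))
  if (nrow(report)) {
    warning(sprintf("%d cell(s) failed re-validation and were not restored (see attr 'validation_report')",
                    nrow(report)), call. = FALSE)
  }
  attr(book, "validation_report") <- report
  book
}
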