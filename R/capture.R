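# Recording: applying values at the cursor, remarks, quick dates, photo
# names, dated BBCH descriptors, and selection.

#' Record a value at the cursor
#'
#' Validates `raw` against the cursor's descriptor and stores the
#' observation. On success the cursor auto-advances to the next selected
#' descriptor -- unless multiple-selection mode is active, which removes
#' the automatic jumping so further codes can be added to the same cell.
#' On a validation error nothing is stored and the cursor does not move
#' (the operation is atomic). Re-recording an already filled cell
#' overwrites the value and appends an audit line to the book's log.
#'
#' @param book a `fieldbook` with a valid (non-end) cursor.
#' @param raw the value as entered.
#' @return the updated `fieldbook`.
#' @export
record <- function(book, raw) {
  cur <- book$cursor
  if (cur$at_end) {
    stop_validation("cursor is past the end of the traversal plan",
                    subclass = "pheno_cursor_at_end")
  }
  d <- get_descriptor(book, cur$trait)
  obs <- validate_value(d, raw, multiple = book$options$multiple_selection,
                        registry = book$registry, context = book$context,
                        strict = book$options$strict_rating)
  key <- obs_key(cur$loc, cur$trait)
  if (!is.null(book$observations[[key]])) {
    book$log <- c(book$log,
                  sprintf("overwrite %s@%d: '%s' -> '%s'", cur$trait, cur$loc,
                          serialize_observation(book$observations[[key]]),
                          serialize_observation(obs)))
  }
  book$observations[[key]] <- obs
  if (obs$type == TRAIT_TYPES[["bbch"]]) {
    book$context <- bbch_sticky_context(structure(obs$value, class = "bbch_code"))
  }
  if (!book$options$multiple_selection) {
    book$cursor <- advance(book)
  }
  book
}

#' Quick date entry
#'
#' The date-type entry buttons: day before yesterday, yesterday, today,
#' tomorrow, day after tomorrow (offsets -2..+2 relative to `today`), or
#' an explicitly chosen date.
#'
#' @param offset integer day offset in `-2:2`; ignored when `date` is given.
#' @param date explicit `Date` or ISO-8601 string.
#' @param today reference date (defaults to the system date).
#' @return a `Date`.
#' @export
#' @examples
#' quick_date(-2, today = as.Date("2022-03-01"))  # 2022-02-27
quick_date <- function(offset = 0L, date = NULL, today = Sys.Date()) {
  if (!is.null(date)) {
    if (inherits(date, "Date")) return(date)
    d <- parse_iso_date(as.character(date))
    if (is.null(d)) {
      stop_validation(sprintf("'%s' is not a valid date (expected YYYY-MM-DD)", date),
                      subclass = "pheno_bad_date")
    }
    return(d)
  }
  if (length(offset) != 1L || is.na(offset) || !offset %in% -2:2) {
    stop_validation("quick-date offset must be between -2 and +2 days",
                    subclass = "pheno_bad_date")
  }
  today + as.integer(offset)
}

#' Set remarks for the cursor's location
#'
#' Two independent notes per location: general information on the location
#' itself and a note on the current plant. They are stored (and exported)
#' as two separate columns, never concatenated. The merge is field-wise:
#' an empty argument leaves that field untouched.
#'
#' @param book a `fieldbook`.
#' @param location_info,plant_note note text; `""` keeps the stored value.
#' @param loc location index; defaults to the cursor's location.
#' @return the updated `fieldbook`.
#' @export
set_remarks <- function(book, location_info = "", plant_note = "",
                        loc = book$cursor$loc) {
  if (is.na(loc) || loc < 1L || loc > nrow(book$locations)) {
    stop_validation("no valid location to attach remarks to",
                    subclass = "pheno_cursor_at_end")
  }
  key <- as.character(loc)
  cur <- book$remarks[[key]] %||% list(location_info = "", plant_note = "")
  if (nzchar(str_trim(location_info))) cur$location_info <- str_trim(location_info)
  if (nzchar(str_trim(plant_note))) cur$plant_note <- str_trim(plant_note)
  if (nzchar(cur$location_info) || nzchar(cur$plant_note)) {
    book$remarks[[key]] <- cur
  }
  book
}

sanitize_name_part <- function(x) {
  x <- gsub("[[:space:]]+", "-", str_trim(x))
  x <- gsub('[\\\\/:*?"<>|[:cntrl:]]', "", x)
  x
}

#' Photo file name for the cursor's location
#'
#' Photos taken during scoring are named from the current location, a
#' sortable timestamp, and the variety (accession) name when one is given:
#' `<plot>-<row>-<plant>_<YYYYMMDD-HHMMSS>[_<variety>]`. Accession-keyed
#' locations use the accession name as the location part (without the
#' redundant variety suffix). All parts are sanitized to be
#' filesystem-safe: whitespace becomes `-`, reserved characters are
#' stripped.
#'
#' @param book a `fieldbook`.
#' @param timestamp `POSIXct` or `"YYYY-MM-DD HH:MM:SS"` text; defaults to
#'   the current local time.
#' @return the file name (no extension).
#' @export
photo_name <- function(book, timestamp = Sys.time()) {
  cur <- book$cursor
  if (cur$at_end) {
    stop_validation("cursor is past the end of the traversal plan",
                    subclass = "pheno_cursor_at_end")
  }
  if (!inherits(timestamp, "POSIXct")) {
    timestamp <- as.POSIXct(timestamp, tz = "")
  }
  l <- book$locations[cur$loc, ]
  stamp <- format(timestamp, "%Y%m%d-%H%M%S")
  if (identical(validate_location(l)$mode, "triple")) {
    part <- paste(sanitize_name_part(l$plot), sanitize_name_part(l$row),
                  sanitize_name_part(l$plant), sep = "-")
    variety <- sanitize_name_part(l$accession_name)
    if (nzchar(variety)) paste(part, stamp, variety, sep = "_")
    else paste(part, stamp, sep = "_")
  } else {
    paste(sanitize_name_part(l$accession_name), stamp, sep = "_")
  }
}

#' Append a dated BBCH descriptor
#'
#' The "BBCH question" workflow: when phenology is scored repeatedly over
#' the season, each scoring date gets its own type-5 descriptor column
#' `BBCH_<YYYY-MM-DD>`. Adding the same date twice is an error.
#'
#' @param book a `fieldbook`.
#' @param date the scoring date (`Date` or ISO text; default today).
#' @return the updated `fieldbook`.
#' @export
add_dated_bbch_descriptor <- function(book, date = Sys.Date()) {
  date <- quick_date(date = date)
  shortcut <- paste0("BBCH_", iso_date(date))
  if (shortcut %in% book$descriptors$shortcut) {
    stop_validation(sprintf("a BBCH descriptor for %s already exists", iso_date(date)),
                    subclass = "pheno_duplicate_shortcut")
  }
  d <- trait_descriptor(shortcut,
                        sprintf("BBCH growth stage scored on %s", iso_date(date)),
                        TRAIT_TYPES[["bbch"]])
  book$descriptors <- rbind(book$descriptors, d)
  book
}

#' Set the partial descriptor selection
#'
#' Marks exactly the given descriptors for data acquisition; all others
#' are skipped by [advance()] and [first_empty()]. If the cursor's current
#' descriptor is deselected, the cursor relocates to the next selected
#' descriptor at the same location (wrapping to the first).
#'
#' @param book a `fieldbook`.
#' @param shortcuts non-empty character vector of descriptor shortcuts.
#' @return the updated `fieldbook`.
#' @export
set_selection <- function(book, shortcuts) {
  shortcuts <- str_trim(shortcuts)
  shortcuts <- shortcuts[nzchar(shortcuts)]
  if (length(shortcuts) == 0L) {
    stop_validation("selection must keep at least one descriptor",
                    subclass = "pheno_empty_selection")
  }
  unknown <- setdiff(shortcuts, book$descriptors$shortcut)
  if (length(unknown)) {
    stop_validation(sprintf("unknown descriptor shortcut(s): %s",
                            paste(unknown, collapse = ", ")),
                    subclass = "pheno_unknown_descriptor")
  }
  book$descriptors$selected <- book$descriptors$shortcut %in% shortcuts
  cur <- book$cursor
  if (!cur$at_end && !cur$trait %in% selected_shortcuts(book)) {
    sel <- selected_shortcuts(book)
    all_sc <- book$descriptors$shortcut
    after <- all_sc[seq_along(all_sc) > match(cur$trait, all_sc)]
    nxt <- c(intersect(after, sel), sel)[1]
    book$cursor <- new_cursor(cur$loc, nxt, direction = cur$direction)
  }
  book
}
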