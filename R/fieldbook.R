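# The field book: one phenotyping session.
#
# Locations are stored in canonical walking order (plot, then row, then
# plant, numeric-aware; accession-keyed records appended in input order).
# Observations live in a sparse map keyed by (location index, descriptor
# shortcut); remarks per location; the cursor addresses the cell being
# scored next.

obs_key <- function(loc, shortcut) paste0(loc, "\r", shortcut)

default_options <- function() {
  list(zigzag = FALSE, multiple_selection = FALSE, bbch_question = FALSE,
       zigzag_carry = FALSE, strict_rating = TRUE)
}

new_cursor <- function(loc = NA_integer_, trait = NA_character_,
                       direction = "forward", at_end = FALSE) {
  structure(list(loc = as.integer(loc), trait = trait,
                 direction = direction, at_end = isTRUE(at_end)),
            class = "fb_cursor")
}

#' Create a field book
#'
#' Assembles a session from validated locations and descriptors. Locations
#' are reordered into canonical walking order; the cursor starts at the
#' first location and first selected descriptor; the observation matrix is
#' empty.
#'
#' @param locations tibble with the eleven location fields
#'   (see [location_record()]); invalid rows are rejected.
#' @param descriptors tibble of descriptors as built by [trait_descriptor()]
#'   (rows may be concatenated with `rbind`).
#' @param options named list overriding the session options `zigzag`,
#'   `multiple_selection`, `bbch_question`, `zigzag_carry`, `strict_rating`.
#' @param registry BBCH scale registry for type-5 validation; defaults to
#'   the bundled fixture registry ([bbch_bootstrap_registry()]).
#' @return a `fieldbook`.
#' @export
fieldbook <- function(locations, descriptors, options = list(),
                      registry = bbch_bootstrap_registry()) {
  stopifnot(is.data.frame(locations), is.data.frame(descriptors))
  missing_cols <- setdiff(LOCATION_FIELDS, names(locations))
  if (length(missing_cols)) {
    stop_validation(sprintf("locations lack column(s): %s",
                            paste(missing_cols, collapse = ", ")),
                    subclass = "pheno_bad_schema")
  }
  locations <- tibble::as_tibble(locations)[, LOCATION_FIELDS]
  for (f in LOCATION_FIELDS) locations[[f]] <- str_trim(locations[[f]])

  modes <- location_modes(locations)
  if (anyNA(modes)) {
    bad <- which(is.na(modes))
    stop_validation(sprintf("invalid location record(s) at position(s) %s",
                            paste(bad, collapse = ", ")),
                    subclass = "pheno_invalid_location")
  }
  triple <- modes == "triple"
  keys <- paste(locations$plot, locations$row, locations$plant, sep = "\r")
  if (anyDuplicated(keys[triple])) {
    dup <- unique(keys[triple][duplicated(keys[triple])])
    stop_validation(sprintf("duplicate plot/row/plant key(s): %s",
                            paste(gsub("\r", "/", dup), collapse = "; ")),
                    subclass = "pheno_duplicate_location")
  }
  if (anyDuplicated(descriptors$shortcut)) {
    dup <- unique(descriptors$shortcut[duplicated(descriptors$shortcut)])
    stop_validation(sprintf("duplicate descriptor shortcut(s): %s",
                            paste(dup, collapse = ", ")),
                    subclass = "pheno_duplicate_shortcut")
  }
  if (nrow(locations) == 0L) {
    stop_validation("no valid locations", subclass = "pheno_no_locations")
  }
  if (nrow(descriptors) == 0L) {
    stop_validation("no descriptors", subclass = "pheno_no_descriptors")
  }

  ord <- canonical_order(locations)
  locations <- locations[ord, ]

  book <- structure(list(
    locations = locations,
    descriptors = tibble::as_tibble(descriptors),
    observations = list(),
    remarks = list(),
    cursor = NULL,
    options = utils::modifyList(default_options(), options),
    registry = registry,
    context = bbch_sticky_context(),
    log = character(0)
  ), class = "fieldbook")
  book$cursor <- new_cursor(1L, selected_shortcuts(book)[1],
                            direction = "forward")
  book
}

selected_shortcuts <- function(book) {
  book$descriptors$shortcut[book$descriptors$selected]
}

get_descriptor <- function(book, shortcut) {
  i <- match(shortcut, book$descriptors$shortcut)
  if (is.na(i)) {
    stop_validation(sprintf("unknown descriptor '%s'", shortcut),
                    subclass = "pheno_unknown_descriptor")
  }
  book$descriptors[i, ]
}

#' Look up an observation
#'
#' @param book a `fieldbook`.
#' @param loc location index (in field-book order).
#' @param shortcut descriptor shortcut.
#' @return the stored `observation`, or `NULL`.
#' @export
get_observation <- function(book, loc, shortcut) {
  book$observations[[obs_key(loc, shortcut)]]
}

n_cells <- function(book) nrow(book$locations) * length(selected_shortcuts(book))

#' @export
print.fieldbook <- function(x, ...) {
  sel <- sum(x$descriptors$selected)
  cat(sprintf("<fieldbook: %d locations x %d descriptors (%d selected)>\n",
              nrow(x$locations), nrow(x$descriptors), sel))
  cat(sprintf("  observations: %d / %d cells; zigzag %s, multiple selection %s\n",
              length(x$observations), n_cells(x),
              if (x$options$zigzag) "on" else "off",
              if (x$options$multiple_selection) "on" else "off"))
  cat("  cursor:", format(x$cursor, book = x), "\n")
  invisible(x)
}

#' @export
format.fb_cursor <- function(x, book = NULL, ...) {
  if (x$at_end) return("<end of plan>")
  if (is.null(book)) {
    return(sprintf("location %d | %s", x$loc, x$trait))
  }
  l <- book$locations[x$loc, ]
  place <- if (nzchar(l$plot) && nzchar(l$row) && nzchar(l$plant)) {
    paste(l$plot, l$row, l$plant)
  } else {
    l$accession_name
  }
  sprintf("%s | %s", place, x$trait)
}

#' @export
print.fb_cursor <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}
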