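# Plant locations and passport data.
#
# The "Locations" sheet carries eleven fixed columns. Only plot/row/plant
# (the grid key) or, alternatively, the accession name are obligatory; the
# remaining passport columns exist for orientation and database
# synchronization. The database-key column is never shown in listings but
# is copied verbatim to every output row.

LOCATION_FIELDS <- c("plot", "row", "plant", "accession_name",
                     "accession_number", "variety_number", "genotype",
                     "mother", "father", "information", "database_key")

LOCATION_HEADERS <- c("plot", "row", "plant", "accession name",
                      "accession number", "variety number", "genotype",
                      "mother", "father", "information", "database-key")

#' Construct a location record
#'
#' @param plot,row,plant grid key labels (text; usually numbers).
#' @param accession_name accession name; the alternative key when the grid
#'   triple is absent.
#' @param accession_number,variety_number,genotype,mother,father,information
#'   optional passport fields.
#' @param database_key opaque pass-through key for database synchronization.
#' @return one-row tibble with the eleven location fields, trimmed.
#' @export
location_record <- function(plot = "", row = "", plant = "",
                            accession_name = "", accession_number = "",
                            variety_number = "", genotype = "", mother = "",
                            father = "", information = "", database_key = "") {
  vals <- lapply(list(plot, row, plant, accession_name, accession_number,
                      variety_number, genotype, mother, father, information,
                      database_key), function(x) str_trim(as.character(x)))
  names(vals) <- LOCATION_FIELDS
  tibble::as_tibble(vals)
}

#' Validate a location record
#'
#' A record is valid if either all three grid-key labels (plot, row, plant)
#' are non-empty, or -- the alternative-key mode -- the accession name is
#' non-empty. Everything else is optional.
#'
#' @param record one-row location tibble (see [location_record()]).
#' @return list with `valid` (logical), `mode` (`"triple"`, `"accession"` or
#'   `NA`), and `reason` (text, empty when valid).
#' @export
#' @examples
#' validate_location(location_record(plot = "1", row = "2", plant = "3"))$valid
#' validate_location(location_record(accession_name = "Riesling"))$mode
validate_location <- function(record) {
  triple <- c(record$plot[[1]], record$row[[1]], record$plant[[1]])
  if (all(nzchar(triple))) {
    list(valid = TRUE, mode = "triple", reason = "")
  } else if (nzchar(record$accession_name[[1]])) {
    list(valid = TRUE, mode = "accession", reason = "")
  } else {
    missing <- LOCATION_FIELDS[1:3][!nzchar(triple)]
    list(valid = FALSE, mode = NA_character_,
         reason = sprintf(
           "missing %s and no accession name for the alternative key",
           paste(missing, collapse = "/")))
  }
}

# vectorized key mode over a locations tibble
location_modes <- function(locations) {
  vapply(seq_len(nrow(locations)), function(i) {
    validate_location(locations[i, ])$mode
  }, character(1))
}
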