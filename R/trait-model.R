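# The five-type trait system.
#
# Trait descriptors come from the "Traits" sheet of the input workbook with
# columns shortcut / description / type / values / remark. The type column
# is an integer 1-5:
#   1 rating          categorical, scale defined in the values column
#   2 measured_value  decimal number, unit (if any) in the remark column
#   3 date            calendar date
#   4 text            free text
#   5 bbch            BBCH phenology code, validated against a scale registry

TRAIT_TYPES <- c(rating = 1L, measured_value = 2L, date = 3L, text = 4L, bbch = 5L)

#' Trait type codes
#'
#' Map a numeric trait-type code (1-5) to its meaning, rejecting anything
#' outside the defined range.
#'
#' @param code integer or digit string.
#' @return integer code with name equal to the meaning, one of
#'   `rating`, `measured_value`, `date`, `text`, `bbch`.
#' @export
#' @examples
#' trait_type(1)          # rating
#' names(trait_type("5")) # "bbch"
trait_type <- function(code) {
  raw <- str_trim(as.character(code))
  if (!grepl("^[0-9]+$", raw) || !(as.integer(raw) %in% TRAIT_TYPES)) {
    stop_validation(
      sprintf("unknown trait type code '%s' (must be 1-5)", raw),
      subclass = "pheno_unknown_trait_type")
  }
  i <- as.integer(raw)
  stats::setNames(i, names(TRAIT_TYPES)[match(i, TRAIT_TYPES)])
}

#' Parse a rating scale definition
#'
#' A type-1 (rating) descriptor defines its categorical scale in the values
#' column as semicolon-separated `code: label` entries, e.g.
#' `"1: none; 3: little; 5: medium; 7: strong; 9: very strong"`.
#' Entries are split on `";"`, each entry on its first `":"`; tokens are
#' trimmed and order is preserved. Codes are arbitrary text tokens (UPOV
#' scales may use letters), but may not contain `","`, which is reserved as
#' the multi-value separator in output files.
#'
#' @param values_raw scale definition text.
#' @return a `rating_scale`: list with character vectors `code` and `label`.
#' @export
#' @examples
#' sc <- parse_rating_scale("1: none; 3: little; 5: medium; 7: strong; 9: very strong")
#' sc$code   # "1" "3" "5" "7" "9"
parse_rating_scale <- function(values_raw) {
  if (length(values_raw) != 1L || is_blank(values_raw)) {
    stop_validation("rating descriptor has no scale definition in its values column",
                    subclass = "pheno_missing_scale")
  }
  entries <- strsplit(values_raw, ";", fixed = TRUE)[[1]]
  entries <- entries[!is_blank(entries)]
  if (length(entries) == 0L) {
    stop_validation("rating scale definition contains no entries",
                    subclass = "pheno_missing_scale")
  }
  codes <- character(length(entries))
  labels <- character(length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    pos <- regexpr(":", e, fixed = TRUE)
    if (pos < 0) {
      stop_validation(
        sprintf("malformed scale entry '%s': expected 'code: label'", str_trim(e)),
        subclass = "pheno_malformed_scale_entry")
    }
    codes[i] <- str_trim(substr(e, 1L, pos - 1L))
    labels[i] <- str_trim(substr(e, pos + 1L, nchar(e)))
    if (!nzchar(codes[i])) {
      stop_validation(sprintf("scale entry '%s' has an empty code", str_trim(e)),
                      subclass = "pheno_malformed_scale_entry")
    }
    if (grepl(",", codes[i], fixed = TRUE)) {
      stop_validation(
        sprintf("scale code '%s' contains ',', the reserved list separator", codes[i]),
        subclass = "pheno_malformed_scale_entry")
    }
  }
  if (anyDuplicated(codes)) {
    dup <- unique(codes[duplicated(codes)])
    stop_validation(sprintf("duplicate scale code(s): %s", paste(dup, collapse = ", ")),
                    subclass = "pheno_duplicate_scale_code")
  }
  structure(list(code = codes, label = labels), class = "rating_scale")
}

#' Serialize a rating scale back to its definition string
#'
#' Inverse of [parse_rating_scale()]: `parse_rating_scale(format_rating_scale(s))`
#' is identical to `s`.
#'
#' @param scale a `rating_scale`.
#' @return single string `"code: label; code: label; ..."`.
#' @export
format_rating_scale <- function(scale) {
  stopifnot(inherits(scale, "rating_scale"))
  paste(paste0(scale$code, ": ", scale$label), collapse = "; ")
}

#' @export
print.rating_scale <- function(x, ...) {
  cat(sprintf("<rating scale: %d categories>\n", length(x$code)))
  cat(" ", format_rating_scale(x), "\n")
  invisible(x)
}

#' Construct a trait descriptor
#'
#' @param shortcut trait abbreviation, unique within a field book.
#' @param description human-readable trait description.
#' @param type trait type code 1-5 (see [trait_type()]).
#' @param values raw content of the values column; for type 1 this must be a
#'   parseable rating-scale definition, for other types it is ignored.
#' @param remark free-text remark; by convention the measurement unit for
#'   type-2 descriptors.
#' @param selected logical partial-selection flag (default `TRUE`).
#' @return one-row tibble with a `scale` list-column (non-`NULL` iff type 1).
#' @export
trait_descriptor <- function(shortcut, description = "", type, values = "",
                             remark = "", selected = TRUE) {
  shortcut <- str_trim(shortcut)
  if (!nzchar(shortcut)) {
    stop_validation("descriptor shortcut must be non-empty",
                    subclass = "pheno_bad_descriptor")
  }
  tt <- trait_type(type)
  scale <- if (tt == TRAIT_TYPES[["rating"]]) parse_rating_scale(values) else NULL
  tibble::tibble(
    shortcut = shortcut,
    description = str_trim(description),
    type = as.integer(tt),
    values_raw = str_trim(values),
    remark = str_trim(remark),
    selected = isTRUE(selected),
    scale = list(scale)
  )
}

# ---- observations -----------------------------------------------------------

new_observation <- function(type, value) {
  structure(list(type = as.integer(type), value = value), class = "observation")
}

#' Validate a raw value against a descriptor
#'
#' Turns the text a scorer enters into a typed observation, or fails with a
#' classed validation error. The accepted language per type:
#' * type 1 (rating): a scale code, or several codes joined with `","` when
#'   `multiple = TRUE` (multiple-selection mode). Codes outside the
#'   descriptor's scale are rejected unless `strict = FALSE`.
#' * type 2 (measured value): a decimal number with `"."` as decimal
#'   separator (`","` is reserved for rating lists).
#' * type 3 (date): an ISO-8601 date `YYYY-MM-DD`, or a `Date`.
#' * type 4 (text): any text.
#' * type 5 (BBCH): `"species:code"`, or a bare two-digit code when
#'   `context` supplies the species; validated against `registry`.
#'
#' @param descriptor one-row descriptor tibble (see [trait_descriptor()]).
#' @param raw value as entered (text, or a `Date` for type 3).
#' @param multiple is multiple-selection mode active?
#' @param registry a [bbch_registry()] (required for type-5 descriptors).
#' @param context sticky BBCH entry context from [bbch_sticky_context()],
#'   supplying the species for bare codes.
#' @param strict reject rating codes not on the descriptor's scale
#'   (default `TRUE`); with `FALSE` unknown codes are stored as-is.
#' @return an `observation` (tagged payload), or a classed error.
#' @export
#' @examples
#' d <- trait_descriptor("RUST", "leaf rust", 1,
#'                       "1: none; 3: little; 5: medium; 7: strong; 9: very strong")
#' validate_value(d, "3")$value                    # "3"
#' validate_value(d, "3,5", multiple = TRUE)$value # "3" "5"
validate_value <- function(descriptor, raw, multiple = FALSE, registry = NULL,
                           context = NULL, strict = TRUE) {
  type <- descriptor$type[[1]]
  if (type == TRAIT_TYPES[["date"]] && inherits(raw, "Date")) {
    return(new_observation(type, raw))
  }
  raw <- str_trim(as.character(raw))
  if (length(raw) != 1L || !nzchar(raw)) {
    stop_validation("empty value", subclass = "pheno_empty_value")
  }
  if (type == TRAIT_TYPES[["rating"]]) {
    tokens <- str_trim(strsplit(raw, ",", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0L) {
      stop_validation("empty rating value", subclass = "pheno_empty_value")
    }
    if (length(tokens) > 1L && !isTRUE(multiple)) {
      stop_validation(
        sprintf("'%s' holds %d values but multiple selection is not active",
                raw, length(tokens)),
        subclass = "pheno_multiple_not_allowed")
    }
    scale <- descriptor$scale[[1]]
    if (isTRUE(strict)) {
      bad <- setdiff(tokens, scale$code)
      if (length(bad)) {
        stop_validation(
          sprintf("rating code(s) %s not on the scale of '%s' (%s)",
                  paste(sprintf("'%s'", bad), collapse = ", "),
                  descriptor$shortcut[[1]], paste(scale$code, collapse = ", ")),
          subclass = "pheno_out_of_scale")
      }
    }
    new_observation(type, tokens)
  } else if (type == TRAIT_TYPES[["measured_value"]]) {
    if (!grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$", raw)) {
      stop_validation(sprintf("'%s' is not a decimal number", raw),
                      subclass = "pheno_bad_number")
    }
    new_observation(type, as.numeric(raw))
  } else if (type == TRAIT_TYPES[["date"]]) {
    d <- parse_iso_date(raw)
    if (is.null(d)) {
      stop_validation(sprintf("'%s' is not a valid date (expected YYYY-MM-DD)", raw),
                      subclass = "pheno_bad_date")
    }
    new_observation(type, d)
  } else if (type == TRAIT_TYPES[["text"]]) {
    new_observation(type, raw)
  } else {
    # BBCH: fully qualified "species:code" or bare code + sticky context
    if (grepl(":", raw, fixed = TRUE)) {
      pos <- regexpr(":", raw, fixed = TRUE)
      species <- str_trim(substr(raw, 1L, pos - 1L))
      code <- str_trim(substr(raw, pos + 1L, nchar(raw)))
    } else {
      species <- context$species %||% ""
      code <- raw
    }
    if (!nzchar(species)) {
      stop_validation(
        sprintf("BBCH value '%s' names no species and no entry context is active", raw),
        subclass = "pheno_unknown_species")
    }
    if (is.null(registry)) {
      stop_validation("BBCH validation requires a scale registry",
                      subclass = "pheno_unknown_species")
    }
    bc <- validate_bbch_code(registry, species, code)
    new_observation(type, list(species = bc$species, code = bc$code))
  }
}

#' Serialize an observation to its output-file cell text
#'
#' Rating lists are joined with `","`, dates rendered ISO-8601, BBCH codes
#' written fully qualified as `species:code` so that a session can be
#' rebuilt losslessly from its export.
#'
#' @param obs an `observation`.
#' @return single string (empty for `NULL`).
#' @export
serialize_observation <- function(obs) {
  if (is.null(obs)) return("")
  stopifnot(inherits(obs, "observation"))
  switch(names(TRAIT_TYPES)[obs$type],
    rating = paste(obs$value, collapse = ","),
    measured_value = num_to_str(obs$value),
    date = iso_date(obs$value),
    text = obs$value,
    bbch = paste0(obs$value$species, ":", obs$value$code)
  )
}

#' @export
print.observation <- function(x, ...) {
  cat(sprintf("<observation type %d (%s)> %s\n", x$type,
              names(TRAIT_TYPES)[x$type], serialize_observation(x)))
  invisible(x)
}
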