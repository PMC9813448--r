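# BBCH growth-stage scales.
#
# A BBCH scale is a three-level hierarchy: species -> principal growth
# stage (one digit, 0-9) -> specific growth stage (two digits whose first
# digit is the parent principal stage). Scales are held in a registry and
# can be added from an Excel template workbook whose first sheet names the
# species and lists the principal stages, with one further sheet of
# specific stages per principal stage. Each principal stage may carry the
# name of a sample image (sibling file with the same stem as the stage
# title).

#' Construct a BBCH scale
#'
#' @param species species name (free text; `":"` and `","` are reserved).
#' @param principal tibble/data.frame with columns `code` (single digit
#'   0-9, unique), `title`, and optionally `image_name`.
#' @param specifics tibble/data.frame with columns `code` (two-digit text)
#'   and `description`; each code's first digit must name an existing
#'   principal stage.
#' @return a `bbch_scale`.
#' @export
bbch_scale <- function(species, principal, specifics) {
  species <- str_trim(species)
  if (!nzchar(species)) {
    stop_validation("empty species name", subclass = "pheno_bbch_bad_species")
  }
  if (grepl("[:,]", species)) {
    stop_validation(sprintf("species name '%s' contains a reserved character (':' or ',')",
                            species), subclass = "pheno_bbch_bad_species")
  }
  principal <- tibble::as_tibble(principal)
  if (!"image_name" %in% names(principal)) principal$image_name <- ""
  principal <- principal[, c("code", "title", "image_name")]
  principal$code <- str_trim(as.character(principal$code))
  principal$title <- str_trim(principal$title)
  principal$image_name <- str_trim(principal$image_name)
  if (nrow(principal) == 0L || any(!grepl("^[0-9]$", principal$code))) {
    stop_validation("principal stage codes must be single digits 0-9",
                    subclass = "pheno_bbch_bad_principal")
  }
  if (anyDuplicated(principal$code)) {
    stop_validation("duplicate principal stage codes",
                    subclass = "pheno_bbch_duplicate")
  }
  specifics <- tibble::as_tibble(specifics)[, c("code", "description")]
  specifics$code <- str_trim(as.character(specifics$code))
  specifics$description <- str_trim(specifics$description)
  if (any(!grepl("^[0-9]{2}$", specifics$code))) {
    bad <- specifics$code[!grepl("^[0-9]{2}$", specifics$code)]
    stop_validation(sprintf("specific stage code(s) not two-digit: %s",
                            paste(bad, collapse = ", ")),
                    subclass = "pheno_bbch_bad_code")
  }
  orphan <- setdiff(substr(specifics$code, 1, 1), principal$code)
  if (length(orphan)) {
    stop_validation(sprintf("specific stage(s) under principal digit(s) %s, which no principal stage defines",
                            paste(orphan, collapse = ", ")),
                    subclass = "pheno_bbch_orphan_code")
  }
  if (anyDuplicated(specifics$code)) {
    dup <- unique(specifics$code[duplicated(specifics$code)])
    stop_validation(sprintf("duplicate specific stage code(s): %s",
                            paste(dup, collapse = ", ")),
                    subclass = "pheno_bbch_duplicate")
  }
  # canonical presentation: principals by digit, specifics by code
  principal <- principal[order(principal$code), ]
  specifics <- specifics[order(specifics$code), ]
  structure(list(species = species, principal = principal,
                 specifics = specifics), class = "bbch_scale")
}

#' @export
print.bbch_scale <- function(x, ...) {
  cat(sprintf("<BBCH scale '%s': %d principal / %d specific stages>\n",
              x$species, nrow(x$principal), nrow(x$specifics)))
  invisible(x)
}

# ---- registry ---------------------------------------------------------------

#' BBCH scale registry
#'
#' A registry holds the scales a session can validate type-5 observations
#' against. When `dir` is given, every template-format `.xlsx` file in it
#' is loaded on creation and [bbch_register()] persists new scales there
#' (one template file per species).
#'
#' @param dir optional persistence directory.
#' @return a `bbch_registry` (environment).
#' @export
bbch_registry <- function(dir = NULL) {
  reg <- new.env(parent = emptyenv())
  reg$scales <- list()
  reg$dir <- dir
  class(reg) <- "bbch_registry"
  if (!is.null(dir) && dir.exists(dir)) {
    for (f in sort(list.files(dir, pattern = "\\.xlsx$", full.names = TRUE))) {
      sc <- import_bbch_template(f)
      reg$scales[[sc$species]] <- sc
    }
  }
  reg
}

#' Register a scale
#'
#' Re-registering an existing species replaces its scale with a warning
#' (versioned replace).
#'
#' @param registry a [bbch_registry()].
#' @param scale a [bbch_scale()].
#' @return the registry, invisibly.
#' @export
bbch_register <- function(registry, scale) {
  stopifnot(inherits(registry, "bbch_registry"), inherits(scale, "bbch_scale"))
  if (scale$species %in% names(registry$scales)) {
    warning(sprintf("replacing existing BBCH scale for '%s'", scale$species),
            call. = FALSE)
  }
  registry$scales[[scale$species]] <- scale
  if (!is.null(registry$dir)) {
    if (!dir.exists(registry$dir)) dir.create(registry$dir, recursive = TRUE)
    export_bbch_template(scale,
                         file.path(registry$dir, paste0(scale$species, ".xlsx")))
  }
  invisible(registry)
}

#' @rdname bbch_registry
#' @param registry a `bbch_registry`.
#' @export
bbch_species <- function(registry) sort(names(registry$scales))

#' Retrieve one species' scale from a registry
#'
#' @param registry a [bbch_registry()].
#' @param species species name.
#' @return the [bbch_scale()].
#' @export
bbch_get <- function(registry, species) {
  sc <- registry$scales[[str_trim(species)]]
  if (is.null(sc)) {
    stop_validation(sprintf("no BBCH scale registered for species '%s'", species),
                    subclass = "pheno_unknown_species")
  }
  sc
}

#' @export
print.bbch_registry <- function(x, ...) {
  cat(sprintf("<BBCH registry: %d species>\n", length(x$scales)))
  for (s in bbch_species(x)) {
    cat(sprintf("  %s (%d specific stages)\n", s, nrow(x$scales[[s]]$specifics)))
  }
  invisible(x)
}

#' Validate a BBCH code against a registry
#'
#' Codes are two-digit text ("07", never 7); anything else is rejected,
#' including codes absent from the species' scale.
#'
#' @param registry a [bbch_registry()].
#' @param species species name.
#' @param code two-digit stage code.
#' @return list `(species, code)` of class `bbch_code`.
#' @export
validate_bbch_code <- function(registry, species, code) {
  sc <- bbch_get(registry, species)
  code <- str_trim(as.character(code))
  if (!grepl("^[0-9]{2}$", code)) {
    stop_validation(sprintf("BBCH code '%s' is not a two-digit code", code),
                    subclass = "pheno_bbch_bad_code")
  }
  if (!code %in% sc$specifics$code) {
    stop_validation(sprintf("BBCH code '%s' is not defined for species '%s'",
                            code, sc$species),
                    subclass = "pheno_bbch_unknown_code")
  }
  structure(list(species = sc$species, code = code), class = "bbch_code")
}

#' Sticky BBCH entry context
#'
#' During phenology scoring only the specific stage changes from plant to
#' plant, so the species and principal-stage list levels are copied forward
#' from the previous entry; explicit arguments override the carried values.
#'
#' @param previous the previous `bbch_code`, or `NULL` at the first entry.
#' @param species optional species override.
#' @param principal optional principal-stage digit override.
#' @return list `(species, principal)`; both `NULL` when no context exists.
#' @export
#' @examples
#' ctx <- bbch_sticky_context(structure(list(species = "maize", code = "31"),
#'                                      class = "bbch_code"))
#' ctx$principal  # "3"
bbch_sticky_context <- function(previous = NULL, species = NULL, principal = NULL) {
  ctx <- list(species = NULL, principal = NULL)
  if (!is.null(previous)) {
    ctx$species <- previous$species
    ctx$principal <- substr(previous$code, 1, 1)
  }
  if (!is.null(species)) ctx$species <- str_trim(species)
  if (!is.null(principal)) ctx$principal <- str_trim(as.character(principal))
  ctx
}

# ---- template workbooks -----------------------------------------------------

#' Import a BBCH template workbook
#'
#' The template layout: the first sheet is named after the species and
#' lists the principal growth stages (columns code / title / image); every
#' further sheet holds the specific growth stages (columns code /
#' description) of one principal stage, bound in sheet order -- or, when a
#' sheet is named with a single digit, to that principal stage explicitly.
#' Principal stages whose image column is empty are associated with sibling
#' image files whose stem matches the stage title (case-insensitively).
#'
#' @param path template workbook (`.xlsx` or legacy `.xls`).
#' @param registry optional registry; when given, the imported scale is
#'   registered (and persisted if the registry has a directory).
#' @param consume move the file into a `processed/` subfolder after a
#'   successful import (the import semantics of the capture app, minus the
#'   deletion).
#' @param images_dir directory scanned for stage images; defaults to the
#'   template's directory.
#' @return the imported [bbch_scale()].
#' @export
import_bbch_template <- function(path, registry = NULL, consume = FALSE,
                                 images_dir = dirname(path)) {
  if (!file.exists(path)) {
    stop_io(sprintf("template '%s' does not exist", path),
            subclass = "pheno_missing_file")
  }
  sheets <- readxl::excel_sheets(path)
  if (length(sheets) < 2L) {
    stop_validation("a BBCH template needs at least two sheets (principal + specific stages)",
                    subclass = "pheno_bbch_bad_template")
  }
  species <- str_trim(sheets[1])
  main <- read_sheet_text(path, 1L)
  if (ncol(main) < 2L) {
    stop_validation("first template sheet needs at least code and title columns",
                    subclass = "pheno_bbch_bad_template")
  }
  principal <- tibble::tibble(
    code = main[[1]],
    title = main[[2]],
    image_name = if (ncol(main) >= 3L) main[[3]] else ""
  )
  principal <- principal[!is_blank(principal$code), ]

  # bind specific-stage sheets: digit-named sheets override sheet order
  spec_sheets <- seq_along(sheets)[-1]
  bound <- character(length(spec_sheets))
  order_pool <- principal$code
  for (k in seq_along(spec_sheets)) {
    nm <- str_trim(sheets[spec_sheets[k]])
    if (grepl("^[0-9]$", nm)) {
      bound[k] <- nm
      order_pool <- setdiff(order_pool, nm)
    }
  }
  for (k in seq_along(spec_sheets)) {
    if (!nzchar(bound[k])) {
      if (length(order_pool) == 0L) {
        stop_validation(sprintf("template sheet '%s' has no principal stage left to bind to",
                                sheets[spec_sheets[k]]),
                        subclass = "pheno_bbch_bad_template")
      }
      bound[k] <- order_pool[1]
      order_pool <- order_pool[-1]
    }
  }

  spec_list <- vector("list", length(spec_sheets))
  for (k in seq_along(spec_sheets)) {
    tab <- read_sheet_text(path, spec_sheets[k])
    if (ncol(tab) < 2L) {
      stop_validation(sprintf("template sheet '%s' needs code and description columns",
                              sheets[spec_sheets[k]]),
                      subclass = "pheno_bbch_bad_template")
    }
    tab <- tibble::tibble(code = tab[[1]], description = tab[[2]])
    tab <- tab[!is_blank(tab$code), ]
    mismatched <- nzchar(tab$code) & substr(tab$code, 1, 1) != bound[k]
    if (any(mismatched)) {
      stop_validation(
        sprintf("sheet '%s' (principal stage %s) lists code(s) %s under another principal digit",
                sheets[spec_sheets[k]], bound[k],
                paste(tab$code[mismatched], collapse = ", ")),
        subclass = "pheno_bbch_orphan_code")
    }
    spec_list[[k]] <- tab
  }
  specifics <- do.call(rbind, spec_list)
  scale <- bbch_scale(species, principal, specifics)
  scale <- bbch_find_images(scale, images_dir)

  if (!is.null(registry)) bbch_register(registry, scale)
  if (isTRUE(consume)) {
    dest_dir <- file.path(dirname(path), "processed")
    if (!dir.exists(dest_dir)) dir.create(dest_dir, recursive = TRUE)
    file.rename(path, file.path(dest_dir, basename(path)))
  }
  scale
}

# fill empty image_name slots from sibling files whose stem matches the
# stage title, case-insensitively
bbch_find_images <- function(scale, dir) {
  if (is.null(dir) || !dir.exists(dir)) return(scale)
  files <- list.files(dir)
  stems <- tolower(tools::file_path_sans_ext(files))
  for (i in seq_len(nrow(scale$principal))) {
    if (!nzchar(scale$principal$image_name[i])) {
      hit <- which(stems == tolower(scale$principal$title[i]))
      if (length(hit)) scale$principal$image_name[i] <- files[hit[1]]
    }
  }
  scale
}

#' Export a scale as a template workbook
#'
#' Inverse of [import_bbch_template()]: writes the species/principal sheet
#' followed by one digit-named sheet of specific stages per principal
#' stage. `import_bbch_template(export_bbch_template(s, f))` reproduces `s`.
#'
#' @param scale a [bbch_scale()].
#' @param path output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
export_bbch_template <- function(scale, path) {
  stopifnot(inherits(scale, "bbch_scale"))
  if (grepl("[][*?/\\:]", scale$species) || nchar(scale$species) > 31) {
    stop_validation(sprintf("species '%s' cannot be used as a sheet name", scale$species),
                    subclass = "pheno_bbch_bad_species")
  }
  sheets <- list()
  main <- data.frame(code = scale$principal$code, title = scale$principal$title,
                     image = scale$principal$image_name, stringsAsFactors = FALSE)
  sheets[[scale$species]] <- main
  for (d in scale$principal$code) {
    sub <- scale$specifics[substr(scale$specifics$code, 1, 1) == d, ]
    sheets[[d]] <- data.frame(code = sub$code, description = sub$description,
                              stringsAsFactors = FALSE)
  }
  write_xlsx_minimal(sheets, path)
  invisible(path)
}

# ---- bundled fixture scales -------------------------------------------------

BBCH_FIXTURE_CROPS <- c("apple", "cereals", "grapevine", "maize", "potato",
                        "rapeseed", "rice")

#' Bundled fixture registry
#'
#' A registry pre-populated with *synthetic* structurally valid scales for
#' the seven crops the capture app ships phenology scales for (apple,
#' cereals, grapevine, maize, potato, rapeseed, rice). Each fixture scale
#' has the ten principal stages 0-9 and, under each, the nine specific
#' stages `d0`-`d8`. These are placeholders exercising the three-level
#' structure; they are **not** transcriptions of the official BBCH
#' monograph code lists.
#'
#' @param dir optional persistence directory passed to [bbch_registry()];
#'   fixture scales are added only for species not already present there.
#' @return a `bbch_registry`.
#' @export
bbch_bootstrap_registry <- function(dir = NULL) {
  reg <- bbch_registry(dir)
  for (crop in BBCH_FIXTURE_CROPS) {
    if (crop %in% names(reg$scales)) next
    principal <- tibble::tibble(
      code = as.character(0:9),
      title = paste("principal stage", 0:9),
      image_name = ""
    )
    specifics <- tibble::tibble(
      code = paste0(rep(0:9, each = 9), rep(0:8, times = 10)),
      description = paste("specific stage", paste0(rep(0:9, each = 9), rep(0:8, times = 10)))
    )
    reg$scales[[crop]] <- bbch_scale(crop, principal, specifics)
  }
  reg
}
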