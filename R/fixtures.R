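# Deterministic synthetic fixtures: field layouts, descriptor sets, BBCH
# templates, and partially filled sessions. All content is a pure function
# of the spec and its seed, so the same call always produces byte-identical
# files -- the basis for the property-based test suites.

ACCESSION_POOL <- c("Riesling", "Kerner", "Silvaner", "Regent", "Phoenix",
                    "Solaris", "Dornfelder", "Morio-Muskat", "Bacchus",
                    "Calandro", "Reberger", "Felicia")

FIXTURE_SCALE <- "1: none; 3: little; 5: medium; 7: strong; 9: very strong"

#' Fixture specification
#'
#' @param plots number of plots.
#' @param rows_per_plot rows per plot: one count, or one count per plot
#'   (ragged layouts allowed).
#' @param plants_per_row plants per row: one count, or one count per row
#'   (recycled over all rows of all plots).
#' @param descriptor_mix named counts per trait type, names among
#'   `rating`, `measured_value`, `date`, `text`, `bbch`.
#' @param fill_fraction fraction of cells pre-recorded by [make_session()].
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   fixture files.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(plots = 2L, rows_per_plot = 1L, plants_per_row = 3L,
                         descriptor_mix = c(rating = 1L, measured_value = 1L,
                                            date = 1L, text = 1L, bbch = 1L),
                         fill_fraction = 0, seed = 42L) {
  if (plots < 1L || any(rows_per_plot < 1L) || any(plants_per_row < 1L)) {
    stop_validation("fixture grid counts must be positive",
                    subclass = "pheno_bad_fixture_spec")
  }
  bad <- setdiff(names(descriptor_mix), names(TRAIT_TYPES))
  if (length(bad)) {
    stop_validation(sprintf("unknown descriptor_mix name(s): %s",
                            paste(bad, collapse = ", ")),
                    subclass = "pheno_bad_fixture_spec")
  }
  if (sum(descriptor_mix) < 1L) {
    stop_validation("descriptor_mix must request at least one descriptor",
                    subclass = "pheno_bad_fixture_spec")
  }
  if (fill_fraction < 0 || fill_fraction > 1) {
    stop_validation("fill_fraction must be in [0, 1]",
                    subclass = "pheno_bad_fixture_spec")
  }
  structure(list(plots = as.integer(plots),
                 rows_per_plot = as.integer(rows_per_plot),
                 plants_per_row = as.integer(plants_per_row),
                 descriptor_mix = descriptor_mix,
                 fill_fraction = fill_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_locations <- function(spec) {
  rows_per_plot <- rep_len(spec$rows_per_plot, spec$plots)
  out <- list()
  row_counter <- 0L
  for (p in seq_len(spec$plots)) {
    for (r in seq_len(rows_per_plot[p])) {
      row_counter <- row_counter + 1L
      nplants <- rep_len(spec$plants_per_row, row_counter)[row_counter]
      for (q in seq_len(nplants)) {
        acc <- ACCESSION_POOL[sample.int(length(ACCESSION_POOL), 1L)]
        out[[length(out) + 1L]] <- location_record(
          plot = as.character(p), row = as.character(r), plant = as.character(q),
          accession_name = acc,
          accession_number = sprintf("ACC%05d", sample.int(99999L, 1L)),
          variety_number = sprintf("V%04d", sample.int(9999L, 1L)),
          genotype = sprintf("G-%03d", sample.int(999L, 1L)),
          mother = ACCESSION_POOL[sample.int(length(ACCESSION_POOL), 1L)],
          father = ACCESSION_POOL[sample.int(length(ACCESSION_POOL), 1L)],
          information = if (runif(1) < 0.3) "border plant" else "",
          database_key = sprintf("DBK%06d", sample.int(999999L, 1L)))
      }
    }
  }
  do.call(rbind, out)
}

fixture_descriptors <- function(spec) {
  mix <- spec$descriptor_mix
  out <- list()
  for (tname in names(TRAIT_TYPES)) {
    k <- if (tname %in% names(mix)) mix[[tname]] else 0L
    if (is.na(k) || k < 1L) next
    for (i in seq_len(k)) {
      out[[length(out) + 1L]] <- switch(tname,
        rating = trait_descriptor(sprintf("RAT%d", i),
                                  sprintf("severity rating %d", i), 1L,
                                  FIXTURE_SCALE),
        measured_value = trait_descriptor(sprintf("MV%d", i),
                                          sprintf("measured value %d", i), 2L,
                                          remark = "cm"),
        date = trait_descriptor(sprintf("DT%d", i),
                                sprintf("event date %d", i), 3L),
        text = trait_descriptor(sprintf("TXT%d", i),
                                sprintf("free-text note %d", i), 4L),
        bbch = trait_descriptor(sprintf("BBCH%d", i),
                                sprintf("growth stage %d", i), 5L))
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic input workbook
#'
#' Builds a plot/row/plant grid with plausible passport fields and a
#' Traits sheet covering the requested trait types (rating descriptors
#' carry the standard 1/3/5/7/9 severity scale). The file parses through
#' [read_input()] with zero errors.
#'
#' @param spec a [fixture_spec()].
#' @param path output path: `.xlsx` for a workbook, `.csv` for the
#'   `<stem>_locations.csv` / `<stem>_traits.csv` pair.
#' @return `path`, invisibly.
#' @export
make_input_workbook <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    loc <- fixture_locations(spec)
    desc <- fixture_descriptors(spec)
    loc_df <- as.data.frame(loc, stringsAsFactors = FALSE)
    names(loc_df) <- LOCATION_HEADERS
    trait_df <- data.frame(shortcut = desc$shortcut, description = desc$description,
                           type = desc$type, values = desc$values_raw,
                           remark = desc$remark, stringsAsFactors = FALSE)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      pair <- csv_pair(path)
      readr::write_csv(loc_df, pair$locations, na = "")
      readr::write_csv(trait_df, pair$traits, na = "")
    } else {
      trait_df$type <- as.character(trait_df$type)
      write_xlsx_minimal(list(Locations = loc_df, Traits = trait_df), path)
    }
  })
  invisible(path)
}

#' Generate a synthetic BBCH template workbook
#'
#' Structurally valid template: first sheet named after the species with
#' principal stages `0 .. n_principal-1`, then one digit-named sheet per
#' principal stage with `specifics_per_principal` specific codes derived
#' from the parent digit.
#'
#' @param species species name (also the first sheet's name).
#' @param n_principal number of principal stages (at most 10).
#' @param specifics_per_principal specific stages per principal (at most 10).
#' @param seed integer seed (stage wording only).
#' @param path output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
make_bbch_template <- function(species, n_principal, specifics_per_principal,
                               seed, path) {
  if (n_principal > 10L || n_principal < 1L) {
    stop_validation("n_principal must be between 1 and 10 (principal stages are single digits)",
                    subclass = "pheno_bad_fixture_spec")
  }
  if (specifics_per_principal > 10L || specifics_per_principal < 1L) {
    stop_validation("specifics_per_principal must be between 1 and 10",
                    subclass = "pheno_bad_fixture_spec")
  }
  words <- c("dormancy", "emergence", "leafing", "tillering", "elongation",
             "booting", "heading", "flowering", "ripening", "senescence")
  with_seed(seed, {
    digits <- sort(sample(0:9, n_principal))
    principal <- tibble::tibble(
      code = as.character(digits),
      title = paste("stage", digits, sample(words, n_principal, replace = TRUE)),
      image_name = "")
    spec_codes <- unlist(lapply(digits, function(d) {
      paste0(d, sort(sample(0:9, specifics_per_principal)))
    }))
    specifics <- tibble::tibble(code = spec_codes,
                                description = paste("specific stage", spec_codes))
    export_bbch_template(bbch_scale(species, principal, specifics), path)
  })
  invisible(path)
}

#' Generate a partially filled session
#'
#' Writes the spec's input workbook to a temporary file, reads it back
#' into a field book, and records exactly
#' `round(fill_fraction * cells)` observations in seeded cells with
#' values drawn validly for each descriptor type (rating codes from the
#' scale, dates within one season, BBCH codes from the registry).
#'
#' @param spec a [fixture_spec()].
#' @param options,registry passed to [read_input()].
#' @return a `fieldbook`.
#' @export
make_session <- function(spec, options = list(),
                         registry = bbch_bootstrap_registry()) {
  stopifnot(inherits(spec, "fixture_spec"))
  wb <- tempfile(fileext = ".xlsx")
  on.exit(unlink(wb))
  make_input_workbook(spec, wb)
  book <- read_input(wb, options = options, registry = registry)
  with_seed(spec$seed + 1L, {
    shortcuts <- selected_shortcuts(book)
    nloc <- nrow(book$locations)
    cells <- expand.grid(loc = seq_len(nloc), trait = shortcuts,
                         stringsAsFactors = FALSE)
    k <- round(spec$fill_fraction * nrow(cells))
    if (k > 0L) {
      picked <- cells[sort(sample.int(nrow(cells), k)), ]
      species_pool <- bbch_species(book$registry)
      for (j in seq_len(nrow(picked))) {
        d <- get_descriptor(book, picked$trait[j])
        raw <- switch(names(TRAIT_TYPES)[d$type],
          rating = sample(d$scale[[1]]$code, 1L),
          measured_value = num_to_str(round(runif(1, 0, 100), 2)),
          date = iso_date(as.Date("2022-04-01") + sample.int(180L, 1L)),
          text = paste("note", sample.int(9999L, 1L)),
          bbch = {
            sp <- sample(species_pool, 1L)
            paste0(sp, ":", sample(bbch_get(book$registry, sp)$specifics$code, 1L))
          })
        obs <- validate_value(d, raw, multiple = FALSE,
                              registry = book$registry)
        book$observations[[obs_key(picked$loc[j], picked$trait[j])]] <- obs
      }
    }
  })
  book
}
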