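# Session persistence: an explicit, versioned JSON file holding the full
# state of a field-book session (locations, descriptors, selection,
# observations, remarks, cursor, options, BBCH registry, audit log).
# Saving then loading reproduces an identical field book; a schema-version
# mismatch refuses to load.

SESSION_SCHEMA_VERSION <- 1L

#' Save a session
#'
#' @param book a `fieldbook`.
#' @param path session file path (JSON).
#' @param input_path the input workbook the session came from (recorded
#'   for provenance).
#' @return `path`, invisibly.
#' @export
session_save <- function(book, path, input_path = attr(book, "input_path") %||% "") {
  obs <- book$observations
  obs_records <- lapply(names(obs), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    list(loc = as.integer(parts[1]), trait = parts[2],
         value = serialize_observation(obs[[k]]))
  })
  rem_records <- lapply(names(book$remarks), function(k) {
    list(loc = as.integer(k),
         location_info = book$remarks[[k]]$location_info,
         plant_note = book$remarks[[k]]$plant_note)
  })
  reg_records <- lapply(bbch_species(book$registry), function(sp) {
    sc <- book$registry$scales[[sp]]
    list(species = sp,
         principal = as.list(sc$principal),
         specifics = as.list(sc$specifics))
  })
  state <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    input = input_path,
    options = book$options,
    locations = as.list(book$locations),
    descriptors = list(shortcut = book$descriptors$shortcut,
                       description = book$descriptors$description,
                       type = book$descriptors$type,
                       values_raw = book$descriptors$values_raw,
                       remark = book$descriptors$remark,
                       selected = book$descriptors$selected),
    observations = obs_records,
    remarks = rem_records,
    cursor = list(loc = book$cursor$loc, trait = book$cursor$trait,
                  direction = book$cursor$direction, at_end = book$cursor$at_end),
    context = list(species = book$context$species %||% "",
                   principal = book$context$principal %||% ""),
    registry = reg_records,
    log = book$log
  )
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a session
#'
#' @param path session file written by [session_save()].
#' @return the reconstructed `fieldbook`, with the originating input path
#'   in the `input_path` attribute.
#' @export
session_load <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("session file '%s' does not exist", path),
            subclass = "pheno_missing_file")
  }
  state <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- state$schema_version %||% -1L
  if (!identical(as.integer(ver), SESSION_SCHEMA_VERSION)) {
    stop_validation(
      sprintf("session schema version %s is not supported (this build reads version %d)",
              ver, SESSION_SCHEMA_VERSION),
      subclass = "pheno_schema_version")
  }
  chr <- function(x) vapply(x, function(v) as.character(v %||% ""), character(1))
  locations <- tibble::as_tibble(lapply(state$locations, chr))
  dsc <- state$descriptors
  desc_rows <- lapply(seq_along(dsc$shortcut), function(i) {
    trait_descriptor(dsc$shortcut[[i]], dsc$description[[i]] %||% "",
                     dsc$type[[i]], dsc$values_raw[[i]] %||% "",
                     dsc$remark[[i]] %||% "",
                     selected = isTRUE(dsc$selected[[i]]))
  })
  descriptors <- do.call(rbind, desc_rows)

  registry <- bbch_registry()
  for (r in state$registry) {
    registry$scales[[r$species]] <- bbch_scale(
      r$species,
      tibble::tibble(code = chr(r$principal$code), title = chr(r$principal$title),
                     image_name = chr(r$principal$image_name)),
      tibble::tibble(code = chr(r$specifics$code),
                     description = chr(r$specifics$description)))
  }

  opts <- lapply(state$options, isTRUE)
  book <- fieldbook(locations, descriptors, options = opts, registry = registry)

  for (o in state$observations) {
    d <- get_descriptor(book, o$trait)
    book$observations[[obs_key(o$loc, o$trait)]] <-
      validate_value(d, o$value, multiple = TRUE, registry = registry,
                     strict = book$options$strict_rating)
  }
  for (r in state$remarks) {
    book$remarks[[as.character(r$loc)]] <-
      list(location_info = as.character(r$location_info %||% ""),
           plant_note = as.character(r$plant_note %||% ""))
  }
  cur <- state$cursor
  book$cursor <- if (isTRUE(cur$at_end)) new_cursor(at_end = TRUE) else
    new_cursor(as.integer(cur$loc), cur$trait, cur$direction %||% "forward")
  if (nzchar(state$context$species %||% "")) {
    book$context <- bbch_sticky_context(species = state$context$species,
                                        principal = state$context$principal)
  }
  book$log <- vapply(state$log, as.character, character(1), USE.NAMES = FALSE)
  attr(book, "input_path") <- state$input %||% ""
  book
}
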