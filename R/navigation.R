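# Traversal: the order a scorer walks the field.
#
# Canonical order is plot, then row, then plant (numeric-aware label
# comparison). Zigzag (serpentine) mode keeps row order but alternates the
# walking direction of consecutive rows within a plot, so after finishing a
# row the scorer enters the next row from the near end and counts backwards.
# Accession-keyed records (no grid position) form one pseudo-row appended
# after all grid records and are always walked forward.

#' Canonical location order
#'
#' @param locations locations tibble (see [location_record()]).
#' @return integer permutation: row indices of `locations` sorted by plot,
#'   then row, then plant with numeric-aware comparison; accession-only
#'   records appended in input order.
#' @export
#' @examples
#' loc <- rbind(location_record("1", "1", "10"), location_record("1", "1", "2"))
#' canonical_order(loc)  # 2 1 -- plant "2" walks before plant "10"
canonical_order <- function(locations) {
  modes <- location_modes(locations)
  triple <- which(modes == "triple")
  alt <- which(modes != "triple")
  ordt <- triple[nat_order(locations$plot[triple], locations$row[triple],
                           locations$plant[triple])]
  c(ordt, alt)
}

# rows of a book's (already canonical) locations, grouped by (plot, row):
# list of integer vectors, each in plant order; accession-only records
# form one trailing pseudo-row
row_groups <- function(locations) {
  modes <- location_modes(locations)
  triple <- which(modes == "triple")
  alt <- which(modes != "triple")
  groups <- list()
  if (length(triple)) {
    key <- paste(locations$plot[triple], locations$row[triple], sep = "\r")
    groups <- unname(split(triple, factor(key, levels = unique(key))))
  }
  if (length(alt)) groups <- c(groups, list(alt))
  groups
}

# plot label per row group ("" for the accession pseudo-row)
row_group_plots <- function(locations, groups) {
  vapply(groups, function(g) {
    m <- validate_location(locations[g[1], ])$mode
    if (identical(m, "triple")) locations$plot[[g[1]]] else ""
  }, character(1))
}

#' Traversal plan
#'
#' The ordered sequence of location indices a session walks: canonical
#' order, or serpentine order when `mode = "zigzag"`. The result is always
#' a permutation of all location indices and carries a `direction`
#' attribute giving the row walking direction at each step.
#'
#' @param book a `fieldbook`.
#' @param mode `"standard"` or `"zigzag"`; default follows the book's
#'   `zigzag` option.
#' @param carry under zigzag, carry the alternation across plot boundaries
#'   instead of resetting to forward at each plot's first row; default
#'   follows the book's `zigzag_carry` option.
#' @return integer vector of location indices with attributes `mode` and
#'   `direction` (`"forward"`/`"backward"` per step).
#' @export
traversal_plan <- function(book,
                           mode = if (book$options$zigzag) "zigzag" else "standard",
                           carry = book$options$zigzag_carry) {
  mode <- match.arg(mode, c("standard", "zigzag"))
  n <- nrow(book$locations)
  if (mode == "standard") {
    plan <- seq_len(n)
    attr(plan, "direction") <- rep("forward", n)
    attr(plan, "mode") <- "standard"
    return(plan)
  }
  groups <- row_groups(book$locations)
  plots <- row_group_plots(book$locations, groups)
  plan <- integer(0)
  dirs <- character(0)
  backward <- FALSE
  prev_plot <- NULL
  for (k in seq_along(groups)) {
    if (!isTRUE(carry) && (is.null(prev_plot) || !identical(plots[[k]], prev_plot))) {
      backward <- FALSE  # each plot starts on a forward row
    }
    g <- groups[[k]]
    if (backward) g <- rev(g)
    plan <- c(plan, g)
    dirs <- c(dirs, rep(if (backward) "backward" else "forward", length(g)))
    backward <- !backward
    prev_plot <- plots[[k]]
  }
  attr(plan, "direction") <- dirs
  attr(plan, "mode") <- "zigzag"
  plan
}

#' Zigzag (serpentine) order
#'
#' Convenience wrapper returning the serpentine traversal of a locations
#' table: within each plot, rows in canonical order with plant order
#' alternating forward/backward, starting forward on each plot's first row.
#'
#' @param locations locations tibble; rows may be in any order.
#' @param carry carry alternation across plot boundaries (default `FALSE`).
#' @return integer permutation of `seq_len(nrow(locations))`.
#' @export
zigzag_order <- function(locations, carry = FALSE) {
  ord <- canonical_order(locations)
  canon <- locations[ord, ]
  book <- structure(list(locations = canon,
                         options = utils::modifyList(default_options(),
                                                     list(zigzag = TRUE,
                                                          zigzag_carry = carry))),
                    class = "fieldbook")
  plan <- traversal_plan(book, mode = "zigzag", carry = carry)
  ord[plan]
}

plan_direction_at <- function(plan, loc) {
  p <- match(loc, plan)
  attr(plan, "direction")[p]
}

#' Advance the cursor
#'
#' Moves to the next selected descriptor at the current location; when the
#' descriptor list is exhausted, to the first selected descriptor of the
#' next location of the active traversal plan. Past the last cell the
#' cursor reaches a defined end state (`at_end = TRUE`).
#'
#' @param book a `fieldbook`.
#' @return the new cursor (the book itself is not modified).
#' @export
advance <- function(book) {
  cur <- book$cursor
  if (cur$at_end) return(cur)
  sel <- selected_shortcuts(book)
  pos <- match(cur$trait, sel)
  plan <- traversal_plan(book)
  if (!is.na(pos) && pos < length(sel)) {
    return(new_cursor(cur$loc, sel[pos + 1L],
                      direction = plan_direction_at(plan, cur$loc)))
  }
  p <- match(cur$loc, plan)
  if (p < length(plan)) {
    nxt <- plan[p + 1L]
    new_cursor(nxt, sel[1], direction = plan_direction_at(plan, nxt))
  } else {
    new_cursor(at_end = TRUE)
  }
}

#' Step the cursor backwards
#'
#' Inverse of [advance()]; clamps at the first cell of the plan.
#'
#' @param book a `fieldbook`.
#' @return the new cursor.
#' @export
retreat <- function(book) {
  cur <- book$cursor
  sel <- selected_shortcuts(book)
  plan <- traversal_plan(book)
  if (cur$at_end) {
    last <- plan[length(plan)]
    return(new_cursor(last, sel[length(sel)],
                      direction = plan_direction_at(plan, last)))
  }
  pos <- match(cur$trait, sel)
  if (!is.na(pos) && pos > 1L) {
    return(new_cursor(cur$loc, sel[pos - 1L],
                      direction = plan_direction_at(plan, cur$loc)))
  }
  p <- match(cur$loc, plan)
  if (p > 1L) {
    prv <- plan[p - 1L]
    new_cursor(prv, sel[length(sel)], direction = plan_direction_at(plan, prv))
  } else {
    cur  # already at the very first cell
  }
}

#' Find the first empty cell
#'
#' Scans forward from the current cursor in plan order over selected
#' descriptors, wrapping once past the start, and returns the first
#' (location, descriptor) pair without an observation -- the "first empty"
#' button used to track missing data points when phenotyping repeatedly
#' over time.
#'
#' @param book a `fieldbook`.
#' @return a cursor at the first empty cell (the current cell if it is
#'   itself empty), or `NULL` when every selected cell is recorded.
#' @export
first_empty <- function(book) {
  sel <- selected_shortcuts(book)
  plan <- traversal_plan(book)
  cells_loc <- rep(plan, each = length(sel))
  cells_trait <- rep(sel, times = length(plan))
  ncell <- length(cells_loc)
  cur <- book$cursor
  start <- if (cur$at_end) 1L else {
    (match(cur$loc, plan) - 1L) * length(sel) + match(cur$trait, sel)
  }
  idx <- ((start - 1L + seq_len(ncell) - 1L) %% ncell) + 1L  # rotate: current first
  for (i in idx) {
    if (is.null(book$observations[[obs_key(cells_loc[i], cells_trait[i])]])) {
      return(new_cursor(cells_loc[i], cells_trait[i],
                        direction = plan_direction_at(plan, cells_loc[i])))
    }
  }
  NULL
}

#' Directional cursor jump
#'
#' The arrow-key moves: `up`/`down` step one plant within the current row
#' (clamped at the row ends); `left`/`right` move to the adjacent row at
#' the same plant position (clamped; when that position does not exist in
#' the target row, the nearest existing plant). The descriptor is
#' unchanged.
#'
#' @param book a `fieldbook`.
#' @param direction one of `"up"`, `"down"`, `"left"`, `"right"`.
#' @return the new cursor.
#' @export
jump <- function(book, direction) {
  direction <- match.arg(direction, c("up", "down", "left", "right"))
  cur <- book$cursor
  if (cur$at_end) return(cur)
  groups <- row_groups(book$locations)
  ri <- which(vapply(groups, function(g) cur$loc %in% g, logical(1)))
  g <- groups[[ri]]
  pos <- match(cur$loc, g)
  if (direction %in% c("up", "down")) {
    pos <- pos + if (direction == "down") 1L else -1L
    pos <- max(1L, min(length(g), pos))
    loc <- g[pos]
  } else {
    ri <- ri + if (direction == "right") 1L else -1L
    ri <- max(1L, min(length(groups), ri))
    tg <- groups[[ri]]
    loc <- tg[min(pos, length(tg))]
  }
  new_cursor(loc, cur$trait, direction = cur$direction)
}

#' Move the cursor to an addressed location
#'
#' @param book a `fieldbook`.
#' @param plot,row,plant grid key of the target location, or
#' @param accession_name alternative key for accession-keyed records.
#' @return cursor at that location and the first selected descriptor.
#' @export
goto_location <- function(book, plot = NULL, row = NULL, plant = NULL,
                          accession_name = NULL) {
  if (!is.null(accession_name)) {
    i <- which(book$locations$accession_name == str_trim(accession_name))
  } else {
    i <- which(book$locations$plot == str_trim(plot %||% "") &
               book$locations$row == str_trim(row %||% "") &
               book$locations$plant == str_trim(plant %||% ""))
  }
  if (length(i) == 0L) {
    stop_validation("no location matches that address",
                    subclass = "pheno_unknown_location")
  }
  plan <- traversal_plan(book)
  new_cursor(i[1], selected_shortcuts(book)[1],
             direction = plan_direction_at(plan, i[1]))
}
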