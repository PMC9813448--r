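# In-memory builders and independent oracles used across the suite.

EXAMPLE_SCALE <- "1: none; 3: little; 5: medium; 7: strong; 9: very strong"

# rectangular or ragged grid of triple-key locations; plants may be a
# single count or one count per (plot, row) in row-major order
grid_locations <- function(plots = 1, rows = 1, plants = 3) {
  out <- list()
  k <- 0L
  for (p in seq_len(plots)) {
    for (r in seq_len(rows)) {
      k <- k + 1L
      np <- rep_len(plants, k)[k]
      for (q in seq_len(np)) {
        out[[length(out) + 1L]] <- location_record(
          plot = as.character(p), row = as.character(r), plant = as.character(q),
          accession_name = "Riesling", database_key = sprintf("DBK%03d", length(out) + 1L))
      }
    }
  }
  do.call(rbind, out)
}

default_descriptors <- function() {
  rbind(
    trait_descriptor("RAT1", "severity", 1, EXAMPLE_SCALE),
    trait_descriptor("MV1", "length", 2, remark = "cm"),
    trait_descriptor("DT1", "budbreak", 3),
    trait_descriptor("TXT1", "note", 4),
    trait_descriptor("BBCH1", "stage", 5))
}

mini_book <- function(plots = 1, rows = 1, plants = 3,
                      descriptors = default_descriptors(), options = list()) {
  fieldbook(grid_locations(plots, rows, plants), descriptors, options = options)
}

# Independent serpentine oracle: per plot (numeric order), rows in numeric
# order; every second row of a plot reversed. Assumes numeric labels, as
# all fuzzed grids here have.
serpentine_oracle <- function(locations) {
  df <- data.frame(i = seq_len(nrow(locations)),
                   p = as.numeric(locations$plot),
                   r = as.numeric(locations$row),
                   q = as.numeric(locations$plant))
  res <- integer(0)
  for (p in sort(unique(df$p))) {
    flip <- FALSE
    for (r in sort(unique(df$r[df$p == p]))) {
      sel <- df[df$p == p & df$r == r, ]
      idx <- sel$i[order(sel$q)]
      if (flip) idx <- rev(idx)
      res <- c(res, idx)
      flip <- !flip
    }
  }
  res
}

# Independent first-empty oracle: linear scan of the full cell list in
# plan order, rotated so the current cursor cell comes first.
first_empty_oracle <- function(book) {
  sel <- book$descriptors$shortcut[book$descriptors$selected]
  plan <- traversal_plan(book)
  cells <- expand.grid(trait = sel, loc = plan, stringsAsFactors = FALSE)
  cells <- cells[, c("loc", "trait")]
  cur <- book$cursor
  start <- which(cells$loc == cur$loc & cells$trait == cur$trait)
  ord <- c(seq(start, nrow(cells)), seq_len(start - 1L))
  for (i in ord) {
    if (is.null(get_observation(book, cells$loc[i], cells$trait[i]))) {
      return(list(loc = cells$loc[i], trait = cells$trait[i]))
    }
  }
  NULL
}

obs_fingerprint <- function(book) {
  keys <- sort(names(book$observations))
  vapply(keys, function(k) serialize_observation(book$observations[[k]]),
         character(1))
}

# drive a full pass with valid values, recording at every advance step
complete_pass <- function(book) {
  fill_value <- function(d) {
    switch(names(c(rating = 1, measured_value = 2, date = 3, text = 4, bbch = 5))[d$type],
      rating = d$scale[[1]]$code[1],
      measured_value = "1.5",
      date = "2022-06-01",
      text = "ok",
      bbch = "grapevine:65")
  }
  steps <- 0L
  while (!book$cursor$at_end) {
    d <- book$descriptors[match(book$cursor$trait, book$descriptors$shortcut), ]
    book <- record(book, fill_value(d))
    if (book$options$multiple_selection) book$cursor <- advance(book)
    steps <- steps + 1L
  }
  list(book = book, steps = steps)
}
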