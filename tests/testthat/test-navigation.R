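# Traversal: canonical order, serpentine mode, advance, first-empty,
# directional jumps.

test_that("canonical order sorts plot, row, plant with numeric-aware comparison", {
  loc <- rbind(location_record("2", "1", "1"), location_record("1", "1", "2"),
               location_record("1", "1", "1"), location_record("2", "1", "2"))
  ord <- canonical_order(loc)
  expect_equal(paste(loc$plot[ord], loc$row[ord], loc$plant[ord]),
               c("1 1 1", "1 1 2", "2 1 1", "2 1 2"))

  loc2 <- rbind(location_record("1", "1", "10"), location_record("1", "1", "2"))
  expect_equal(canonical_order(loc2), c(2L, 1L))  # "2" walks before "10"

  expect_equal(canonical_order(location_record("5", "5", "5")), 1L)

  # accession-only records append after grid records in input order
  loc3 <- rbind(location_record(accession_name = "Zeta"),
                location_record("1", "1", "1"),
                location_record(accession_name = "Alpha"))
  expect_equal(canonical_order(loc3), c(2L, 1L, 3L))
})

test_that("zigzag reverses every second row and matches the brute-force oracle", {
  loc <- grid_locations(plots = 1, rows = 2, plants = 3)
  ord <- zigzag_order(loc)
  expect_equal(paste(loc$row[ord], loc$plant[ord]),
               c("1 1", "1 2", "1 3", "2 3", "2 2", "2 1"))

  one_row <- grid_locations(plots = 3, rows = 1, plants = 4)
  expect_equal(zigzag_order(one_row), canonical_order(one_row))

  set.seed(11)
  for (i in 1:50) {
    plots <- sample(1:3, 1)
    rows <- sample(1:4, 1)
    plants <- sample(1:5, plots * rows, replace = TRUE)  # ragged
    loc <- grid_locations(plots, rows, plants)
    perm <- sample(nrow(loc))
    shuffled <- loc[perm, ]
    ord <- zigzag_order(shuffled)
    expect_equal(sort(ord), seq_len(nrow(loc)))  # a permutation
    expect_equal(perm[ord], serpentine_oracle(loc))
    expect_equal(sort(canonical_order(shuffled)), seq_len(nrow(loc)))
  }
})

test_that("zigzag direction resets at each plot unless carry is requested", {
  # 2 plots x 2 rows x 2 plants: plot 2 row 1 starts forward again
  loc <- grid_locations(plots = 2, rows = 2, plants = 2)
  ord <- zigzag_order(loc)
  walked <- paste(loc$plot[ord], loc$row[ord], loc$plant[ord])
  expect_equal(walked, c("1 1 1", "1 1 2", "1 2 2", "1 2 1",
                         "2 1 1", "2 1 2", "2 2 2", "2 2 1"))
  # odd row count: carry continues the alternation into the next plot,
  # reset starts it forward again
  loc3 <- grid_locations(plots = 2, rows = 3, plants = 2)
  dir_of <- function(ord) {
    w <- split(loc3$plant[ord], paste(loc3$plot[ord], loc3$row[ord]))[
      unique(paste(loc3$plot[ord], loc3$row[ord]))]
    vapply(w, function(p) if (p[1] == "1") "f" else "b", character(1))
  }
  expect_equal(unname(dir_of(zigzag_order(loc3))), c("f", "b", "f", "f", "b", "f"))
  expect_equal(unname(dir_of(zigzag_order(loc3, carry = TRUE))),
               c("f", "b", "f", "b", "f", "b"))
})

test_that("advance walks descriptors within a location, then locations, then ends", {
  b <- mini_book(plots = 1, rows = 1, plants = 2,
                 descriptors = rbind(trait_descriptor("A", "a", 4),
                                     trait_descriptor("B", "b", 4)))
  expect_equal(b$cursor$trait, "A")
  b$cursor <- advance(b)
  expect_equal(b$cursor$trait, "B")
  expect_equal(b$cursor$loc, 1L)
  b$cursor <- advance(b)
  expect_equal(b$cursor$trait, "A")
  expect_equal(b$cursor$loc, 2L)
  b$cursor <- advance(b); b$cursor <- advance(b)
  expect_true(b$cursor$at_end)
  expect_true(advance(b)$at_end)  # end state is absorbing
})

test_that("advance skips unselected descriptors", {
  d <- rbind(trait_descriptor("D1", "", 4), trait_descriptor("D2", "", 4),
             trait_descriptor("D3", "", 4), trait_descriptor("D4", "", 4),
             trait_descriptor("D5", "", 4))
  b <- mini_book(descriptors = d)
  b <- set_selection(b, c("D2", "D4"))
  expect_equal(b$cursor$trait, "D2")
  b$cursor <- advance(b)
  expect_equal(b$cursor$trait, "D4")  # D3 skipped
})

test_that("repeated advance visits every selected cell exactly once in both modes", {
  set.seed(23)
  for (mode in c(FALSE, TRUE)) {
    for (i in 1:10) {
      plots <- sample(1:2, 1); rows <- sample(1:3, 1)
      plants <- sample(1:4, plots * rows, replace = TRUE)
      b <- fieldbook(grid_locations(plots, rows, plants), default_descriptors(),
                     options = list(zigzag = mode))
      nsel <- sample(1:5, 1)
      b <- set_selection(b, sample(b$descriptors$shortcut, nsel))
      b$cursor <- goto_location(b, plot = b$locations$plot[traversal_plan(b)[1]],
                                row = b$locations$row[traversal_plan(b)[1]],
                                plant = b$locations$plant[traversal_plan(b)[1]])
      seen <- character(0)
      while (!b$cursor$at_end) {
        seen <- c(seen, paste(b$cursor$loc, b$cursor$trait))
        b$cursor <- advance(b)
      }
      expect_equal(length(seen), nrow(b$locations) * nsel)
      expect_equal(anyDuplicated(seen), 0L)
    }
  }
})

test_that("retreat inverts advance and clamps at the first cell", {
  b <- mini_book(plants = 2)
  first <- b$cursor
  expect_equal(retreat(b), first)  # clamped
  b$cursor <- advance(b)
  b$cursor <- retreat(b)
  expect_equal(b$cursor$trait, first$trait)
  expect_equal(b$cursor$loc, first$loc)
})

test_that("first_empty returns the current cell on an empty book and NULL when complete", {
  b <- mini_book(plants = 2)
  fe <- first_empty(b)
  expect_equal(fe$loc, b$cursor$loc)
  expect_equal(fe$trait, b$cursor$trait)
  done <- complete_pass(b)$book
  expect_null(first_empty(done))
})

test_that("first_empty agrees with the linear-scan oracle on single-hole books", {
  set.seed(31)
  for (i in 1:100) {
    b <- mini_book(plots = sample(1:2, 1), rows = sample(1:2, 1),
                   plants = sample(1:3, 1),
                   options = list(zigzag = sample(c(TRUE, FALSE), 1)))
    b <- complete_pass(b)$book
    sel <- b$descriptors$shortcut
    hole_loc <- sample(nrow(b$locations), 1)
    hole_trait <- sample(sel, 1)
    b$observations[[paste0(hole_loc, "\r", hole_trait)]] <- NULL
    start <- sample(nrow(b$locations), 1)
    b$cursor <- goto_location(b, plot = b$locations$plot[start],
                              row = b$locations$row[start],
                              plant = b$locations$plant[start])
    got <- first_empty(b)
    want <- first_empty_oracle(b)
    expect_equal(got$loc, want$loc)
    expect_equal(got$trait, want$trait)
    expect_equal(got$loc, hole_loc)
    expect_equal(got$trait, hole_trait)
  }
})

test_that("directional jumps clamp at row ends and find the nearest plant across rows", {
  b <- mini_book(plots = 1, rows = 1, plants = 3)
  b$cursor <- goto_location(b, plot = "1", row = "1", plant = "2")
  b$cursor <- jump(b, "down")
  expect_equal(b$locations$plant[b$cursor$loc], "3")
  b$cursor <- jump(b, "down")
  expect_equal(b$locations$plant[b$cursor$loc], "3")  # clamped
  b$cursor <- jump(b, "up"); b$cursor <- jump(b, "up"); b$cursor <- jump(b, "up")
  expect_equal(b$locations$plant[b$cursor$loc], "1")  # clamped at the top

  b2 <- mini_book(plots = 1, rows = 2, plants = 3)
  b2$cursor <- goto_location(b2, plot = "1", row = "1", plant = "2")
  b2$cursor <- jump(b2, "right")
  expect_equal(paste(b2$locations$row[b2$cursor$loc], b2$locations$plant[b2$cursor$loc]),
               "2 2")
  b2$cursor <- jump(b2, "left")
  expect_equal(b2$locations$row[b2$cursor$loc], "1")
  b2$cursor <- jump(b2, "left")
  expect_equal(b2$locations$row[b2$cursor$loc], "1")  # clamped

  # ragged target row: jump lands on the nearest existing plant
  b3 <- fieldbook(grid_locations(plots = 1, rows = 2, plants = c(3, 2)),
                  default_descriptors())
  b3$cursor <- goto_location(b3, plot = "1", row = "1", plant = "3")
  b3$cursor <- jump(b3, "right")
  expect_equal(paste(b3$locations$row[b3$cursor$loc], b3$locations$plant[b3$cursor$loc]),
               "2 2")

  # descriptor is untouched by jumps
  expect_equal(b3$cursor$trait, "RAT1")
})
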