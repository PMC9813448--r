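# Exchange formats: input workbook parsing, output layout, round-trips.

test_that("a fixture workbook parses to the constructed counts", {
  wb <- withr::local_tempfile(fileext = ".xlsx")
  make_input_workbook(fixture_spec(plots = 2, rows_per_plot = 1,
                                   plants_per_row = 3), wb)
  b <- read_input(wb)
  expect_equal(nrow(b$locations), 6)
  expect_equal(nrow(b$descriptors), 5)
  expect_length(b$observations, 0)
  expect_equal(b$cursor$loc, 1L)
  expect_equal(b$cursor$trait, b$descriptors$shortcut[1])
})

test_that("descriptor rows with unknown type codes abort the import naming the row", {
  dir <- withr::local_tempdir()
  loc <- data.frame(a = "1", b = "1", c = "1", d = "", e = "", f = "", g = "",
                    h = "", i = "", j = "", k = "")
  names(loc) <- c("plot", "row", "plant", "accession name", "accession number",
                  "variety number", "genotype", "mother", "father",
                  "information", "database-key")
  traits <- data.frame(shortcut = c("OK", "BAD"), description = c("", ""),
                       type = c("4", "7"), values = c("", ""), remark = c("", ""))
  wb <- file.path(dir, "bad.xlsx")
  write_xlsx_minimal(list(Locations = loc, Traits = traits), wb)
  err <- tryCatch(read_input(wb), error = function(e) e)
  expect_s3_class(err, "pheno_validation_error")
  expect_match(conditionMessage(err), "row 3")
  expect_match(conditionMessage(err), "7")
})

test_that("accession-only rows load in alternative-key mode; invalid rows are reported", {
  dir <- withr::local_tempdir()
  loc <- data.frame(plot = c("1", "", ""), row = c("1", "", ""),
                    plant = c("1", "", ""),
                    acc = c("", "Riesling", ""), n5 = "", n6 = "", n7 = "",
                    n8 = "", n9 = "", n10 = "", n11 = "")
  names(loc) <- c("plot", "row", "plant", "accession name", "accession number",
                  "variety number", "genotype", "mother", "father",
                  "information", "database-key")
  loc$information[3] <- "orphan"  # row 4: neither key -> invalid
  traits <- data.frame(shortcut = "T", description = "", type = "4",
                       values = "", remark = "")
  wb <- file.path(dir, "alt.xlsx")
  write_xlsx_minimal(list(Locations = loc, Traits = traits), wb)
  expect_warning(b <- read_input(wb), "invalid location row")
  expect_equal(nrow(b$locations), 2)
  rep <- attr(b, "import_report")
  expect_equal(rep$invalid_locations$row, 4L)
})

test_that("missing sheets and missing files raise distinct errors", {
  dir <- withr::local_tempdir()
  one <- file.path(dir, "one.xlsx")
  write_xlsx_minimal(list(Locations = data.frame(plot = "1")), one)
  expect_error(read_input(one), class = "pheno_missing_sheet")
  expect_error(read_input(file.path(dir, "absent.xlsx")), class = "pheno_io_error")
})

test_that("output layout: location columns + two remarks columns + one per descriptor", {
  b <- mini_book(plots = 2, rows = 1, plants = 3)
  b <- record(b, "3")
  b <- set_remarks(b, "north edge", "leaf damage")
  out <- withr::local_tempfile(fileext = ".csv")
  write_output(b, out, format = "csv")
  tab <- readr::read_csv(out, col_types = readr::cols(.default = "c"), na = character())
  expect_equal(ncol(tab), 11 + 2 + 5)
  expect_equal(names(tab)[12:13], c("location info", "plant note"))
  expect_equal(names(tab)[14:18], b$descriptors$shortcut)
  # exactly one observation cell filled, with the recorded code
  obs_cells <- unlist(tab[, 14:18])
  expect_equal(sum(nzchar(obs_cells)), 1)
  expect_equal(tab$RAT1[1], "3")
  # remarks in two distinct cells of the first row
  expect_equal(tab[["location info"]][1], "north edge")
  expect_equal(tab[["plant note"]][1], "leaf damage")
  expect_equal(sum(nzchar(tab[["location info"]])), 1)
  # database key copied verbatim
  expect_equal(tab[["database-key"]], b$locations$database_key)
})

test_that("multi-valued ratings are comma-joined in the export", {
  b <- mini_book(options = list(multiple_selection = TRUE))
  b <- record(b, "3,5")
  out <- withr::local_tempfile(fileext = ".csv")
  write_output(b, out, format = "csv")
  tab <- readr::read_csv(out, col_types = readr::cols(.default = "c"), na = character())
  expect_equal(tab$RAT1[1], "3,5")
})

test_that("xlsx stores dates as native date cells", {
  b <- mini_book()
  b$cursor <- structure(list(loc = 1L, trait = "DT1", direction = "forward",
                             at_end = FALSE), class = "fb_cursor")
  b <- record(b, "2022-06-01")
  out <- withr::local_tempfile(fileext = ".xlsx")
  write_output(b, out)
  raw <- suppressMessages(readxl::read_excel(out))
  expect_s3_class(raw$DT1, "POSIXct")
  expect_equal(format(raw$DT1[1], "%Y-%m-%d"), "2022-06-01")
})

test_that("a multi-code rating cell is flagged, not restored, when multiple selection is off", {
  b <- mini_book(options = list(multiple_selection = TRUE))
  b <- record(b, "3,5")
  out <- withr::local_tempfile(fileext = ".csv")
  write_output(b, out, format = "csv")
  b_single <- mini_book(options = list(multiple_selection = FALSE))
  expect_warning(b2 <- read_output(out, b_single), "failed re-validation")
  expect_length(b2$observations, 0)
  rep <- attr(b2, "validation_report")
  expect_equal(rep$value, "3,5")
  expect_equal(rep$shortcut, "RAT1")
})

test_that("read_output rejects files whose columns do not match the book", {
  b <- mini_book()
  out <- withr::local_tempfile(fileext = ".csv")
  write_output(b, out, format = "csv")
  fewer <- fieldbook(b$locations, b$descriptors[1:3, ])
  expect_error(read_output(out, fewer), class = "pheno_output_mismatch")
})

roundtrip_identical <- function(b, format) {
  out <- tempfile(fileext = paste0(".", format))
  on.exit(unlink(out))
  write_output(b, out, format = format)
  fresh <- fieldbook(b$locations, b$descriptors,
                     options = b$options, registry = b$registry)
  b2 <- read_output(out, fresh)
  expect_identical(as.data.frame(b2$locations), as.data.frame(b$locations))
  expect_identical(obs_fingerprint(b2), obs_fingerprint(b))
  b2
}

test_that("read -> write -> read reproduces locations and observations losslessly", {
  set.seed(99)
  for (i in 1:10) {
    spec <- fixture_spec(plots = sample(1:3, 1), rows_per_plot = sample(1:3, 1),
                         plants_per_row = sample(1:4, 1),
                         fill_fraction = runif(1), seed = i)
    b <- make_session(spec)
    x <- roundtrip_identical(b, "xlsx")
    c <- roundtrip_identical(b, "csv")
    # cross-format equality
    expect_identical(obs_fingerprint(x), obs_fingerprint(c))
  }
})

test_that("the CSV pair container round-trips through read_input", {
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "trial.csv")
  make_input_workbook(fixture_spec(plots = 1, rows_per_plot = 2,
                                   plants_per_row = 2), stem)
  expect_true(file.exists(file.path(dir, "trial_locations.csv")))
  expect_true(file.exists(file.path(dir, "trial_traits.csv")))
  b <- read_input(stem)
  expect_equal(nrow(b$locations), 4)
  # same fixture as xlsx decodes identically
  wb <- file.path(dir, "trial.xlsx")
  make_input_workbook(fixture_spec(plots = 1, rows_per_plot = 2,
                                   plants_per_row = 2), wb)
  bx <- read_input(wb)
  expect_identical(as.data.frame(b$locations), as.data.frame(bx$locations))
  expect_identical(b$descriptors$values_raw, bx$descriptors$values_raw)
})

test_that("a merged 'accession name and number' column is accepted on read", {
  dir <- withr::local_tempdir()
  loc <- data.frame(p = "1", r = "1", q = "1", m = "Riesling ACC1", v = "",
                    g = "", mo = "", f = "", i = "", k = "")
  names(loc) <- c("plot", "row", "plant", "accession name and number",
                  "variety number", "genotype", "mother", "father",
                  "information", "database-key")
  traits <- data.frame(shortcut = "T", description = "", type = "4",
                       values = "", remark = "")
  wb <- file.path(dir, "merged.xlsx")
  write_xlsx_minimal(list(Locations = loc, Traits = traits), wb)
  b <- read_input(wb)
  expect_equal(b$locations$accession_name, "Riesling ACC1")
  expect_equal(b$locations$accession_number, "")
  expect_equal(b$locations$database_key, "")
})
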