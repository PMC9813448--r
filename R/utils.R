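# Small shared helpers.

str_trim <- function(x) {
  x[is.na(x)] <- ""
  gsub("^[[:space:]]+|[[:space:]]+$", "", x)
}

is_blank <- function(x) !nzchar(str_trim(x))

#' @noRd
#' Numeric-aware ordering key for plot/row/plant labels. Labels that are
#' pure digit strings compare numerically among themselves and sort before
#' non-numeric labels; everything else compares lexicographically (C locale).
nat_key <- function(x) {
  x <- str_trim(x)
  digits <- grepl("^[0-9]+$", x)
  num <- rep(Inf, length(x))
  num[digits] <- as.numeric(x[digits])
  list(nondigit = !digits, num = num, str = x)
}

# order() over one or more label vectors using nat_key on each
nat_order <- function(...) {
  keys <- lapply(list(...), nat_key)
  args <- unlist(lapply(keys, function(k) list(k$nondigit, k$num, k$str)),
                 recursive = FALSE)
  args$method <- "radix"
  do.call(order, args)
}

# numeric -> shortest exact-ish decimal text, never scientific
num_to_str <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
}

iso_date <- function(d) format(d, "%Y-%m-%d")

parse_iso_date <- function(x) {
  x <- str_trim(x)
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)) return(NULL)
  d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) NA)
  if (is.na(d) || format(d, "%Y-%m-%d") != x) return(NULL)
  d
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
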