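#' Well addresses on a 384-well plate
#'
#' A well address is a row letter followed by an unpadded column number
#' ("A1" ... "P24"). Input is case-insensitive and leading zeros in the
#' column are tolerated ("a01" parses to "A1"); the canonical form is
#' upper-case with no zero padding, so that parsing followed by formatting
#' is the identity on canonical strings.
#'
#' @param x Character vector of well addresses.
#' @param n_rows,n_cols Plate geometry bounds. Defaults describe a 384-well
#'   plate (rows A-P, columns 1-24); other rectangular geometries are
#'   supported by changing the bounds.
#' @return `parse_well()` returns a tibble with columns `well` (canonical
#'   string), `row` (integer, 1-based), `column` (integer), and `valid`
#'   (logical). `canonical_well()` returns the canonical string, `NA` for
#'   invalid input. `well_address()` builds canonical strings from row and
#'   column indices.
#' @examples
#' parse_well(c("a1", "P24", "Q1"))
#' canonical_well("b07")
#' well_address(2, 7)
#' @export
parse_well <- function(x, n_rows = 16L, n_cols = 24L) {
  stopifnot(n_rows >= 1, n_rows <= 26, n_cols >= 1)
  x_up <- toupper(trimws(as.character(x)))
  m <- regmatches(x_up, regexec("^([A-Z])0*([0-9]+)$", x_up))
  row <- vapply(m, function(g) if (length(g) == 3) match(g[2], LETTERS) else NA_integer_,
                integer(1))
  col <- vapply(m, function(g) if (length(g) == 3) suppressWarnings(as.integer(g[3])) else NA_integer_,
                integer(1))
  valid <- !is.na(row) & !is.na(col) & row <= n_rows & col >= 1L & col <= n_cols
  tibble::tibble(
    well = ifelse(valid, paste0(LETTERS[row], col), NA_character_),
    row = ifelse(valid, row, NA_integer_),
    column = ifelse(valid, col, NA_integer_),
    valid = valid
  )
}

#' @rdname parse_well
#' @export
canonical_well <- function(x, n_rows = 16L, n_cols = 24L) {
  parse_well(x, n_rows = n_rows, n_cols = n_cols)$well
}

#' @rdname parse_well
#' @param row,column Integer row (1 = "A") and column indices.
#' @export
well_address <- function(row, column) {
  stopifnot(all(row >= 1), all(row <= 26), all(column >= 1))
  paste0(LETTERS[row], as.integer(column))
}
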