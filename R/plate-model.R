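#' Assemble a screen dataset
#'
#' A screen dataset bundles the three tables every downstream stage works
#' from: the plate layout (which well holds which role or compound), the
#' well-level signals for every plate and read, and the compound-library
#' registry. All three are ordinary tibbles so they compose with dplyr.
#'
#' @param layout Tibble with columns `plate_id`, `well`, `role`
#'   (one of `"M0"`, `"M1_DMSO"`, `"M1_TSA"`, `"COMPOUND"`, `"EMPTY"`) and
#'   `compound_id` (`NA` except for compound wells).
#' @param signals Tibble with columns `plate_id`, `read` (integer read
#'   index), `well`, `rlu` (non-negative signal) and optionally `viability`.
#' @param registry Tibble with columns `compound_id`, `library`.
#' @param n_rows,n_cols Plate geometry bounds (see [parse_well()]).
#' @return An object of class `screen_dataset`: a list with elements
#'   `layout`, `signals`, `registry`.
#' @export
screen_dataset <- function(layout, signals, registry, n_rows = 16L, n_cols = 24L) {
  layout <- tibble::as_tibble(layout)
  signals <- tibble::as_tibble(signals)
  registry <- tibble::as_tibble(registry)

  need <- function(tbl, cols, what) {
    miss <- setdiff(cols, names(tbl))
    if (length(miss)) {
      abort(sprintf("%s is missing mandatory column(s): %s", what,
                    paste(miss, collapse = ", ")),
            class = "seapscreen_format_error")
    }
  }
  need(layout, c("plate_id", "well", "role", "compound_id"), "layout")
  need(signals, c("plate_id", "read", "well", "rlu"), "signals")
  need(registry, c("compound_id", "library"), "registry")
  if (!"viability" %in% names(signals)) signals$viability <- NA_real_

  layout$well <- canonical_well(layout$well, n_rows, n_cols)
  signals$well <- canonical_well(signals$well, n_rows, n_cols)
  signals$read <- as.integer(signals$read)

  dup <- signals |>
    dplyr::count(.data$plate_id, .data$read, .data$well) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicate (plate, read, well) rows: %s",
                  paste(utils::head(paste(dup$plate_id, dup$read, dup$well), 5),
                        collapse = "; ")),
          class = "seapscreen_integrity_error")
  }

  orphan <- signals |>
    dplyr::anti_join(layout, by = c("plate_id", "well"))
  if (nrow(orphan)) {
    abort(sprintf("signal wells absent from layout: %s",
                  paste(utils::head(paste(orphan$plate_id, orphan$well), 5),
                        collapse = "; ")),
          class = "seapscreen_integrity_error")
  }

  cmpd <- layout$compound_id[layout$role == "COMPOUND"]
  unresolved <- setdiff(cmpd, registry$compound_id)
  if (length(unresolved)) {
    abort(sprintf("compound id(s) not in library registry: %s",
                  paste(utils::head(unresolved, 5), collapse = ", ")),
          class = "seapscreen_integrity_error")
  }

  structure(
    list(layout = layout,
         signals = dplyr::arrange(signals, .data$plate_id, .data$read, .data$well),
         registry = dplyr::distinct(registry, .data$compound_id, .data$library)),
    class = "screen_dataset"
  )
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf(
    "<screen_dataset> %d plate(s), %d read(s)/plate, %d compounds in %d library(ies)\n",
    dplyr::n_distinct(x$layout$plate_id),
    dplyr::n_distinct(x$signals$read),
    nrow(x$registry),
    dplyr::n_distinct(x$registry$library)))
  invisible(x)
}

## Auto-detect tab vs comma delimiter from the header line.
.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
}

## Parse RLU-style numbers; thousands-separator commas are accepted
## ("12,432.0" -> 12432), decimal separator is the dot only.
parse_signal_number <- function(x) {
  suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
}

#' Load a screen dataset from delimited text files
#'
#' Reads long-format plate files (one row per well per read) and compound
#' manifests, and assembles a validated [screen_dataset()]. The delimiter
#' (comma or tab) is auto-detected per file. Numeric fields may carry
#' thousands-separator commas ("12,432.0"); rows whose signal cannot be
#' parsed are dropped with a warning naming the file and line.
#'
#' @param plate_files Paths to plate files with columns `plate_id`, `read`,
#'   `well`, `role`, `compound_id`, `rlu` and optionally `viability`.
#' @param manifest_files Paths to manifest files with columns
#'   `compound_id`, `library`, `plate_id`, `well`.
#' @inheritParams screen_dataset
#' @return A [screen_dataset()].
#' @export
load_screen <- function(plate_files, manifest_files, n_rows = 16L, n_cols = 24L) {
  if (length(manifest_files) == 0) {
    abort("no libraries registered: at least one manifest file is required",
          class = "seapscreen_format_error")
  }
  if (length(plate_files) == 0) {
    abort("no plate files given", class = "seapscreen_format_error")
  }

  plate_rows <- purrr::map_dfr(plate_files, function(f) {
    tbl <- .read_delim_auto(f)
    miss <- setdiff(c("plate_id", "read", "well", "role", "compound_id", "rlu"),
                    names(tbl))
    if (length(miss)) {
      abort(sprintf("plate file '%s' is missing mandatory column(s): %s",
                    f, paste(miss, collapse = ", ")),
            class = "seapscreen_format_error")
    }
    tbl$rlu_parsed <- parse_signal_number(tbl$rlu)
    bad <- which(!is.na(tbl$rlu) & is.na(tbl$rlu_parsed))
    if (length(bad)) {
      warn(sprintf("dropping %d row(s) with unparseable rlu in '%s' (lines %s)",
                   length(bad), f,
                   paste(utils::head(bad + 1L, 10), collapse = ", ")))
      tbl <- tbl[-bad, , drop = FALSE]
    }
    tbl$viability_parsed <-
      if ("viability" %in% names(tbl)) parse_signal_number(tbl$viability) else NA_real_
    tibble::tibble(
      plate_id = tbl$plate_id,
      read = as.integer(tbl$read),
      well = tbl$well,
      role = toupper(tbl$role),
      compound_id = dplyr::if_else(tbl$role == "COMPOUND", tbl$compound_id,
                                   NA_character_),
      rlu = tbl$rlu_parsed,
      viability = tbl$viability_parsed
    )
  })

  bad_role <- setdiff(unique(plate_rows$role), .roles)
  if (length(bad_role)) {
    abort(sprintf("unknown well role(s): %s", paste(bad_role, collapse = ", ")),
          class = "seapscreen_format_error")
  }

  layout <- plate_rows |>
    dplyr::distinct(.data$plate_id, .data$well, .data$role, .data$compound_id)
  conflict <- layout |>
    dplyr::count(.data$plate_id, .data$well) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict)) {
    abort(sprintf("conflicting role/compound assignment across reads for well(s): %s",
                  paste(utils::head(paste(conflict$plate_id, conflict$well), 5),
                        collapse = "; ")),
          class = "seapscreen_integrity_error")
  }

  manifest <- purrr::map_dfr(manifest_files, function(f) {
    tbl <- .read_delim_auto(f)
    miss <- setdiff(c("compound_id", "library"), names(tbl))
    if (length(miss)) {
      abort(sprintf("manifest file '%s' is missing mandatory column(s): %s",
                    f, paste(miss, collapse = ", ")),
            class = "seapscreen_format_error")
    }
    tbl
  })
  dup <- manifest |>
    dplyr::count(.data$library, .data$compound_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicate compound id(s) within a library: %s",
                  paste(utils::head(paste(dup$library, dup$compound_id), 5),
                        collapse = "; ")),
          class = "seapscreen_integrity_error")
  }

  screen_dataset(
    layout = dplyr::arrange(layout, .data$plate_id, .data$well),
    signals = plate_rows[, c("plate_id", "read", "well", "rlu", "viability")],
    registry = dplyr::distinct(manifest, .data$compound_id, .data$library),
    n_rows = n_rows, n_cols = n_cols
  )
}

#' Write a screen dataset back to delimited text
#'
#' Inverse of [load_screen()]: emits one tab-separated plate file and one
#' manifest file. Numbers are written with a round-trippable representation
#' so `load_screen(write_screen(x))` reproduces every value bit-exactly.
#'
#' @param dataset A [screen_dataset()].
#' @param plate_file,manifest_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_screen <- function(dataset, plate_file, manifest_file) {
  stopifnot(inherits(dataset, "screen_dataset"))
  out <- dataset$signals |>
    dplyr::left_join(dataset$layout, by = c("plate_id", "well")) |>
    dplyr::select("plate_id", "read", "well", "role", "compound_id",
                  "rlu", "viability")
  readr::write_tsv(out, plate_file, progress = FALSE)
  manifest <- dataset$registry |>
    dplyr::left_join(
      dplyr::filter(dataset$layout, .data$role == "COMPOUND") |>
        dplyr::select("compound_id", "plate_id", "well"),
      by = "compound_id")
  readr::write_tsv(manifest, manifest_file, progress = FALSE)
  invisible(c(plate_file, manifest_file))
}

#' Convert a plate-reader matrix grid to long format
#'
#' Long format (one row per well per read) is the canonical form
#' throughout the package; readers that export a 16 x 24 signal grid (rows
#' A-P, columns 1-24) can be converted with this helper and fed to
#' [screen_dataset()] alongside a layout.
#'
#' @param grid Numeric matrix of signals; rows are plate rows (A, B, ...),
#'   columns are plate columns (1, 2, ...).
#' @param plate_id Plate identifier for every well.
#' @param read Read index.
#' @param drop_na Drop wells with `NA` signal (unused wells) from the
#'   output (default `TRUE`).
#' @return Tibble with columns `plate_id`, `read`, `well`, `rlu`.
#' @examples
#' g <- matrix(1:8, nrow = 2, ncol = 4)
#' grid_to_long(g, "P1", 1)
#' @export
grid_to_long <- function(grid, plate_id, read, drop_na = TRUE) {
  grid <- as.matrix(grid)
  stopifnot(nrow(grid) <= 26)
  out <- tibble::tibble(
    plate_id = plate_id,
    read = as.integer(read),
    well = well_address(rep(seq_len(nrow(grid)), times = ncol(grid)),
                        rep(seq_len(ncol(grid)), each = nrow(grid))),
    rlu = as.vector(grid))
  if (drop_na) out <- out[!is.na(out$rlu), , drop = FALSE]
  out
}

#' Validate a plate layout
#'
#' Checks a layout table against the plate geometry and role rules, and
#' reports problems as a tibble of issues rather than raising errors, so a
#' whole plate set can be screened in one pass. A usable layout must also
#' contain at least one solvent-control (`M1_DMSO`) well per plate, since
#' hit thresholds are undefined without solvent controls.
#'
#' @inheritParams screen_dataset
#' @return Tibble with columns `severity` (`"error"` or `"warning"`),
#'   `plate_id`, `well`, `message`; zero rows iff the layout is valid.
#' @export
validate_layout <- function(layout, n_rows = 16L, n_cols = 24L) {
  layout <- tibble::as_tibble(layout)
  issues <- list()
  add <- function(severity, plate_id, well, message) {
    issues[[length(issues) + 1L]] <<-
      tibble::tibble(severity = severity, plate_id = plate_id,
                     well = well, message = message)
  }

  parsed <- parse_well(layout$well, n_rows, n_cols)
  for (i in which(!parsed$valid)) {
    add("error", layout$plate_id[i], as.character(layout$well[i]),
        sprintf("well address out of range (rows A-%s, columns 1-%d)",
                LETTERS[n_rows], n_cols))
  }
  for (i in which(!layout$role %in% .roles)) {
    add("error", layout$plate_id[i], layout$well[i],
        sprintf("unknown role '%s'", layout$role[i]))
  }
  for (i in which(layout$role == "COMPOUND" & is.na(layout$compound_id))) {
    add("error", layout$plate_id[i], layout$well[i],
        "compound well without compound_id")
  }
  for (i in which(layout$role != "COMPOUND" & !is.na(layout$compound_id))) {
    add("warning", layout$plate_id[i], layout$well[i],
        "non-compound well carries a compound_id (ignored)")
  }

  dup_well <- layout |>
    dplyr::count(.data$plate_id, .data$well) |>
    dplyr::filter(.data$n > 1)
  for (i in seq_len(nrow(dup_well))) {
    add("error", dup_well$plate_id[i], dup_well$well[i],
        "well assigned more than one role")
  }
  dup_cmpd <- layout |>
    dplyr::filter(.data$role == "COMPOUND") |>
    dplyr::count(.data$plate_id, .data$compound_id) |>
    dplyr::filter(.data$n > 1)
  for (i in seq_len(nrow(dup_cmpd))) {
    add("error", dup_cmpd$plate_id[i], NA_character_,
        sprintf("compound '%s' appears more than once on the plate",
                dup_cmpd$compound_id[i]))
  }

  for (p in unique(layout$plate_id)) {
    if (!any(layout$role[layout$plate_id == p] == "M1_DMSO")) {
      add("error", p, NA_character_,
          "no solvent control wells: hit thresholds are not computable")
    }
  }

  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(severity = character(), plate_id = character(),
                   well = character(), message = character())
  }
}
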