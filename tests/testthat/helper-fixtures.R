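# Small in-code fixtures shared across test files.

# A minimal one-plate layout: 3 M0, 3 M1_DMSO, 2 M1_TSA wells in column 1,
# then `n_compound` compound wells.
tiny_layout <- function(n_compound = 4, plate_id = "P1") {
  wells <- as.vector(outer(LETTERS[1:16], 1:24, paste0))
  roles <- c(rep("M0", 3), rep("M1_DMSO", 3), rep("M1_TSA", 2),
             rep("COMPOUND", n_compound))
  tibble::tibble(
    plate_id = plate_id,
    well = wells[seq_along(roles)],
    role = roles,
    compound_id = c(rep(NA_character_, 8), sprintf("X%02d", seq_len(n_compound)))
  )
}

# Noiseless two-read dataset: every role has a fixed signal, compounds get
# `m1_signal * effect` where `effects` is named by compound_id.
tiny_dataset <- function(effects = c(X01 = 1, X02 = 1, X03 = 1, X04 = 1),
                         m0_signal = 100, m1_signal = 300, tsa_signal = 3000,
                         reads = 1:2, read_scale = c(1, 1),
                         viability = NULL) {
  layout <- tiny_layout(n_compound = length(effects))
  base <- c(M0 = m0_signal, M1_DMSO = m1_signal, M1_TSA = tsa_signal,
            COMPOUND = m1_signal)
  signals <- purrr::map_dfr(seq_along(reads), function(i) {
    r <- reads[i]
    rlu <- base[layout$role] * read_scale[i]
    is_c <- layout$role == "COMPOUND"
    rlu[is_c] <- rlu[is_c] * effects[layout$compound_id[is_c]]
    tibble::tibble(plate_id = layout$plate_id, read = r, well = layout$well,
                   rlu = unname(rlu),
                   viability = if (is.null(viability)) NA_real_
                               else unname(viability[layout$well]))
  })
  registry <- tibble::tibble(compound_id = names(effects), library = "LIB")
  screen_dataset(layout, signals, registry)
}

# Ct record builder: one row per technical replicate from a table of
# (experiment, condition, gene) -> mean ct, zero technical spread.
ct_records_exact <- function(ct_tbl, n_tech = 2) {
  tidyr::uncount(tibble::as_tibble(ct_tbl), n_tech)
}
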