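## sdlog such that a log-normal has coefficient of variation `cv`.
.lognorm_sigma <- function(cv) sqrt(log(1 + cv^2))

## Mean-one multiplicative log-normal noise with the requested CV, so a
## configured role mean is the true mean of the simulated signals.
.rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- .lognorm_sigma(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Configuration for a simulated reporter screen
#'
#' Describes a multi-plate, dual-read 384-well reporter screen with
#' background (M0), solvent (M1_DMSO) and positive (M1_TSA) control wells,
#' one compound well per compound per plate, planted multiplicative hit
#' effects, and planted cytotoxic compounds that depress both viability
#' and signal. Defaults emulate a 2054-compound deck screened on seven
#' plates (four of 320 and three of 258 compounds), two reads whose
#' baselines differ (read 1 attenuated, as in phenol-red-containing
#' medium) with control CVs of 0.45 and 0.30 — the high-variability
#' regime in which per-plate Z' between background and solvent controls
#' is negative and only strong activators are callable.
#'
#' @param n_plates Number of plates.
#' @param n_m0,n_m1_dmso,n_m1_tsa Control wells per role per plate.
#' @param compounds_per_plate Integer vector (recycled) of compound wells
#'   per plate.
#' @param libraries Character vector (recycled) naming each plate's
#'   library.
#' @param reads Number of reads.
#' @param base_rlu Mean M0 background signal in read 2 (RLU).
#' @param m1_multiplier Solvent-control activation over M0.
#' @param tsa_multiplier Positive-control activation over the solvent
#'   control.
#' @param read_scale Per-read baseline scale factors (read 1 < 1 models
#'   phenol-red attenuation).
#' @param control_cv Per-read multiplicative noise CV applied to every
#'   well.
#' @param viability_base Mean viability luminescence of healthy wells.
#' @param viability_cv CV of the viability measurement.
#' @param hits Tibble with columns `compound` (1-based deck index) and
#'   `effect` (multiplier on the M1 signal); default three 5x activators.
#' @param cytotoxics Tibble with columns `compound`,
#'   `viability_fraction`, `signal_fraction`; default four strongly
#'   cytotoxic compounds whose reporter signal collapses with viability.
#' @param seed Integer RNG seed; the whole simulation is a deterministic
#'   function of the config including the seed.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_plates = 7,
                              n_m0 = 16, n_m1_dmso = 16, n_m1_tsa = 8,
                              compounds_per_plate = c(320, 320, 320, 320,
                                                      258, 258, 258),
                              libraries = c(rep("LOPAC", 4), rep("ENZO", 3)),
                              reads = 2,
                              base_rlu = 5000,
                              m1_multiplier = 3,
                              tsa_multiplier = 10,
                              read_scale = c(0.5, 1),
                              control_cv = c(0.45, 0.30),
                              viability_base = 1e5,
                              viability_cv = 0.1,
                              hits = tibble::tibble(
                                compound = c(150, 900, 1600), effect = 5),
                              cytotoxics = tibble::tibble(
                                compound = c(300, 700, 1400, 1900),
                                viability_fraction = 0.2,
                                signal_fraction = 0.3),
                              seed = 1L) {
  compounds_per_plate <- rep_len(compounds_per_plate, n_plates)
  libraries <- rep_len(libraries, n_plates)
  read_scale <- rep_len(read_scale, reads)
  control_cv <- rep_len(control_cv, reads)
  hits <- tibble::as_tibble(hits)
  cytotoxics <- tibble::as_tibble(cytotoxics)

  n_cmpd <- sum(compounds_per_plate)
  stopifnot(base_rlu > 0, m1_multiplier > 0, tsa_multiplier > 0,
            all(read_scale > 0), all(control_cv >= 0),
            n_m0 + n_m1_dmso + n_m1_tsa + max(compounds_per_plate) <= 384)
  if (nrow(hits) && (any(hits$compound < 1) || any(hits$compound > n_cmpd))) {
    abort("planted hit slots exceed the number of compound wells",
          class = "seapscreen_config_error")
  }
  if (nrow(cytotoxics) &&
      (any(cytotoxics$compound < 1) || any(cytotoxics$compound > n_cmpd))) {
    abort("planted cytotoxic slots exceed the number of compound wells",
          class = "seapscreen_config_error")
  }
  if (length(intersect(hits$compound, cytotoxics$compound))) {
    abort("hit and cytotoxic slots overlap; compose effects explicitly instead",
          class = "seapscreen_config_error")
  }
  if (nrow(hits)) stopifnot(all(hits$effect > 0))

  structure(
    list(n_plates = n_plates, n_m0 = n_m0, n_m1_dmso = n_m1_dmso,
         n_m1_tsa = n_m1_tsa, compounds_per_plate = compounds_per_plate,
         libraries = libraries, reads = reads, base_rlu = base_rlu,
         m1_multiplier = m1_multiplier, tsa_multiplier = tsa_multiplier,
         read_scale = read_scale, control_cv = control_cv,
         viability_base = viability_base, viability_cv = viability_cv,
         hits = hits, cytotoxics = cytotoxics, seed = as.integer(seed)),
    class = "screen_sim_config")
}

#' Simulate a truth-labelled reporter screen
#'
#' Draws a full screen dataset under the configured generative model:
#' well signal = read scale x role multiplier x compound effect x
#' mean-one log-normal noise at the configured per-read CV, with reads
#' coupled only through the shared true effect (measurement noise is
#' independent across reads). Viability is emitted for read 2 as the
#' healthy-well mean times the compound's viability fraction times
#' log-normal noise. The same config and seed give bit-identical output.
#'
#' @param config A [screen_sim_config()].
#' @return A list with elements `dataset` (a [screen_dataset()]) and
#'   `truth` (tibble: `compound_id`, `library`, `plate_id`, `well`,
#'   `effect`, `cytotoxic`, `viability_fraction`, `signal_fraction`).
#' @export
simulate_screen <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  withr::with_seed(config$seed, .simulate_screen_impl(config))
}

.simulate_screen_impl <- function(cfg) {
  n_cmpd_total <- sum(cfg$compounds_per_plate)
  compound_ids <- sprintf("C%04d", seq_len(n_cmpd_total))
  effect <- rep(1, n_cmpd_total)
  effect[cfg$hits$compound] <- cfg$hits$effect
  viab_frac <- rep(1, n_cmpd_total)
  sig_frac <- rep(1, n_cmpd_total)
  viab_frac[cfg$cytotoxics$compound] <- cfg$cytotoxics$viability_fraction
  sig_frac[cfg$cytotoxics$compound] <- cfg$cytotoxics$signal_fraction

  # column-major well order: A1..P1, A2..P2, ...
  all_wells <- as.vector(outer(LETTERS[1:16], 1:24,
                               function(r, c) paste0(r, c)))
  offset <- 0L
  layouts <- vector("list", cfg$n_plates)
  for (p in seq_len(cfg$n_plates)) {
    n_c <- cfg$compounds_per_plate[p]
    roles <- c(rep("M0", cfg$n_m0), rep("M1_DMSO", cfg$n_m1_dmso),
               rep("M1_TSA", cfg$n_m1_tsa), rep("COMPOUND", n_c))
    roles <- c(roles, rep("EMPTY", 384 - length(roles)))
    ids <- rep(NA_character_, 384)
    ids[roles == "COMPOUND"] <- compound_ids[offset + seq_len(n_c)]
    layouts[[p]] <- tibble::tibble(
      plate_id = sprintf("P%d", p), well = all_wells, role = roles,
      compound_id = ids)
    offset <- offset + n_c
  }
  layout <- dplyr::bind_rows(layouts) |>
    dplyr::filter(.data$role != "EMPTY")

  plate_lib <- setNames(cfg$libraries, sprintf("P%d", seq_len(cfg$n_plates)))
  registry <- layout |>
    dplyr::filter(.data$role == "COMPOUND") |>
    dplyr::transmute(compound_id = .data$compound_id,
                     library = plate_lib[.data$plate_id]) |>
    dplyr::arrange(.data$compound_id)

  eff_lookup <- setNames(effect, compound_ids)
  sig_lookup <- setNames(sig_frac, compound_ids)
  viab_lookup <- setNames(viab_frac, compound_ids)
  role_mult <- c(M0 = 1, M1_DMSO = cfg$m1_multiplier,
                 M1_TSA = cfg$m1_multiplier * cfg$tsa_multiplier,
                 COMPOUND = cfg$m1_multiplier)

  reads <- purrr::map_dfr(seq_len(cfg$reads), function(r) {
    base <- cfg$base_rlu * cfg$read_scale[r]
    mu <- base * role_mult[layout$role]
    is_cmpd <- layout$role == "COMPOUND"
    mu[is_cmpd] <- mu[is_cmpd] * eff_lookup[layout$compound_id[is_cmpd]] *
      sig_lookup[layout$compound_id[is_cmpd]]
    rlu <- mu * .rlnorm_mean1(nrow(layout), cfg$control_cv[r])
    viability <- rep(NA_real_, nrow(layout))
    if (r == 2L) {
      vf <- rep(1, nrow(layout))
      vf[is_cmpd] <- viab_lookup[layout$compound_id[is_cmpd]]
      viability <- cfg$viability_base * vf *
        .rlnorm_mean1(nrow(layout), cfg$viability_cv)
    }
    tibble::tibble(plate_id = layout$plate_id, read = r,
                   well = layout$well, rlu = rlu, viability = viability)
  })

  truth <- layout |>
    dplyr::filter(.data$role == "COMPOUND") |>
    dplyr::transmute(
      compound_id = .data$compound_id,
      library = plate_lib[.data$plate_id],
      plate_id = .data$plate_id, well = .data$well,
      effect = unname(eff_lookup[.data$compound_id]),
      cytotoxic = .data$compound_id %in%
        compound_ids[cfg$cytotoxics$compound],
      viability_fraction = unname(viab_lookup[.data$compound_id]),
      signal_fraction = unname(sig_lookup[.data$compound_id]))

  list(dataset = screen_dataset(layout, reads, registry), truth = truth)
}

#' Simulate a dilution series with background
#'
#' Level mean = `base_signal / factor + background`, with multiplicative
#' log-normal noise; the negative control is background-only. The truth
#' (base signal and background) is returned so linearity handling of
#' background-limited levels can be scored exactly.
#'
#' @param base_signal Undiluted mean signal (RLU).
#' @param n_decades Number of 10-fold dilution levels (>= 3), starting at
#'   undiluted (factor 1).
#' @param n_replicates Replicates per level.
#' @param cv Multiplicative noise CV per well.
#' @param background Mean background signal added to every level and
#'   measured alone as the negative control.
#' @param seed Integer RNG seed.
#' @return List with `dilution_factors`, `replicates` (list of numeric
#'   vectors), `negative_control`, and `truth = list(base_signal,
#'   background)`.
#' @export
simulate_dilution_series <- function(base_signal = 1e6, n_decades = 5,
                                     n_replicates = 3, cv = 0.05,
                                     background = 50, seed = 1L) {
  stopifnot(n_decades >= 3, base_signal > 0, background >= 0, cv >= 0)
  withr::with_seed(as.integer(seed), {
    factors <- 10^(seq_len(n_decades) - 1)
    reps <- lapply(factors, function(f) {
      (base_signal / f + background) * .rlnorm_mean1(n_replicates, cv)
    })
    neg <- background * .rlnorm_mean1(n_replicates, max(cv, 0.05))
    list(dilution_factors = factors, replicates = reps,
         negative_control = neg,
         truth = list(base_signal = base_signal, background = background))
  })
}

#' Configuration for a simulated qPCR experiment
#'
#' Describes a ddCt-style experiment: a reference gene with a fixed
#' baseline Ct, target genes with baseline dCt offsets, per-condition true
#' fold changes versus the calibrator condition, biological noise at the
#' (experiment, condition) level, and technical well noise. The default
#' panel mirrors an inflammation reporter study: reporter and endogenous
#' target genes plus strongly induced cytokine/chemokine genes under a
#' stimulated solvent condition and two suppressive compound treatments.
#'
#' @param truth Tibble with columns `condition`, `gene`, `true_fold`
#'   (fold versus the control condition; the control itself is implied at
#'   fold 1).
#' @param baseline_dct Named numeric vector: each gene's dCt versus the
#'   reference in the control condition.
#' @param control Control (calibrator) condition label.
#' @param reference_gene Reference gene name.
#' @param ref_baseline_ct Mean reference-gene Ct.
#' @param sigma_tech Technical (well-to-well) Ct noise SD in cycles,
#'   applied independently to every technical replicate of every gene.
#' @param sigma_bio Biological ΔCt noise SD in cycles, applied per
#'   (experiment, condition, gene) to target genes.
#' @param sigma_ref_bio Biological noise SD of the reference-gene level
#'   per (experiment, condition); cancels in dCt.
#' @param n_tech Technical replicates per sample.
#' @param n_bio Biological replicates (independent experiments).
#' @param seed Integer RNG seed.
#' @return A list of class `ct_sim_config`.
#' @export
ct_sim_config <- function(truth = NULL,
                          baseline_dct = c(CEBPD_SEAP = 6, CEBPD = 5,
                                           IL6 = 12, CCL2 = 8, IL1B = 9),
                          control = "M0",
                          reference_gene = "RPL37A",
                          ref_baseline_ct = 20,
                          sigma_tech = 0.2,
                          sigma_bio = 0.25,
                          sigma_ref_bio = 0.3,
                          n_tech = 3, n_bio = 3,
                          seed = 1L) {
  if (is.null(truth)) {
    truth <- tibble::tibble(
      condition = rep(c("M1_DMSO", "M1_TSA", "M1_SAHA"), each = 5),
      gene = rep(c("CEBPD_SEAP", "CEBPD", "IL6", "CCL2", "IL1B"), 3),
      true_fold = c(4.5, 6.1, 7617, 114.9, 374.3,
                    6.4, 0.9, 58.1, 6.8, 492.5,
                    6.8, 1.1, 68.7, 7.6, 501.9))
  }
  truth <- tibble::as_tibble(truth)
  stopifnot(all(truth$true_fold > 0), sigma_tech >= 0, sigma_bio >= 0,
            sigma_ref_bio >= 0, n_tech >= 1, n_bio >= 1,
            all(truth$gene %in% names(baseline_dct)))
  structure(
    list(truth = truth, baseline_dct = baseline_dct, control = control,
         reference_gene = reference_gene, ref_baseline_ct = ref_baseline_ct,
         sigma_tech = sigma_tech, sigma_bio = sigma_bio,
         sigma_ref_bio = sigma_ref_bio, n_tech = n_tech, n_bio = n_bio,
         seed = as.integer(seed)),
    class = "ct_sim_config")
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Per (experiment, condition): the reference level is
#' `ref_baseline_ct + N(0, sigma_ref_bio)`; a target gene's level is the
#' reference level plus its baseline dCt minus log2 of the condition's
#' true fold, plus gene-level biological noise; each technical replicate
#' then adds independent technical noise. With all noise SDs at zero the
#' ddCt pipeline recovers every true fold exactly.
#'
#' @param config A [ct_sim_config()].
#' @return List with `records` (tibble `experiment_id`, `condition`,
#'   `gene`, `ct` — one row per technical replicate) and `truth`.
#' @export
simulate_ct_experiment <- function(config = ct_sim_config()) {
  stopifnot(inherits(config, "ct_sim_config"))
  withr::with_seed(config$seed, .simulate_ct_impl(config))
}

.simulate_ct_impl <- function(cfg) {
  conditions <- c(cfg$control, setdiff(unique(cfg$truth$condition),
                                       cfg$control))
  genes <- names(cfg$baseline_dct)
  fold_of <- function(cond, gene) {
    if (cond == cfg$control) return(1)
    hit <- cfg$truth$true_fold[cfg$truth$condition == cond &
                                 cfg$truth$gene == gene]
    if (length(hit) == 1) hit else 1
  }
  rows <- list()
  for (e in seq_len(cfg$n_bio)) {
    for (cond in conditions) {
      ref_level <- cfg$ref_baseline_ct + stats::rnorm(1, 0, cfg$sigma_ref_bio)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        experiment_id = sprintf("E%d", e), condition = cond,
        gene = cfg$reference_gene,
        ct = ref_level + stats::rnorm(cfg$n_tech, 0, cfg$sigma_tech))
      for (g in genes) {
        level <- ref_level + cfg$baseline_dct[[g]] -
          log2(fold_of(cond, g)) + stats::rnorm(1, 0, cfg$sigma_bio)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          experiment_id = sprintf("E%d", e), condition = cond, gene = g,
          ct = level + stats::rnorm(cfg$n_tech, 0, cfg$sigma_tech))
      }
    }
  }
  list(records = dplyr::bind_rows(rows), truth = cfg$truth)
}
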