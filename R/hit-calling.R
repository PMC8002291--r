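#' Per-plate, per-read control statistics
#'
#' Computes the mean `m`, sample SD and well count of a control role
#' separately for every (plate, read) pair — thresholds are never pooled
#' across plates or reads. Non-finite control signals are excluded with a
#' warning.
#'
#' @param dataset A [screen_dataset()].
#' @param role Control role to summarise (default the solvent control
#'   `"M1_DMSO"`, the role that defines hit thresholds).
#' @return Tibble with columns `plate_id`, `read`, `role`, `m`, `sd`, `n`.
#' @export
summarize_controls <- function(dataset, role = "M1_DMSO") {
  stopifnot(inherits(dataset, "screen_dataset"), role %in% .roles)
  wells <- dataset$layout |>
    dplyr::filter(.data$role == !!role) |>
    dplyr::select("plate_id", "well")
  ctrl <- dataset$signals |>
    dplyr::inner_join(wells, by = c("plate_id", "well"))
  n_bad <- sum(!is.finite(ctrl$rlu))
  if (n_bad > 0) {
    warn(sprintf("excluding %d non-finite %s control signal(s)", n_bad, role))
    ctrl <- ctrl[is.finite(ctrl$rlu), , drop = FALSE]
  }
  out <- ctrl |>
    dplyr::group_by(.data$plate_id, .data$read) |>
    dplyr::summarise(m = mean(.data$rlu), sd = stats::sd(.data$rlu),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(role = role, .after = "read")
  short <- out |> dplyr::filter(.data$n < 2)
  have <- dplyr::distinct(dataset$signals, .data$plate_id, .data$read) |>
    dplyr::anti_join(out, by = c("plate_id", "read"))
  if (nrow(short) || nrow(have)) {
    abort(sprintf("fewer than 2 usable %s control wells on plate/read: %s", role,
                  paste(c(paste(short$plate_id, short$read),
                          paste(have$plate_id, have$read)), collapse = "; ")),
          class = "seapscreen_insufficient_controls")
  }
  out
}

#' Hit thresholds from control statistics
#'
#' Adds `upper = m + k * sd` and `lower = m - k * sd` to a control summary.
#' `k = 3` reproduces the conventional mean-plus-three-SD rule.
#'
#' @param summary A control summary from [summarize_controls()].
#' @param k Non-negative SD multiplier.
#' @return The summary tibble with `k`, `upper`, `lower` columns.
#' @export
activation_threshold <- function(summary, k = 3) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0) {
    abort("k must be a single non-negative number",
          class = "seapscreen_domain_error")
  }
  dplyr::mutate(tibble::as_tibble(summary), k = k,
                upper = .data$m + k * .data$sd,
                lower = .data$m - k * .data$sd)
}

#' Call a single compound against per-read thresholds
#'
#' Exceedance is strict: an activator exceeds a read iff its signal is
#' strictly greater than that read's upper threshold (an inhibitor iff
#' strictly below the lower threshold); a signal exactly at the threshold
#' is not a hit. The compound is a hit iff it exceeds in every configured
#' read; if any configured read is missing the call is `"incomplete"`.
#'
#' @param signals Named numeric vector of per-read signals (names are read
#'   indices).
#' @param thresholds Tibble with columns `read`, `upper`, `lower`.
#' @param direction `"activator"` or `"inhibitor"`.
#' @param reads Integer vector of configured read indices (defaults to the
#'   reads present in `thresholds`).
#' @return One-row tibble: `status` (`"hit"`, `"no_hit"`, `"incomplete"`),
#'   `n_reads`, `n_exceeded`, plus a list-column `per_read` detailing each
#'   read's signal, threshold and exceedance flag.
#' @export
call_compound <- function(signals, thresholds,
                          direction = c("activator", "inhibitor"),
                          reads = NULL) {
  direction <- match.arg(direction)
  thresholds <- tibble::as_tibble(thresholds)
  if (is.null(reads)) reads <- sort(unique(thresholds$read))
  per <- tibble::tibble(read = as.integer(reads)) |>
    dplyr::left_join(thresholds, by = "read") |>
    dplyr::mutate(
      signal = as.numeric(signals[as.character(.data$read)]),
      exceeded = if (direction == "activator") .data$signal > .data$upper
                 else .data$signal < .data$lower
    )
  status <- if (anyNA(per$signal)) "incomplete"
            else if (all(per$exceeded)) "hit" else "no_hit"
  tibble::tibble(status = status, n_reads = sum(!is.na(per$signal)),
                 n_exceeded = sum(per$exceeded, na.rm = TRUE),
                 per_read = list(per))
}

#' Call hits across a whole screen
#'
#' Applies the per-plate, per-read mean + k*SD rule with dual-read (more
#' generally, all-read) concordance: for every compound well, the signal in
#' each read is compared with that plate and read's solvent-control
#' threshold, and a compound is a hit only if it exceeds strictly in every
#' configured read. Hit calling on the inhibitor side is supported but
#' emits a warning: with high control variability the lower threshold can
#' sit near or below zero signal, so inhibitor calls from this rule are
#' weakly powered.
#'
#' @inheritParams summarize_controls
#' @param k SD multiplier for [activation_threshold()].
#' @param direction `"activator"` (default) or `"inhibitor"`.
#' @return Tibble with one row per compound, ordered by (library, plate,
#'   well): `compound_id`, `library`, `plate_id`, `well`, `n_reads`,
#'   `n_exceeded`, `status`, `direction`. Attributes: `per_read` (long
#'   per-compound, per-read signals and thresholds), `thresholds`,
#'   `qc` (per-plate control QC from [screen_qc()]), `counts` (status
#'   tally) and `k`.
#' @export
call_screen <- function(dataset, k = 3,
                        direction = c("activator", "inhibitor")) {
  direction <- match.arg(direction)
  if (direction == "inhibitor") {
    warn(paste("inhibitor calling requested: with noisy controls the",
               "mean - k*SD threshold has limited power to identify",
               "inhibitory compounds; interpret with caution"))
  }
  thr <- activation_threshold(summarize_controls(dataset, "M1_DMSO"), k)
  reads <- sort(unique(dataset$signals$read))

  cmpd_wells <- dataset$layout |>
    dplyr::filter(.data$role == "COMPOUND") |>
    dplyr::select("plate_id", "well", "compound_id") |>
    dplyr::left_join(dataset$registry, by = "compound_id")

  grid <- tidyr::crossing(cmpd_wells, read = reads) |>
    dplyr::left_join(dplyr::select(dataset$signals, "plate_id", "read",
                                   "well", "rlu"),
                     by = c("plate_id", "read", "well")) |>
    dplyr::left_join(dplyr::select(thr, "plate_id", "read", "upper", "lower"),
                     by = c("plate_id", "read")) |>
    dplyr::mutate(exceeded = if (direction == "activator")
                               .data$rlu > .data$upper
                             else .data$rlu < .data$lower)

  calls <- grid |>
    dplyr::group_by(.data$compound_id, .data$library, .data$plate_id,
                    .data$well) |>
    dplyr::summarise(
      n_reads = sum(is.finite(.data$rlu)),
      n_exceeded = sum(.data$exceeded, na.rm = TRUE),
      status = dplyr::case_when(
        sum(is.finite(rlu)) < length(reads) ~ "incomplete",
        all(exceeded) ~ "hit",
        TRUE ~ "no_hit"),
      .groups = "drop") |>
    dplyr::mutate(direction = direction) |>
    dplyr::arrange(.data$library, .data$plate_id, .data$well)

  attr(calls, "per_read") <- dplyr::arrange(grid, .data$library,
                                            .data$plate_id, .data$well,
                                            .data$read)
  attr(calls, "thresholds") <- thr
  attr(calls, "qc") <- screen_qc(dataset)
  attr(calls, "counts") <- table(calls$status)
  attr(calls, "k") <- k
  calls
}

#' Per-plate screen quality control
#'
#' For every (plate, read): the CV of each control role with at least two
#' wells, and the Z'-factor between the M0 background and M1 solvent
#' controls. A negative Z' (overlapping control distributions) triggers a
#' logged robustness message, not a failure — screens in this noise regime
#' remain analysable on the activator side.
#'
#' @inheritParams summarize_controls
#' @return Tibble with columns `plate_id`, `read`, `cv_m0`, `cv_m1_dmso`,
#'   `cv_m1_tsa`, `z_prime` (`NA` where a role is absent).
#' @export
screen_qc <- function(dataset) {
  stopifnot(inherits(dataset, "screen_dataset"))
  sig <- dataset$signals |>
    dplyr::left_join(dataset$layout, by = c("plate_id", "well"))
  per_role_cv <- function(v) {
    if (sum(is.finite(v)) >= 2 && mean(v, na.rm = TRUE) > 0)
      intra_assay_cv(v[is.finite(v)]) else NA_real_
  }
  qc <- sig |>
    dplyr::group_by(.data$plate_id, .data$read) |>
    dplyr::summarise(
      cv_m0 = per_role_cv(.data$rlu[.data$role == "M0"]),
      cv_m1_dmso = per_role_cv(.data$rlu[.data$role == "M1_DMSO"]),
      cv_m1_tsa = per_role_cv(.data$rlu[.data$role == "M1_TSA"]),
      z_prime = {
        m0 <- .data$rlu[.data$role == "M0" & is.finite(.data$rlu)]
        m1 <- .data$rlu[.data$role == "M1_DMSO" & is.finite(.data$rlu)]
        if (length(m0) >= 2 && length(m1) >= 2 && mean(m0) != mean(m1))
          z_factor(m1, m0) else NA_real_
      },
      .groups = "drop")
  neg <- qc |> dplyr::filter(!is.na(.data$z_prime) & .data$z_prime < 0)
  if (nrow(neg)) {
    inform(sprintf(
      "negative Z'-factor on %d plate/read pair(s) (min %.2f): control distributions overlap; activator calls remain usable, inhibitor calls are unreliable",
      nrow(neg), min(neg$z_prime)))
  }
  qc
}

#' Flag hit calls confounded by cytotoxicity
#'
#' Joins a viability counterscreen (measured in one read, conventionally
#' read 2) onto a hit-call table. Relative viability is the compound
#' well's viability signal divided by the plate's solvent-control
#' viability mean. Flags:
#' \describe{
#'   \item{`reduced_viability`}{relative viability below `cutoff`; an
#'     activator hit keeps its hit status but carries the flag.}
#'   \item{`viability_confounded`}{relative viability below `cutoff` and
#'     reporter signal below the solvent-control mean in the viability
#'     read — the signature of a cytotoxic compound whose apparent signal
#'     drop merely reflects dying cells.}
#'   \item{`unassessed`}{a hit without a viability measurement (warned).}
#'   \item{`none`}{otherwise.}
#' }
#'
#' @param calls Hit-call table from [call_screen()].
#' @param dataset The [screen_dataset()] the calls came from (supplies the
#'   viability signals).
#' @param cutoff Relative-viability cutoff (fraction of the solvent-control
#'   mean; default 0.7).
#' @param viability_read Read index carrying the viability counterscreen.
#' @return `calls` with added columns `relative_viability` and
#'   `viability_flag`; the cutoff is recorded in attribute
#'   `viability_cutoff`.
#' @export
flag_viability <- function(calls, dataset, cutoff = 0.7, viability_read = 2L) {
  stopifnot(inherits(dataset, "screen_dataset"),
            is.numeric(cutoff), cutoff > 0)
  sig <- dataset$signals |>
    dplyr::filter(.data$read == viability_read) |>
    dplyr::left_join(dataset$layout, by = c("plate_id", "well"))
  ctrl <- sig |>
    dplyr::filter(.data$role == "M1_DMSO") |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(viab_ctrl = mean(.data$viability, na.rm = TRUE),
                     m_ctrl = mean(.data$rlu, na.rm = TRUE),
                     .groups = "drop")

  out <- calls |>
    dplyr::left_join(
      dplyr::select(sig, "plate_id", "well", "viability",
                    signal_vread = "rlu"),
      by = c("plate_id", "well")) |>
    dplyr::left_join(ctrl, by = "plate_id") |>
    dplyr::mutate(
      relative_viability = .data$viability / .data$viab_ctrl,
      viability_flag = dplyr::case_when(
        is.na(relative_viability) & status == "hit" ~ "unassessed",
        is.na(relative_viability) ~ "none",
        relative_viability < cutoff & signal_vread < m_ctrl ~
          "viability_confounded",
        relative_viability < cutoff ~ "reduced_viability",
        TRUE ~ "none")) |>
    dplyr::select(-"viability", -"signal_vread", -"viab_ctrl", -"m_ctrl")

  n_un <- sum(out$viability_flag == "unassessed")
  if (n_un > 0) {
    warn(sprintf("%d hit(s) have no viability measurement (flag 'unassessed')",
                 n_un))
  }
  attr(out, "viability_cutoff") <- cutoff
  out
}
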