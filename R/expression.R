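#' Aggregate technical qPCR replicates
#'
#' Averages technical Ct replicates to one mean Ct per
#' (experiment, condition, gene). Ct values must lie in the plausible
#' cycler range (0, 45]; samples with a single technical value are
#' accepted with a warning.
#'
#' @param records Tibble with columns `experiment_id`, `condition`,
#'   `gene`, `ct` (one row per technical replicate).
#' @return Tibble with columns `experiment_id`, `condition`, `gene`,
#'   `ct_mean`, `n_tech`, `ct_sd`.
#' @export
aggregate_technical <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("experiment_id", "condition", "gene", "ct") %in%
                  names(records)))
  if (nrow(records) == 0) abort("empty Ct record table")
  bad <- which(!is.finite(records$ct) | records$ct <= 0 | records$ct > 45)
  if (length(bad)) {
    abort(sprintf("Ct value(s) outside (0, 45]: %s",
                  paste(utils::head(records$ct[bad], 5), collapse = ", ")),
          class = "seapscreen_range_error")
  }
  out <- records |>
    dplyr::group_by(.data$experiment_id, .data$condition, .data$gene) |>
    dplyr::summarise(ct_mean = mean(.data$ct), n_tech = dplyr::n(),
                     ct_sd = stats::sd(.data$ct), .groups = "drop")
  n_single <- sum(out$n_tech == 1)
  if (n_single > 0) {
    warn(sprintf("%d sample(s) have no technical replication", n_single))
  }
  out
}

#' Normalise Ct values to a reference gene
#'
#' Computes `dCt = Ct_mean(gene) - Ct_mean(reference)` within each
#' (experiment, condition). The reference gene's own rows yield exactly 0.
#'
#' @param ct_means Output of [aggregate_technical()].
#' @param reference_gene Reference (housekeeping) gene identifier,
#'   e.g. `"RPL37A"`.
#' @return Tibble with columns `experiment_id`, `condition`, `gene`,
#'   `delta_ct`.
#' @export
delta_ct <- function(ct_means, reference_gene = "RPL37A") {
  ct_means <- tibble::as_tibble(ct_means)
  ref <- ct_means |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("experiment_id", "condition", ref_ct = "ct_mean")
  out <- ct_means |>
    dplyr::left_join(ref, by = c("experiment_id", "condition"))
  missing <- out |> dplyr::filter(is.na(.data$ref_ct))
  if (nrow(missing)) {
    abort(sprintf("reference gene '%s' not measured for: %s", reference_gene,
                  paste(utils::head(unique(paste(missing$experiment_id,
                                                 missing$condition)), 5),
                        collapse = "; ")),
          class = "seapscreen_missing_reference")
  }
  out |>
    dplyr::transmute(.data$experiment_id, .data$condition, .data$gene,
                     delta_ct = .data$ct_mean - .data$ref_ct)
}

#' Relative expression as 2^-ddCt fold changes
#'
#' For every gene and condition, each biological replicate's fold change is
#' `2^-(dCt_replicate - mean dCt of the control condition)`; the summary is
#' the mean and sample SD of those per-replicate folds, matching the
#' "mean fold +/- SD" convention of relative-quantification tables. The
#' control condition is summarised the same way against its own mean, so
#' its mean fold is ~1 (exactly 1 when its replicates agree).
#'
#' @param dct Output of [delta_ct()].
#' @param control Condition label of the calibrator group (default
#'   `"M0"`, the unstimulated state).
#' @return Tibble with columns `gene`, `condition`, `fold_mean`,
#'   `fold_sd`, `n`; per-replicate folds in attribute `per_replicate`.
#' @export
fold_change <- function(dct, control = "M0") {
  dct <- tibble::as_tibble(dct)
  if (!control %in% dct$condition) {
    abort(sprintf("control condition '%s' absent from data", control))
  }
  ctrl_mean <- dct |>
    dplyr::filter(.data$condition == control) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(ctrl_dct = mean(.data$delta_ct), .groups = "drop")

  per <- dct |>
    dplyr::inner_join(ctrl_mean, by = "gene") |>
    dplyr::mutate(fold = 2^(-(.data$delta_ct - .data$ctrl_dct)))
  out <- per |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(fold_mean = mean(.data$fold),
                     fold_sd = stats::sd(.data$fold),
                     n = dplyr::n(), .groups = "drop")
  attr(out, "per_replicate") <-
    dplyr::select(per, "experiment_id", "condition", "gene", "fold")
  attr(out, "control") <- control
  out
}

#' Fold-suppression (or further-activation) ratio
#'
#' Ratio of the vehicle-control mean fold change to the compound-treated
#' mean fold change for one gene: values above 1 quantify suppression by
#' the compound ("the compound reduced expression x-fold"), values below 1
#' further activation.
#'
#' @param fold_control Mean fold change of the vehicle (e.g. M1 DMSO)
#'   condition.
#' @param fold_treated Mean fold change of the compound-treated condition
#'   (must be positive).
#' @return The ratio (positive scalar).
#' @examples
#' suppression_ratio(7617.0, 68.7) # ~110.9
#' @export
suppression_ratio <- function(fold_control, fold_treated) {
  stopifnot(is.numeric(fold_control), is.numeric(fold_treated))
  if (any(fold_treated <= 0)) {
    abort("treated fold change must be positive",
          class = "seapscreen_domain_error")
  }
  fold_control / fold_treated
}
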