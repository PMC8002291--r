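#' Coefficient of variation of a replicate set
#'
#' `intra_assay_cv()` measures within-run variability over technical
#' replicates of one sample; `inter_assay_cv()` measures between-run
#' variability over biological-replicate (per-experiment) means. Both are
#' 100 * SD / mean with the sample (n - 1) standard deviation, so the two
#' functions differ only in what the caller feeds them.
#'
#' @param values Numeric vector of replicate measurements (RLU) for
#'   `intra_assay_cv()`, or of per-experiment means for `inter_assay_cv()`.
#' @return The CV in percent (non-negative scalar).
#' @examples
#' intra_assay_cv(c(8, 12)) # 28.28
#' inter_assay_cv(c(90, 110)) # 14.14
#' @export
intra_assay_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values)) {
    abort("CV needs at least 2 finite replicate values",
          class = "seapscreen_undefined_statistic")
  }
  m <- mean(values)
  if (m <= 0) {
    abort("CV is undefined for non-positive mean signal",
          class = "seapscreen_undefined_statistic")
  }
  100 * stats::sd(values) / m
}

#' @rdname intra_assay_cv
#' @export
inter_assay_cv <- function(values) intra_assay_cv(values)

#' Z'-factor screening-window statistic
#'
#' `Z' = 1 - 3 * (SD_sample + SD_negative) / |mean_sample - mean_negative|`,
#' computed with sample (n - 1) standard deviations. Z' is at most 1
#' (reached only when both SDs are zero), is conventionally called optimal
#' at >= 0.5, and can be arbitrarily negative when the sample and control
#' distributions overlap.
#'
#' @param sample,negative Numeric vectors of signal for the positive sample
#'   and the negative control (each needs >= 2 values).
#' @return The Z'-factor (scalar <= 1).
#' @examples
#' z_factor(c(9, 10, 11), c(1, 2, 3)) # 0.25
#' @export
z_factor <- function(sample, negative) {
  sample <- as.numeric(sample); negative <- as.numeric(negative)
  if (length(sample) < 2 || length(negative) < 2 ||
      anyNA(sample) || anyNA(negative)) {
    abort("Z'-factor needs at least 2 finite values in each set",
          class = "seapscreen_undefined_statistic")
  }
  sep <- abs(mean(sample) - mean(negative))
  if (sep == 0) {
    abort("Z'-factor is undefined when sample and control means are equal",
          class = "seapscreen_undefined_statistic")
  }
  1 - 3 * (stats::sd(sample) + stats::sd(negative)) / sep
}

#' Dilution-series linearity and sensitivity
#'
#' Fits ordinary least squares of log10(mean signal) on
#' log10(1 / dilution factor), the concentration surrogate, so a perfectly
#' linear assay has slope +1. Levels whose mean signal is indistinguishable
#' from the negative control (mean <= control mean + 2 * control SD) are
#' excluded from the fit and reported; each level also gets a Z'-factor
#' against the negative control as a per-level sensitivity measure.
#'
#' @param dilution_factors Strictly increasing positive dilution factors
#'   (1 = undiluted, 10, 100, ...).
#' @param replicates List of numeric replicate vectors, one per factor.
#' @param negative_control Numeric vector of background signal replicates.
#' @return A list of class `dilution_fit`: `r_squared`, `slope`,
#'   `levels` (tibble with per-level mean, SD, Z', and `excluded` flag),
#'   `n_used`, and `dynamic_range_decades` (decades spanned by usable
#'   levels).
#' @export
dilution_linearity <- function(dilution_factors, replicates, negative_control) {
  stopifnot(length(dilution_factors) == length(replicates),
            all(dilution_factors > 0))
  if (is.unsorted(dilution_factors, strictly = TRUE)) {
    abort("dilution factors must be strictly increasing")
  }
  if (length(negative_control) < 2) {
    abort("negative control needs >= 2 replicate values")
  }
  bg_mean <- mean(negative_control)
  bg_sd <- stats::sd(negative_control)

  lv <- tibble::tibble(
    dilution_factor = dilution_factors,
    mean = vapply(replicates, mean, numeric(1)),
    sd = vapply(replicates, stats::sd, numeric(1)),
    n = lengths(replicates)
  )
  if (length(unique(lv$n)) > 1) {
    warn("unequal replicate counts across dilution levels")
  }
  lv$z_prime <- vapply(replicates, function(v) {
    if (length(v) >= 2 && mean(v) != bg_mean) z_factor(v, negative_control)
    else NA_real_
  }, numeric(1))
  lv$excluded <- lv$mean <= bg_mean + 2 * bg_sd

  usable <- !lv$excluded
  if (sum(usable) < 3) {
    abort(sprintf("only %d usable dilution level(s) above background; >= 3 needed",
                  sum(usable)),
          class = "seapscreen_insufficient_data")
  }
  fit <- stats::lm(log10(mean) ~ I(-log10(dilution_factor)), data = lv[usable, ])
  # noiseless series fit exactly; lm's perfect-fit warning is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(r_squared = r2,
         slope = unname(stats::coef(fit)[2]),
         levels = lv,
         n_used = sum(usable),
         dynamic_range_decades =
           diff(range(log10(lv$dilution_factor[usable])))),
    class = "dilution_fit"
  )
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf(
    "<dilution_fit> R^2 = %.4f, slope = %.4f over %d levels (%g decades); %d excluded at background\n",
    x$r_squared, x$slope, x$n_used, x$dynamic_range_decades,
    sum(x$levels$excluded)))
  invisible(x)
}

#' QC report for a replicate table
#'
#' Convenience wrapper computing intra-assay CVs per sample label and the
#' inter-assay CV over per-label means, from a long replicate table.
#'
#' @param replicates Tibble with columns `label`, `level`
#'   (`"technical"` or `"biological"`) and `value`.
#' @return Tibble with one row per label (`label`, `n`, `mean`, `cv`) and
#'   an `inter_cv` attribute (CV across biological-level labels, `NA` if
#'   fewer than two).
#' @export
qc_report <- function(replicates) {
  replicates <- tibble::as_tibble(replicates)
  stopifnot(all(c("label", "level", "value") %in% names(replicates)))
  per <- replicates |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     cv = intra_assay_cv(.data$value), .groups = "drop")
  bio <- replicates |>
    dplyr::filter(.data$level == "biological") |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  attr(per, "inter_cv") <-
    if (nrow(bio) >= 2) inter_assay_cv(bio$m) else NA_real_
  per
}
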