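#' Reference fold-change table for the hit-compound panel
#'
#' Bundled 2^-ddCt fold-change summaries (mean, SD and number of
#' biological replicates, relative to the unstimulated M0 state) for the
#' BET-inhibitor (I-BET151, Ro 11-1464) and HDAC-inhibitor (SAHA, TSA)
#' panel in LPS + IFN-gamma-stimulated THP-1 reporter macrophages. Each
#' `experiment` block carries its own solvent-control (`M1_DMSO`)
#' condition, so [suppression_ratio()] can be applied within a block —
#' e.g. SAHA suppresses IL-6 about 111-fold relative to solvent.
#'
#' @return Tibble with columns `experiment`, `gene`, `condition`,
#'   `fold_mean`, `fold_sd`, `n`.
#' @examples
#' ref <- reference_fold_changes()
#' il6 <- subset(ref, experiment == "SAHA_TSA" & gene == "IL6")
#' suppression_ratio(il6$fold_mean[il6$condition == "M1_DMSO"],
#'                   il6$fold_mean[il6$condition == "M1_SAHA"])
#' @export
reference_fold_changes <- function() {
  path <- system.file("extdata", "reference_fold_changes.csv",
                      package = "seapscreen", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    experiment = "c", gene = "c", condition = "c",
                    fold_mean = "d", fold_sd = "d", n = "i"))
}
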