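#' Full ddCt analysis of a Ct table
#'
#' Chains [aggregate_technical()], [delta_ct()] and [fold_change()]:
#' technical Ct replicates to mean Ct, normalisation to the reference
#' gene, and 2^-ddCt fold changes versus the control condition.
#'
#' @inheritParams aggregate_technical
#' @inheritParams delta_ct
#' @inheritParams fold_change
#' @return The [fold_change()] summary tibble.
#' @export
analyze_ct <- function(records, reference_gene = "RPL37A", control = "M0") {
  records |>
    aggregate_technical() |>
    delta_ct(reference_gene = reference_gene) |>
    fold_change(control = control)
}

#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run — data source (simulation
#' configs or input file paths), hit-calling parameters, expression
#' parameters, and the master seed — so a run is a pure function of its
#' config. All randomness flows from `seed`: the stage generators receive
#' deterministic sub-seeds derived from it.
#'
#' @param screen_sim A [screen_sim_config()], or `NULL` to load from
#'   files.
#' @param ct_sim A [ct_sim_config()], or `NULL` to skip / load from
#'   files.
#' @param plate_files,manifest_files,ct_file Input paths used when the
#'   corresponding sim config is `NULL`.
#' @param k SD multiplier for hit thresholds.
#' @param direction Hit direction (`"activator"` or `"inhibitor"`).
#' @param viability_cutoff Relative-viability cutoff for
#'   [flag_viability()].
#' @param reference_gene,control_condition Expression-stage parameters.
#' @param seed Master integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(screen_sim = screen_sim_config(),
                       ct_sim = ct_sim_config(),
                       plate_files = NULL, manifest_files = NULL,
                       ct_file = NULL,
                       k = 3, direction = "activator",
                       viability_cutoff = 0.7,
                       reference_gene = "RPL37A",
                       control_condition = "M0",
                       seed = 1L) {
  seed <- as.integer(seed)
  if (!is.null(screen_sim)) {
    stopifnot(inherits(screen_sim, "screen_sim_config"))
    screen_sim$seed <- seed
  }
  if (!is.null(ct_sim)) {
    stopifnot(inherits(ct_sim, "ct_sim_config"))
    ct_sim$seed <- seed + 1L
  }
  structure(
    list(screen_sim = screen_sim, ct_sim = ct_sim,
         plate_files = plate_files, manifest_files = manifest_files,
         ct_file = ct_file, k = k, direction = direction,
         viability_cutoff = viability_cutoff,
         reference_gene = reference_gene,
         control_condition = control_condition, seed = seed),
    class = "run_config")
}

#' Run the whole screen-analysis pipeline
#'
#' Executes simulate/load, per-plate QC, hit calling with viability
#' flagging, and (when Ct data are configured) ddCt quantification with
#' per-gene group comparisons against the solvent control. When
#' `out_dir` is given, all artifacts are written as plain TSV/JSON:
#' `config.json`, `qc.tsv`, `hits.tsv`, `thresholds.tsv`, `folds.tsv`,
#' `comparisons.tsv`, and `truth_*.tsv` for simulated inputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list of class `screen_run_report`: `config`, `qc`, `hits`
#'   (flagged hit-call table), `hit_counts`, `folds`, `comparisons`,
#'   `truth` (screen + ct, for simulated inputs).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$screen_sim)) {
    sim <- simulate_screen(config$screen_sim)
    dataset <- sim$dataset
    screen_truth <- sim$truth
  } else {
    if (is.null(config$plate_files) || is.null(config$manifest_files)) {
      abort("run_config has neither a screen simulation nor input files")
    }
    dataset <- load_screen(config$plate_files, config$manifest_files)
    screen_truth <- NULL
  }

  qc <- screen_qc(dataset)
  calls0 <- call_screen(dataset, k = config$k, direction = config$direction)
  thresholds <- attr(calls0, "thresholds")
  calls <- flag_viability(calls0, dataset, cutoff = config$viability_cutoff)

  folds <- NULL; comparisons <- NULL; ct_truth <- NULL
  ct_records <- NULL
  if (!is.null(config$ct_sim)) {
    ct <- simulate_ct_experiment(config$ct_sim)
    ct_records <- ct$records
    ct_truth <- ct$truth
  } else if (!is.null(config$ct_file)) {
    ct_records <- readr::read_csv(config$ct_file, show_col_types = FALSE)
  }
  if (!is.null(ct_records)) {
    folds <- suppressWarnings(
      analyze_ct(ct_records, reference_gene = config$reference_gene,
                 control = config$control_condition))
    per_rep <- attr(folds, "per_replicate")
    solvent <- "M1_DMSO"
    comparisons <- purrr::map_dfr(unique(per_rep$gene), function(g) {
      sub <- per_rep[per_rep$gene == g &
                       per_rep$condition != config$control_condition, ]
      grp <- split(sub$fold, sub$condition)
      if (length(grp) < 2 || !solvent %in% names(grp) ||
          any(lengths(grp) < 3)) return(NULL)
      res <- tryCatch(
        suppressWarnings(run_comparison(grp, control = solvent)),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      dplyr::mutate(res, gene = g, .before = 1)
    })
  }

  report <- structure(
    list(config = config, qc = qc, hits = calls,
         hit_counts = table(calls$status),
         thresholds = thresholds, folds = folds,
         comparisons = comparisons,
         truth = list(screen = screen_truth, ct = ct_truth)),
    class = "screen_run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_json <- config
    cfg_json$screen_sim <- unclass(cfg_json$screen_sim)
    cfg_json$ct_sim <- unclass(cfg_json$ct_sim)
    jsonlite::write_json(unclass(cfg_json),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    readr::write_tsv(qc, file.path(out_dir, "qc.tsv"), progress = FALSE)
    readr::write_tsv(calls, file.path(out_dir, "hits.tsv"),
                     progress = FALSE)
    readr::write_tsv(thresholds, file.path(out_dir, "thresholds.tsv"),
                     progress = FALSE)
    if (!is.null(folds)) {
      readr::write_tsv(folds, file.path(out_dir, "folds.tsv"),
                       progress = FALSE)
    }
    if (!is.null(comparisons) && nrow(comparisons)) {
      readr::write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"),
                       progress = FALSE)
    }
    if (!is.null(screen_truth)) {
      readr::write_tsv(screen_truth,
                       file.path(out_dir, "truth_screen.tsv"),
                       progress = FALSE)
    }
    if (!is.null(ct_truth)) {
      readr::write_tsv(ct_truth, file.path(out_dir, "truth_ct.tsv"),
                       progress = FALSE)
    }
  }
  report
}

#' @export
print.screen_run_report <- function(x, ...) {
  cat("<screen_run_report>\n")
  cat(sprintf("  plates: %d  (k = %g, direction = %s)\n",
              dplyr::n_distinct(x$qc$plate_id), x$config$k,
              x$config$direction))
  cat("  hit calls:", paste(names(x$hit_counts), as.integer(x$hit_counts),
                            sep = "=", collapse = ", "), "\n")
  zp <- x$qc$z_prime[!is.na(x$qc$z_prime)]
  if (length(zp)) {
    cat(sprintf("  per-plate Z' (M0 vs M1_DMSO): %.2f to %.2f\n",
                min(zp), max(zp)))
  }
  if (!is.null(x$folds)) {
    cat(sprintf("  expression: %d gene/condition fold summaries\n",
                nrow(x$folds)))
  }
  invisible(x)
}
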