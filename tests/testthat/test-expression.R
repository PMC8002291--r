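test_that("technical Ct replicates aggregate to means with range checks", {
  rec <- tibble::tibble(experiment_id = "E1", condition = "M0",
                        gene = "IL6", ct = c(24.9, 25.1))
  agg <- aggregate_technical(rec)
  expect_equal(agg$ct_mean, 25)
  expect_equal(agg$n_tech, 2)

  expect_warning(
    aggregate_technical(dplyr::mutate(rec[1, ], ct = 25.0)),
    "no technical replication")
  expect_error(
    aggregate_technical(dplyr::mutate(rec, ct = c(24, 46))),
    class = "seapscreen_range_error")
  expect_error(aggregate_technical(rec[0, ]), "empty")
})

test_that("delta_ct subtracts the reference gene within each sample", {
  agg <- tibble::tibble(
    experiment_id = "E1",
    condition = c("M1", "M1"),
    gene = c("IL6", "RPL37A"),
    ct_mean = c(25, 20), n_tech = 2, ct_sd = 0)
  dct <- delta_ct(agg, reference_gene = "RPL37A")
  expect_equal(dct$delta_ct[dct$gene == "IL6"], 5)
  # the reference gene against itself is exactly 0
  expect_identical(dct$delta_ct[dct$gene == "RPL37A"], 0)

  expect_error(delta_ct(agg[agg$gene != "RPL37A", ], "RPL37A"),
               class = "seapscreen_missing_reference")
})

test_that("fold_change reproduces the hand-worked 2^-ddCt example", {
  # test: Ct(gene)=25, Ct(ref)=20; M0: Ct(gene)=28, Ct(ref)=20
  # ddCt = 5 - 8 = -3 -> fold 8
  rec <- tibble::tibble(
    experiment_id = "E1",
    condition = rep(c("M1", "M0"), each = 2),
    gene = rep(c("IL6", "RPL37A"), 2),
    ct = c(25, 20, 28, 20))
  fc <- suppressWarnings(analyze_ct(rec, "RPL37A", control = "M0"))
  expect_equal(fc$fold_mean[fc$condition == "M1" & fc$gene == "IL6"], 8)
  # the control's own fold is exactly 1 when its replicates agree
  expect_equal(fc$fold_mean[fc$condition == "M0" & fc$gene == "IL6"], 1)
})

test_that("planted folds are recovered exactly at zero noise", {
  cfg <- ct_sim_config(
    truth = tibble::tibble(condition = "TRT", gene = "G", true_fold = 4),
    baseline_dct = c(G = 5), sigma_tech = 0, sigma_bio = 0,
    sigma_ref_bio = 0, n_tech = 2, n_bio = 3, seed = 2)
  fc <- suppressWarnings(analyze_ct(simulate_ct_experiment(cfg)$records))
  expect_equal(fc$fold_mean[fc$condition == "TRT" & fc$gene == "G"], 4)
  expect_equal(fc$fold_sd[fc$condition == "TRT" & fc$gene == "G"], 0)
})

make_noisy_records <- function(seed) {
  set.seed(seed)
  tidyr::crossing(experiment_id = paste0("E", 1:3),
                  condition = c("M0", "M1"),
                  gene = c("G", "RPL37A"),
                  tech = 1:2) |>
    dplyr::mutate(ct = 20 + (gene == "G") * 5 - (condition == "M1" &
                                                   gene == "G") * 2 +
                    rnorm(dplyr::n(), 0, 0.3)) |>
    dplyr::select(-tech)
}

test_that("fold changes are invariant to a global Ct shift", {
  for (seed in 1:5) {
    rec <- make_noisy_records(seed)
    f1 <- analyze_ct(rec, "RPL37A", "M0")
    rec2 <- dplyr::mutate(rec, ct = ct + 3.7) # shifts every gene incl. reference
    f2 <- analyze_ct(rec2, "RPL37A", "M0")
    expect_equal(f1$fold_mean, f2$fold_mean)
    expect_equal(f1$fold_sd, f2$fold_sd)
  }
})

test_that("one cycle off the target gene in the test group doubles its folds", {
  rec <- make_noisy_records(42)
  f1 <- analyze_ct(rec, "RPL37A", "M0")
  rec2 <- dplyr::mutate(rec, ct = ct - (gene == "G" & condition == "M1"))
  f2 <- analyze_ct(rec2, "RPL37A", "M0")
  r1 <- attr(f1, "per_replicate"); r2 <- attr(f2, "per_replicate")
  m1 <- r1$fold[r1$condition == "M1" & r1$gene == "G"]
  m2 <- r2$fold[r2$condition == "M1" & r2$gene == "G"]
  expect_equal(m2, 2 * m1)
})

test_that("suppression ratios reproduce the reference-panel statements", {
  ref <- reference_fold_changes()
  sr <- function(exp, gene, treated) {
    sub <- ref[ref$experiment == exp & ref$gene == gene, ]
    suppression_ratio(sub$fold_mean[sub$condition == "M1_DMSO"],
                      sub$fold_mean[sub$condition == treated])
  }
  expect_equal(sr("SAHA_TSA", "IL6", "M1_SAHA"), 7617.0 / 68.7)
  expect_gt(sr("SAHA_TSA", "IL6", "M1_SAHA"), 110)
  # I-BET151 more than doubles IL-1B (further activation reads as ratio < 1)
  expect_equal(suppression_ratio(927.1, 396.0), 2.341162, tolerance = 1e-6)
  expect_gt(suppression_ratio(927.1, 396.0), 2) # "more than doubled"
  expect_error(suppression_ratio(5, 0), class = "seapscreen_domain_error")
  expect_equal(suppression_ratio(3, 3), 1)
})

test_that("suppression ratios compose over a shared control", {
  a <- 927.1; b <- 396.0; c <- 68.7
  expect_equal(suppression_ratio(a, b) * suppression_ratio(b, c),
               suppression_ratio(a, c))
})

test_that("select_test walks the normality / equal-SD decision tree", {
  # deterministic fixtures: normal quantiles pass Shapiro by construction,
  # their exponential transform fails it; sd scaling drives Levene
  norm_q <- function(n, mean, sd) mean + sd * qnorm(ppoints(n))
  n1 <- norm_q(12, 10, 1); n2 <- norm_q(12, 12, 1)
  wide <- norm_q(15, 10, 20)
  skew <- exp(norm_q(30, 0, 1.5))

  expect_equal(select_test(list(a = n1, b = n2))$test, "t")
  expect_equal(select_test(list(a = norm_q(15, 10, 1), b = wide))$test,
               "welch_t")
  expect_equal(select_test(list(a = n1, b = n2, c = norm_q(12, 9, 1)))$test,
               "anova_dunnett")
  expect_equal(select_test(list(a = norm_q(15, 10, 1), b = wide,
                                c = norm_q(15, 11, 1)))$test,
               "welch_anova_dunnett")
  expect_equal(select_test(list(a = n1, b = n2, c = skew))$test,
               "kruskal_dunn")
  expect_equal(select_test(list(a = n1, b = skew))$test, "wilcoxon")

  expect_error(select_test(list(a = c(1, 2), b = c(3, 4, 5))),
               class = "seapscreen_decision_error")
})

test_that("dunn_test matches an independently computed oracle", {
  groups <- list(A = c(1.2, 2.3, 1.8, 2.9, 3.1),
                 B = c(4.5, 5.1, 3.9, 6.0, 5.5),
                 C = c(2.0, 2.5, 3.0, 2.2, 2.8))
  d <- dunn_test(groups, p_adjust = "holm")
  # frozen from an independent rank-sum computation (SciPy)
  expect_equal(d$z[d$comparison == "A vs B"], -2.7577164, tolerance = 1e-6)
  expect_equal(d$p_unadjusted[d$comparison == "A vs B"], 0.00582067,
               tolerance = 1e-6)
  expect_equal(d$p[d$comparison == "A vs B"], 0.01746200, tolerance = 1e-6)
  expect_equal(d$p[d$comparison == "A vs C"], 0.83200403, tolerance = 1e-6)
  expect_equal(d$p[d$comparison == "B vs C"], 0.02181900, tolerance = 1e-6)
})

test_that("run_comparison reports per-comparison p-values with star bands", {
  expect_identical(significance_stars(c(0.2, 0.03, 0.004, 0.0005, 0.00005)),
                   c("", "*", "**", "***", "****"))

  # degenerate: all values identical -> p = 1, no stars
  expect_warning(
    res <- run_comparison(list(a = c(1, 1, 1), b = c(1, 1, 1))),
    "degenerate")
  expect_equal(res$p, 1)
  expect_identical(res$stars, "")

  groups <- list(A = c(1.2, 2.3, 1.8, 2.9, 3.1),
                 B = c(4.5, 5.1, 3.9, 6.0, 5.5),
                 C = c(2.0, 2.5, 3.0, 2.2, 2.8))
  spec <- structure(list(test = "kruskal_dunn", n_groups = 3),
                    class = "test_spec")
  res <- run_comparison(groups, spec = spec, control = "A")
  expect_equal(attr(res, "omnibus_p"), 0.00900478, tolerance = 1e-6)
  expect_setequal(res$comparison, c("A vs B", "A vs C"))
  expect_equal(res$p[res$comparison == "A vs B"], 0.0116413, tolerance = 1e-5)

  # two-sample branches agree with the base tests they wrap
  set.seed(7)
  g2 <- list(ctl = rnorm(10, 10, 1), trt = rnorm(10, 12, 1))
  spec_t <- structure(list(test = "t", n_groups = 2), class = "test_spec")
  res_t <- run_comparison(g2, spec = spec_t, control = "ctl")
  expect_equal(res_t$p,
               t.test(g2$ctl, g2$trt, var.equal = TRUE)$p.value)

  # Dunnett branch returns one p per treated group, all in (0, 1]
  spec_d <- structure(list(test = "anova_dunnett", n_groups = 3),
                      class = "test_spec")
  res_d <- run_comparison(groups, spec = spec_d, control = "A")
  expect_equal(nrow(res_d), 2)
  expect_true(all(res_d$p > 0 & res_d$p <= 1))
})
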