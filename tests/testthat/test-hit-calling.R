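test_that("summarize_controls computes per-plate, per-read mean and sample SD", {
  ds <- tiny_dataset()
  # override the three solvent wells of read 1 with known values
  ds$signals$rlu[ds$signals$read == 1 &
                   ds$signals$well %in% c("D1", "E1", "F1")] <- c(90, 100, 110)
  ctrl <- summarize_controls(ds)
  r1 <- ctrl[ctrl$read == 1, ]
  expect_equal(r1$m, 100)
  expect_equal(r1$sd, 10)
  expect_equal(r1$n, 3)

  # constant controls give sd 0
  r2 <- ctrl[ctrl$read == 2, ]
  expect_equal(r2$sd, 0)

  # fewer than 2 usable control wells is an error
  ds_bad <- ds
  ds_bad$signals$rlu[ds_bad$signals$read == 2 &
                       ds_bad$signals$well %in% c("D1", "E1")] <- NaN
  expect_warning(
    expect_error(summarize_controls(ds_bad),
                 class = "seapscreen_insufficient_controls"),
    "non-finite")
})

test_that("activation_threshold is m +/- k*sd with k validation", {
  s <- tibble::tibble(plate_id = "P1", read = 1L, role = "M1_DMSO",
                      m = 100, sd = 10, n = 16)
  thr <- activation_threshold(s, k = 3)
  expect_equal(thr$upper, 130)
  expect_equal(thr$lower, 70)
  thr0 <- activation_threshold(s, k = 0)
  expect_equal(thr0$upper, thr0$lower)
  expect_equal(activation_threshold(dplyr::mutate(s, sd = 0), k = 5)$upper, 100)
  expect_error(activation_threshold(s, k = -1),
               class = "seapscreen_domain_error")
})

test_that("call_compound applies the strict dual-read AND rule", {
  thr <- tibble::tibble(read = 1:2, upper = c(130, 130), lower = c(70, 70))
  expect_equal(call_compound(c("1" = 135, "2" = 131), thr)$status, "hit")
  expect_equal(call_compound(c("1" = 135, "2" = 129), thr)$status, "no_hit")
  # a signal exactly at the threshold is NOT a hit (strict >)
  expect_equal(call_compound(c("1" = 130, "2" = 135), thr)$status, "no_hit")
  # missing read -> incomplete
  expect_equal(call_compound(c("1" = 135), thr)$status, "incomplete")
  # inhibitor side uses the lower threshold, strictly
  expect_equal(call_compound(c("1" = 60, "2" = 65), thr,
                             direction = "inhibitor")$status, "hit")
  expect_equal(call_compound(c("1" = 70, "2" = 65), thr,
                             direction = "inhibitor")$status, "no_hit")
})

test_that("call_screen recovers planted activators exactly in a noiseless screen", {
  ds <- tiny_dataset(effects = c(X01 = 5, X02 = 1, X03 = 8, X04 = 1))
  calls <- call_screen(ds, k = 3)
  # zero-variance controls: threshold is exactly m; signals at m do not
  # exceed it (strict >), so only the planted activators are hits
  expect_setequal(calls$compound_id[calls$status == "hit"], c("X01", "X03"))
  expect_equal(calls$status[calls$compound_id == "X02"], "no_hit")
  expect_equal(calls$status[calls$compound_id == "X04"], "no_hit")
})

test_that("a compound measured in one read only is incomplete", {
  ds <- tiny_dataset(effects = c(X01 = 5, X02 = 1))
  ds$signals <- dplyr::filter(ds$signals,
                              !(well == "I1" & read == 2)) # X01's well
  calls <- call_screen(ds, k = 3)
  expect_equal(calls$status[calls$compound_id == "X01"], "incomplete")
})

test_that("hit calls are invariant to compound well placement", {
  cfg <- screen_sim_config(n_plates = 1, compounds_per_plate = 40,
                           hits = tibble::tibble(compound = c(5, 20), effect = 6),
                           cytotoxics = tibble::tibble(compound = integer(),
                                                       viability_fraction = numeric(),
                                                       signal_fraction = numeric()),
                           seed = 21)
  sim <- simulate_screen(cfg)
  calls <- suppressMessages(call_screen(sim$dataset))

  # permute which wells the compounds sit in (signals travel with compounds)
  ds2 <- sim$dataset
  cw <- which(ds2$layout$role == "COMPOUND")
  set.seed(1); perm <- sample(length(cw))
  old_wells <- ds2$layout$well[cw]
  map <- setNames(old_wells[perm], old_wells)
  sig_idx <- ds2$signals$well %in% old_wells
  ds2$signals$well[sig_idx] <- map[ds2$signals$well[sig_idx]]
  ds2$layout$well[cw] <- map[ds2$layout$well[cw]]
  calls2 <- suppressMessages(call_screen(ds2))
  expect_setequal(calls$compound_id[calls$status == "hit"],
                  calls2$compound_id[calls2$status == "hit"])
})

test_that("the hit set shrinks monotonically in k and is read-wise an AND", {
  cfg <- screen_sim_config(n_plates = 2, compounds_per_plate = 60,
                           control_cv = c(0.45, 0.30),
                           hits = tibble::tibble(compound = c(3, 40, 90),
                                                 effect = c(2, 4, 8)),
                           cytotoxics = tibble::tibble(compound = integer(),
                                                       viability_fraction = numeric(),
                                                       signal_fraction = numeric()),
                           seed = 5)
  sim <- simulate_screen(cfg)
  ds <- sim$dataset
  hit_set <- function(k) {
    calls <- suppressMessages(call_screen(ds, k = k))
    calls$compound_id[calls$status == "hit"]
  }
  ks <- c(0, 1, 2, 3, 4)
  sets <- lapply(ks, hit_set)
  for (i in seq_len(length(ks) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }

  # dual-read AND rule: hit set = intersection of single-read hit sets
  calls <- suppressMessages(call_screen(ds, k = 3))
  per_read <- attr(calls, "per_read")
  read_hits <- lapply(split(per_read, per_read$read), function(g) {
    g$compound_id[g$exceeded]
  })
  expect_setequal(calls$compound_id[calls$status == "hit"],
                  Reduce(intersect, read_hits))
})

test_that("thresholds are local to a plate", {
  cfg <- screen_sim_config(n_plates = 2, compounds_per_plate = 30,
                           hits = tibble::tibble(compound = c(2, 35),
                                                 effect = 6),
                           cytotoxics = tibble::tibble(compound = integer(),
                                                       viability_fraction = numeric(),
                                                       signal_fraction = numeric()),
                           seed = 9)
  ds <- simulate_screen(cfg)$dataset
  calls1 <- suppressMessages(call_screen(ds, k = 3))
  # corrupt every signal on plate 2; plate 1 calls must not move
  ds2 <- ds
  idx <- ds2$signals$plate_id == "P2"
  ds2$signals$rlu[idx] <- ds2$signals$rlu[idx] * 40 + 1234
  calls2 <- suppressMessages(call_screen(ds2, k = 3))
  p1 <- function(x) dplyr::filter(x, plate_id == "P1")
  expect_identical(p1(calls1)$status, p1(calls2)$status)
})

test_that("viability flagging distinguishes confounded from merely reduced", {
  viab <- setNames(rep(100, 12), tiny_layout(4)$well)
  # X01 (well I1): strong activator with healthy cells
  # X02 (well J1): cytotoxic - viability 40% and signal below control mean
  # X03 (well K1): activator hit with reduced (60%) viability -> flagged, kept
  viab[c("I1", "J1", "K1", "L1")] <- c(95, 40, 60, 85)
  ds <- tiny_dataset(effects = c(X01 = 5, X02 = 0.3, X03 = 6, X04 = 1.5),
                     viability = viab)
  calls <- call_screen(ds, k = 0) # sd-zero controls; k irrelevant here
  fl <- flag_viability(calls, ds, cutoff = 0.7)

  flag_of <- function(id) fl$viability_flag[fl$compound_id == id]
  expect_equal(flag_of("X02"), "viability_confounded")
  expect_equal(flag_of("X03"), "reduced_viability")
  # hit status retained despite the reduced-viability flag
  expect_equal(fl$status[fl$compound_id == "X03"], "hit")
  expect_equal(flag_of("X01"), "none")
  expect_equal(flag_of("X04"), "none")
  expect_equal(attr(fl, "viability_cutoff"), 0.7)
})

test_that("hits without viability measurements are flagged unassessed", {
  ds <- tiny_dataset(effects = c(X01 = 5, X02 = 1))
  calls <- call_screen(ds, k = 3)
  expect_warning(fl <- flag_viability(calls, ds), "unassessed")
  expect_equal(fl$viability_flag[fl$compound_id == "X01"], "unassessed")
})

test_that("inhibitor calling works but warns about its limited power", {
  ds <- tiny_dataset(effects = c(X01 = 0.1, X02 = 1))
  # give controls some spread so lower threshold is meaningful
  i <- ds$signals$well %in% c("D1", "E1", "F1")
  ds$signals$rlu[i] <- ds$signals$rlu[i] + rep(c(-10, 0, 10), 2)
  expect_warning(calls <- call_screen(ds, k = 3, direction = "inhibitor"),
                 "inhibitor")
  expect_equal(calls$status[calls$compound_id == "X01"], "hit")
})
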