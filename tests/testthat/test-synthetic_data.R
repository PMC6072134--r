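test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_lfq(n_background = 50, n_planted = 5, seed = 2),
                   gen_lfq(n_background = 50, n_planted = 5, seed = 2))
  expect_identical(gen_ct(seed = 3), gen_ct(seed = 3))
  expect_identical(gen_biosort(seed = 4), gen_biosort(seed = 4))
  expect_identical(gen_survival(seed = 5), gen_survival(seed = 5))
  expect_false(identical(gen_ct(seed = 3), gen_ct(seed = 4)))
})

test_that("LFQ missingness is monotone decreasing in the protein's true abundance", {
  sim <- gen_lfq(n_background = 10000, n_planted = 0, seed = 10)
  vals <- as.matrix(sim$table[, sim$design$sample_id])
  prot_mean <- rowMeans(log2(vals), na.rm = TRUE)
  miss_rate <- rowMeans(is.na(vals))
  bins <- cut(prot_mean, stats::quantile(prot_mean, seq(0, 1, 0.2),
                                         na.rm = TRUE),
              include.lowest = TRUE)
  rate_by_bin <- tapply(miss_rate, bins, mean)
  expect_true(all(diff(rate_by_bin) < 0))
  ## near-zero slope makes missingness intensity-independent at rate ~0.5
  flat <- gen_lfq(n_background = 4000, n_planted = 0, mnar_slope = 1e-9,
                  seed = 11)
  fv <- as.matrix(flat$table[, flat$design$sample_id])
  expect_lt(abs(mean(is.na(fv)) - 0.5), 0.02)
})

test_that("gen_lfq honors counts, ids and the structural-missing switch", {
  sim <- gen_lfq(n_background = 20, n_planted = 3,
                 planted_ids = c("X", "Y", "Z"), structural_missing = TRUE,
                 seed = 12)
  expect_equal(nrow(sim$table), 23L)
  expect_equal(sim$truth$planted_ids, c("X", "Y", "Z"))
  ctl <- sim$design$sample_id[sim$design$group == "control"]
  expect_true(all(is.na(sim$table[sim$table$protein_id %in% c("X", "Y", "Z"),
                                  ctl])))
})

test_that("caller recovers planted interactors and stays quiet on nulls", {
  ## power at the study-like design: effect 4 log2, noise 0.5, 3v3
  sim <- gen_lfq(n_background = 500, n_planted = 50, effect_log2 = 4,
                 seed = 13)
  v <- run_apms_pipeline(sim$table, sim$design, seed = 13)
  called <- v$protein_id[v$significant]
  expect_gte(mean(sim$truth$planted_ids %in% called), 0.9)

  ## zero planted effect: indistinguishable from background
  frac <- vapply(1:5, function(s) {
    null <- gen_lfq(n_background = 500, n_planted = 50, effect_log2 = 0,
                    seed = 20 + s)
    mean(run_apms_pipeline(null$table, null$design, seed = 20 + s)$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.01)
})

test_that("gen_ct embeds recoverable folds and is null-calibrated", {
  exact <- gen_ct(induction_folds = 8, targets = "nlp-29", noise_sd = 0,
                  seed = 14)
  folds <- fold_induction_table(exact)
  expect_equal(folds$fold, rep(8, 3), tolerance = 1e-12)
  expect_equal(length(unique(exact$experiment_id)), 3L)

  ## fold = 1 for all targets: one-tailed p roughly uniform over seeds
  ps <- vapply(1:50, function(s) {
    ct <- gen_ct(induction_folds = 1, targets = "t1", seed = 100 + s)
    ratio_paired_t(fold_induction_table(ct)$fold)$p
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 4 * sqrt(1 / 12 / 50))
})

test_that("gen_biosort hits group sizes, ratios, and null/power behaviour", {
  pop <- gen_biosort(groups = list(a = list(n = 17, mean_ratio = 1),
                                   b = list(n = 23, mean_ratio = 3)),
                     seed = 15)
  expect_equal(as.integer(table(pop$group)[c("a", "b")]), c(17L, 23L))
  r <- green_tof_ratio(pop)
  expect_gt(mean(r$ratio[r$group == "b"]), 2 * mean(r$ratio[r$group == "a"]))

  ## equal means: Dunn p roughly uniform over seeds
  ps <- vapply(1:50, function(s) {
    p <- gen_biosort(groups = list(ctl = list(n = 30, mean_ratio = 1),
                                   g = list(n = 30, mean_ratio = 1)),
                     seed = 200 + s)
    kruskal_dunn(green_tof_ratio(p), "ctl",
                 adjust = "none")$comparisons$p_raw
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 4 * sqrt(1 / 12 / 50))

  ## doubled ratio at n = 80 with small dispersion: decisive
  pw <- gen_biosort(groups = list(ctl = list(n = 80, mean_ratio = 1),
                                  g = list(n = 80, mean_ratio = 2)),
                    dispersion = 0.1, seed = 16)
  expect_lt(kruskal_dunn(green_tof_ratio(pw), "ctl")$comparisons$p_adjusted,
            0.001)
})

test_that("gen_survival censors at the horizon and separates doubled hazards", {
  coh <- gen_survival(censor_time = 10, seed = 17)
  expect_true(all(coh$time <= 10))
  expect_true(all(coh$event[coh$time < 10] == 1))

  ## Weibull shape 2: halving scale^shape doubles the hazard everywhere.
  ## With ~100 events the one-sided log-rank power at hazard ratio 2 is
  ## about 0.83 at alpha 0.01 and 0.95 at alpha 0.05 (asymptotic
  ## z = log(2)/sqrt(4/events)); assert accordingly.
  ps <- vapply(1:50, function(s) {
    d <- gen_survival(groups = list(a = list(n = 50, scale = 10, shape = 2),
                                    b = list(n = 50, scale = 10 / sqrt(2),
                                             shape = 2)),
                      censor_time = 25, seed = 300 + s)
    logrank_onesided(d, "a", "b", "b")$p_one_sided
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.9)
  expect_gte(mean(ps < 0.01), 0.7)

  ## equal parameters: two-sided p roughly uniform (KS sanity)
  ps <- vapply(1:200, function(s) {
    d <- gen_survival(groups = list(a = list(n = 30, scale = 8, shape = 2),
                                    b = list(n = 30, scale = 8, shape = 2)),
                      censor_time = 20, seed = 400 + s)
    logrank_onesided(d, "a", "b", "b")$p_two_sided
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
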