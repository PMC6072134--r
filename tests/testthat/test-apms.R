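make_matrix <- function(values, samples = NULL) {
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  dimnames(values) <- list(paste0("P", seq_len(nrow(values))), samples)
  lfq_matrix(values, scale = "raw")
}

design6 <- sample_design(paste0("S", 1:6),
                         c(rep("bait", 3), rep("control", 3)))

test_that("min-valid filter counts presence in bait replicates only", {
  v <- rbind(c(10, 10, NA, NA, NA, NA),   # 2/3 bait, 0/3 control -> keep
             c(10, NA, NA, 10, 10, 10),   # 1/3 bait -> drop
             c(10, 10, 10, 10, 10, 10))   # keep
  m <- make_matrix(v)
  f <- filter_min_valid(m, design6, 2L)
  expect_equal(rownames(f$values), c("P1", "P3"))
  expect_equal(filter_min_valid(m, design6, 0L)$values, m$values)
  expect_error(filter_min_valid(m, design6, 4L), "min_valid")
  bad_design <- sample_design(paste0("X", 1:4),
                              c("bait", "bait", "control", "control"))
  expect_error(filter_min_valid(m, bad_design, 2L), "absent")
})

test_that("log2 transform maps powers of two exactly, keeps missing, guards the scale tag", {
  m <- make_matrix(rbind(c(1024, NA, 4, 8, 16, 32)))
  l <- log2_transform(m)
  expect_equal(l$values[1, ], c(S1 = 10, S2 = NA, S3 = 2, S4 = 3, S5 = 4,
                                S6 = 5))
  expect_equal(l$scale, "log2")
  expect_error(log2_transform(l), "raw")
})

test_that("down-shifted imputation draws from Normal(mu - shift*sigma, width*sigma)", {
  ## one column with mu = 25, sd = 2 from many observed values, many missing
  set.seed(42)
  n_obs <- 4000; n_miss <- 10000
  obs <- stats::rnorm(n_obs, 25, 2)
  col <- c(obs, rep(NA_real_, n_miss))
  v <- cbind(col, stats::rnorm(n_obs + n_miss, 25, 2))
  dimnames(v) <- list(paste0("P", seq_len(nrow(v))), c("A", "B"))
  m <- lfq_matrix(v, scale = "log2")
  imp <- impute_downshifted(m, width = 0.3, shift = 1.8, seed = 99)
  draws <- imp$values[imp$imputed[, 1], 1]
  mu <- mean(obs); sigma <- sd(obs)
  ## 4 Monte-Carlo standard errors around the stated law
  expect_lt(abs(mean(draws) - (mu - 1.8 * sigma)),
            4 * 0.3 * sigma / sqrt(n_miss))
  expect_lt(abs(sd(draws) - 0.3 * sigma),
            4 * 0.3 * sigma / sqrt(2 * n_miss))
  ## present values never altered; imputed count equals prior missing count
  expect_equal(imp$values[!m$imputed & !is.na(m$values)],
               m$values[!is.na(m$values)])
  expect_equal(sum(imp$imputed), sum(is.na(m$values)))
})

test_that("imputation is deterministic, per-column, and errors on sd-undefined columns", {
  v <- rbind(c(20, NA), c(22, 25), c(24, NA), c(NA, 27))
  dimnames(v) <- list(paste0("P", 1:4), c("A", "B"))
  m <- lfq_matrix(v, scale = "log2")
  i1 <- impute_downshifted(m, seed = 5)
  i2 <- impute_downshifted(m, seed = 5)
  expect_identical(i1$values, i2$values)
  i3 <- impute_downshifted(m, seed = 6)
  expect_false(identical(i1$values, i3$values))

  ## a column with no missing values is returned unchanged
  full <- lfq_matrix(matrix(c(1, 2, 3, 4), 2, 2,
                            dimnames = list(c("P1", "P2"), c("A", "B"))),
                     scale = "log2")
  expect_identical(impute_downshifted(full, seed = 1)$values, full$values)

  thin <- lfq_matrix(matrix(c(20, NA, NA, 21, 22, 23), 3, 2,
                            dimnames = list(paste0("P", 1:3), c("A", "B"))),
                     scale = "log2")
  expect_error(impute_downshifted(thin, seed = 1), "fewer than 2")
})

test_that("pooled equal-variance t matches closed form, t.test and numerical integration", {
  res <- two_sample_t_equal_var(c(2, 3, 4), c(0, 1, 2))
  expect_equal(res$t, 2.449489742783178, tolerance = 1e-12)
  expect_equal(res$df, 4L)
  expect_equal(res$se, sqrt(2 / 3), tolerance = 1e-12)
  ## p checked against numerical integration of the t density (frozen)
  expect_equal(res$p, 0.07048399691021993, tolerance = 1e-8)

  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(4, 1); b <- rnorm(5)
    mine <- two_sample_t_equal_var(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$se, unname(ref$stderr), tolerance = 1e-12)
    swapped <- two_sample_t_equal_var(b, a)
    expect_equal(swapped$t, -mine$t, tolerance = 1e-12)
    expect_equal(swapped$p, mine$p, tolerance = 1e-12)
  }

  same <- two_sample_t_equal_var(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(const <- two_sample_t_equal_var(c(1, 1), c(2, 2)),
                 "infinite")
  expect_equal(const$t, -Inf)
  expect_equal(const$p, 0)
  expect_equal(two_sample_t_equal_var(c(1, 1), c(1, 1))$p, 1)
})

test_that("SAM d is the fudged t and reduces to t at s0 = 0", {
  expect_equal(sam_d(2, 0.8165, 1.5), 2 / 2.3165, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(3, 2); b <- rnorm(3)
    res <- two_sample_t_equal_var(a, b)
    expect_equal(sam_d(res$diff, res$se, 0), res$t, tolerance = 1e-12)
  }
  ## strictly decreasing in s0 for positive differences
  d <- sam_d(2, 0.5, c(0, 0.5, 1, 1.5))
  expect_true(all(diff(d) < 0))
  expect_error(sam_d(1, 0, 0), "> 0")
})

test_that("combined threshold calls d >= t0 enrichment-side, never below t0*s0, never blacklisted", {
  rows <- data.frame(log2_diff = c(3, 1.8, -3, 2.5, 5),
                     se = c(0, 0.1, 0, 0.2, 0.4),
                     blacklist_hit = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- combined_threshold(rows, s0 = 1.5, t0 = 1.2, side = "enrichment")
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  ## no row with log2_diff <= t0*s0 = 1.8 can ever be significant
  expect_false(any(out$significant[out$log2_diff <= 1.8]))
  both <- combined_threshold(rows, s0 = 1.5, t0 = 1.2, side = "both")
  expect_true(both$significant[3])

  ## monotonicity: significant set shrinks as t0 or s0 grows
  set.seed(11)
  rand <- data.frame(log2_diff = rnorm(200, 1, 2),
                     se = abs(rnorm(200, 0.5, 0.3)))
  s_12 <- combined_threshold(rand, 1.5, 1.2)$significant
  s_15 <- combined_threshold(rand, 1.5, 1.5)$significant
  expect_true(all(which(s_15) %in% which(s_12)))
  s_s0 <- combined_threshold(rand, 2.0, 1.2)$significant
  expect_true(all(which(s_s0) %in% which(s_12)))
})

test_that("significance curve is the hyperbola equivalent to the d >= t0 decision", {
  curve <- significance_curve(1.5, 1.2, df = 4, diff_grid = seq(0, 10, 0.1))
  expect_false(any(curve$reachable[curve$log2_diff <= 1.8 - 1e-9]))
  reach <- curve[curve$reachable, ]
  expect_true(all(diff(reach$critical_neg_log10_p) < 0))
  ## critical -log10 p diverges approaching t0*s0 from above
  near <- significance_curve(1.5, 1.2, 4, 1.8 + 10^seq(-1, -8, by = -1))
  expect_true(all(diff(near$critical_neg_log10_p) > 0))
  expect_gt(max(near$critical_neg_log10_p), 10)

  ## equivalence on random rows: p <= critical p at own delta  <=>  d >= t0
  set.seed(21)
  for (i in 1:50) {
    a <- rnorm(3, 1.5, 1); b <- rnorm(3, 0, 1)
    st <- two_sample_t_equal_var(a, b)
    d <- sam_d(st$diff, st$se, 1.5)
    cv <- significance_curve(1.5, 1.2, st$df, st$diff)
    under_curve <- isTRUE(cv$reachable) &&
      -log10(st$p) >= cv$critical_neg_log10_p
    expect_equal(under_curve, d >= 1.2 && st$diff > 0)
  }
})

test_that("the pipeline is deterministic, permutation-equivariant, and blind to identical groups", {
  sim <- gen_lfq(n_background = 150, n_planted = 10, seed = 31)
  v1 <- run_apms_pipeline(sim$table, sim$design, seed = 31)
  v2 <- run_apms_pipeline(sim$table, sim$design, seed = 31)
  expect_identical(v1, v2)

  ## filtering, transform and flagging are permutation-equivariant in
  ## protein order (imputation draws are stream-positional, so imputed rows
  ## may differ; compare the retained set and all fully observed rows)
  perm <- sample(nrow(sim$table))
  vp <- run_apms_pipeline(sim$table[perm, ], sim$design, seed = 31)
  expect_setequal(vp$protein_id, v1$protein_id)
  vp <- vp[match(v1$protein_id, vp$protein_id), ]
  rownames(vp) <- NULL
  full <- v1$n_imputed_bait + v1$n_imputed_control == 0
  expect_equal(vp[full, ], v1[full, ], ignore_attr = TRUE)

  ## bait columns identical to control columns -> no calls
  tab <- sim$table
  tab[, sim$design$sample_id[4:6]] <- tab[, sim$design$sample_id[1:3]]
  v0 <- run_apms_pipeline(tab, sim$design, seed = 31)
  expect_equal(sum(v0$significant), 0L)
})

test_that("decoys, contaminants and blacklisted proteins are never called", {
  sim <- gen_lfq(n_background = 100, n_planted = 10, seed = 41)
  tab <- sim$table
  planted <- sim$truth$planted_ids
  tab$reverse[tab$protein_id == planted[1]] <- TRUE
  tab$contaminant[tab$protein_id == planted[2]] <- TRUE
  v <- run_apms_pipeline(tab, sim$design, seed = 41,
                         blacklist = planted[3],
                         annotations = planted[4])
  expect_false(any(planted[1:2] %in% v$protein_id))
  bl_row <- v[v$protein_id == planted[3], ]
  expect_true(bl_row$blacklist_hit)
  expect_false(bl_row$significant)
  expect_true(v$dna_binding[v$protein_id == planted[4]])
  expect_false(any(v$significant & v$blacklist_hit))
})
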