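ct_fixture <- function() {
  data.frame(sample = paste0("s", 1:6),
             group = rep(c("ctrl", "trt"), each = 3),
             target = "geneX",
             ct_target = c(25, 25.2, 24.8, 23, 23.2, 22.8),
             ct_reference = c(18, 18.2, 17.8, 18, 18.2, 17.8))
}

test_that("ddCT gives calibrator mean 1 and inverts planted fold changes", {
  ct <- ct_fixture()
  out <- ddct(ct, "ctrl")
  # calibrator geometric mean is exactly 1
  expect_equal(exp(mean(log(out$rel_expr[out$group == "ctrl"]))), 1)
  # treated dCT = 5 vs calibrator mean 7 -> ddCT -2 -> fold 4
  expect_equal(out$rel_expr[out$sample == "s4"], 4)
  # shifting every CT (target and reference alike) changes nothing
  shifted <- ct
  shifted$ct_target <- shifted$ct_target + 3.7
  shifted$ct_reference <- shifted$ct_reference + 3.7
  expect_equal(ddct(shifted, "ctrl")$rel_expr, out$rel_expr)
  # row order invariance
  expect_equal(sort(ddct(ct[sample(6), ], "ctrl")$rel_expr),
               sort(out$rel_expr))
  expect_error(ddct(ct, "nope"), "not present")
  bad <- ct; bad$ct_reference[1] <- NA
  expect_error(ddct(bad, "ctrl"), "CT")
})

test_that("noise-free simulated qPCR is inverted exactly", {
  tab <- simulate_qpcr(c(control = 1, treated = 4), sigma_ct = 0, seed = 3)
  out <- ddct(tab, "control")
  expect_equal(out$rel_expr[out$group == "treated"], rep(4, 3))
  expect_equal(out$rel_expr[out$group == "control"], rep(1, 3))
  expect_identical(simulate_qpcr(c(a = 1, b = 2), seed = 9),
                   simulate_qpcr(c(a = 1, b = 2), seed = 9))
})

test_that("Bonferroni adjustment multiplies and caps", {
  dct <- c(7, 7.1, 6.9, 5, 5.1, 4.9, 6, 6.2, 5.8)
  grp <- rep(c("ctrl", "t1", "t2"), each = 3)
  cmp <- list(c("ctrl", "t1"), c("ctrl", "t2"))
  res <- ttest_bonferroni(dct, grp, cmp, m = 3)
  expect_equal(res$p_adj, pmin(1, 3 * res$p_raw))
  identical_groups <- ttest_bonferroni(rep(c(5, 5, 5, 5, 5, 5)),
                                       rep(c("a", "b"), each = 3),
                                       list(c("a", "b")), m = 1)
  expect_equal(identical_groups$p_adj, 1)
  big <- ttest_bonferroni(dct, grp, list(c("ctrl", "t2")), m = 3)
  expect_lte(big$p_adj, 1)
  expect_error(ttest_bonferroni(dct, grp, cmp, m = 1), "smaller")
  expect_error(ttest_bonferroni(c(1, 2, 3), c("a", "a", "b"),
                                list(c("a", "b"))), ">= 2 samples")
})

test_that("time-course correlation hits the closed-form endpoints", {
  t4 <- c(15, 30, 45, 60)
  expect_equal(timecourse_correlation(t4, 2 * t4 + 1)$pearson_r, 1)
  expect_equal(timecourse_correlation(t4, -t4)$pearson_r, -1)
  flat <- timecourse_correlation(t4, rep(3, 4))
  expect_true(is.na(flat$pearson_r))
  expect_error(timecourse_correlation(c(1, 2), c(1, 2)), "3 observations")

  # planted r ~ 0.9 with n = 24 pooled replicate observations
  set.seed(31)
  times <- rep(t4, each = 6)
  vals <- times + rnorm(24, 0, 10)
  res <- timecourse_correlation(times, vals)
  expect_equal(res$pearson_r, cor(times, vals))
  boots <- vapply(1:2000, function(i) {
    idx <- sample.int(24, replace = TRUE)
    suppressWarnings(cor(times[idx], vals[idx]))
  }, 0)
  ci <- quantile(boots, c(0.005, 0.995), na.rm = TRUE)
  expect_gte(res$pearson_r, ci[[1]])
  expect_lte(res$pearson_r, ci[[2]])
})

test_that("synthesis-rate OLS matches hand-computed slopes", {
  exact <- data.frame(time = c(15, 30, 45, 60),
                      abundance = c(15, 30, 45, 60))
  f <- fit_synthesis_rate(exact)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)

  dmog_like <- data.frame(time = c(15, 30, 45, 60),
                          abundance = c(5.1, 10.2, 15.3, 20.4))
  expect_equal(fit_synthesis_rate(dmog_like)$slope, 0.34)

  shifted <- dmog_like
  shifted$abundance <- shifted$abundance + 7
  fs <- fit_synthesis_rate(shifted)
  expect_equal(fs$slope, 0.34)
  expect_equal(fs$intercept, 7)

  expect_error(fit_synthesis_rate(data.frame(time = c(10, 10, 10),
                                             abundance = 1:3)),
               "distinct")
})

test_that("slope comparison: identity null, power at the planted contrast, permutation agreement", {
  set.seed(32)
  a <- simulate_labeling(1.0, sigma_frac = 0.05, seed = 33)
  same <- compare_slopes(a, a)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  # slopes 0.3 vs 1.9 at sigma 5%: rejected in >= 95% of seeded reps
  rej <- vapply(1:100, function(i) {
    x <- simulate_labeling(0.3, sigma_frac = 0.05, seed = 1000 + i)
    y <- simulate_labeling(1.9, sigma_frac = 0.05, seed = 2000 + i)
    compare_slopes(x, y)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.95)

  # permutation oracle on a small case: within each time point,
  # reshuffle which observations carry which condition label
  set.seed(34)
  x <- simulate_labeling(0.8, sigma_frac = 0.3, replicates = 3, seed = 35)
  y <- simulate_labeling(1.1, sigma_frac = 0.3, replicates = 3, seed = 36)
  obs <- abs(compare_slopes(x, y)$t)
  times <- sort(unique(x$time))
  B <- 2000
  hits <- 0
  for (i in seq_len(B)) {
    pa <- pb <- list()
    for (t0 in times) {
      vals <- sample(c(x$abundance[x$time == t0], y$abundance[y$time == t0]))
      pa[[as.character(t0)]] <- data.frame(time = t0,
                                           abundance = vals[1:3])
      pb[[as.character(t0)]] <- data.frame(time = t0,
                                           abundance = vals[4:6])
    }
    ti <- abs(compare_slopes(do.call(rbind, pa), do.call(rbind, pb))$t)
    if (ti >= obs - 1e-12) hits <- hits + 1
  }
  p_perm <- (hits + 1) / (B + 1)
  p_mod <- compare_slopes(x, y)$p_value
  expect_lt(abs(p_mod - p_perm),
            0.04 + 3 * sqrt(p_perm * (1 - p_perm) / B))
})

test_that("labeling simulation is deterministic and exact at zero noise", {
  s0 <- simulate_labeling(0.34, sigma_frac = 0, seed = 5)
  expect_equal(fit_synthesis_rate(s0)$slope, 0.34)
  expect_identical(simulate_labeling(2, seed = 6),
                   simulate_labeling(2, seed = 6))
})
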