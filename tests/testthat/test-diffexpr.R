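test_that("expression filter keeps features passing >10 counts in >=70% of a group", {
  counts <- rbind(a = c(11, 11, 11, 11, 0, 0, 0, 0),
                  b = c(11, 0, 0, 0, 0, 0, 0, 0),
                  c = c(0, 0, 0, 0, 0, 0, 0, 0),
                  d = c(11, 11, 11, 0, 0, 0, 0, 0))
  colnames(counts) <- paste0("s", 1:8)
  cm <- count_matrix(counts, setNames(rep(c("g1", "g2"), each = 4),
                                      colnames(counts)))
  kept <- rownames(filter_expressed(cm)$counts)
  expect_setequal(kept, c("a", "d"))   # 100% and 75% pass; 25% and 0% fail
  # boundary: count == 10 does not count as "> 10"
  cm10 <- count_matrix(matrix(10, 1, 8, dimnames = list("x", paste0("s", 1:8))),
                       setNames(rep(c("g1", "g2"), each = 4),
                                paste0("s", 1:8)))
  expect_equal(nrow(filter_expressed(cm10)$counts), 0L)
})

test_that("TMM factors: identity, pure depth shift, permutation symmetry, geometric mean 1", {
  set.seed(11)
  base <- nb_counts(800, 3, mean_count = 150, phi = 0.05)
  same <- count_matrix(matrix(rep(base$counts[, 1], 4), ncol = 4,
                              dimnames = list(rownames(base$counts),
                                              paste0("s", 1:4))),
                       setNames(rep("g", 4), paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(same)$factors), rep(1, 4))

  # sample with counts doubled gene-wise: composition unchanged, so the
  # extra depth is absorbed by the library size, factors stay ~1 and the
  # effective-size ratio recovers 2x within 1%
  y <- base$counts
  y[, 5] <- 2 * y[, 1]
  colnames(y)[5] <- "dbl"
  cm <- count_matrix(y, setNames(rep("g", ncol(y)), colnames(y)))
  nf <- tmm_factors(cm)
  eff <- nf$effective_lib_sizes
  expect_equal(unname(eff["dbl"] / eff["A1"]), 2, tolerance = 0.01)
  expect_equal(prod(nf$factors), 1, tolerance = 1e-9)

  # gene-order permutation leaves factors unchanged
  perm <- count_matrix(y[sample(nrow(y)), ], cm_groups(cm))
  expect_equal(tmm_factors(perm)$factors, nf$factors)

  zero <- y; zero[, 2] <- 0
  expect_error(tmm_factors(count_matrix(zero, cm_groups(cm))), "all-zero")
})

test_that("TMM factors agree with edgeR's calcNormFactors", {
  set.seed(12)
  cm <- nb_counts(1500, 4, mean_count = 120, phi = 0.15,
                  lfc = c(rep(2, 150), rep(0, 1350)))
  ours <- tmm_factors(cm)$factors
  theirs <- edgeR::calcNormFactors(cm$counts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  set.seed(13)
  pois <- nb_counts(1500, 4, mean_count = 200, phi = 0)
  d0 <- estimate_dispersion(pois, tmm_factors(pois))
  expect_lte(d0$common, 0.01)

  nb <- nb_counts(2000, 4, mean_count = 200, phi = 0.1)
  d1 <- estimate_dispersion(nb, tmm_factors(nb))
  expect_gte(d1$common, 0.07)
  expect_lte(d1$common, 0.13)
  expect_true(all(d1$tagwise >= 1e-6 & d1$tagwise <= 10))

  # duplicating every sample must not raise the estimate appreciably
  dup <- count_matrix(cbind(nb$counts,
                            `colnames<-`(nb$counts,
                                         paste0(colnames(nb$counts), "_d"))),
                      setNames(rep(cm_groups(nb), 2),
                               c(colnames(nb$counts),
                                 paste0(colnames(nb$counts), "_d"))))
  d2 <- estimate_dispersion(dup, tmm_factors(dup))
  expect_lte(d2$common, d1$common * 1.1)

  one <- count_matrix(matrix(5:9, 5, 1, dimnames = list(letters[1:5], "s")),
                      c(s = "g"))
  expect_error(estimate_dispersion(one, tmm_factors(one)), "unidentifiable")
})

test_that("NB LRT: null behaviour, effect recovery, and label-swap symmetry", {
  ids <- c("f1", "f2")
  y <- matrix(c(100, 50, 100, 50, 100, 50, 100, 50), 2, 4,
              dimnames = list(ids, paste0("s", 1:4)))
  cm <- count_matrix(y, setNames(rep(c("A", "B"), each = 2),
                                 colnames(y)))
  nf <- tmm_factors(cm)
  res <- nb_lrt(cm, nf, 0.1, c("B", "A"))
  expect_equal(res$log2FC, c(0, 0))
  expect_true(all(res$p_raw > 0.99))

  set.seed(14)
  cm2 <- nb_counts(300, 4, mean_count = 200, phi = 0.05,
                   lfc = rep(c(2, 0), c(30, 270)))
  nf2 <- tmm_factors(cm2)
  res2 <- nb_lrt(cm2, nf2, 0.05, c("B", "A"))
  expect_lt(abs(median(res2$log2FC[1:30]) - 2), 0.3)
  expect_lt(abs(median(res2$log2FC[31:300])), 0.2)

  swap <- nb_lrt(cm2, nf2, 0.05, c("A", "B"))
  expect_equal(swap$log2FC, -res2$log2FC)
  expect_equal(swap$p_raw, res2$p_raw)
})

test_that("LRT p-values agree with edgeR's glmLRT at matched dispersion", {
  set.seed(15)
  cm <- nb_counts(500, 4, mean_count = 150, phi = 0.1,
                  lfc = rep(c(1, 0), c(50, 450)))
  nf <- tmm_factors(cm)
  phi <- 0.1
  ours <- nb_lrt(cm, nf, phi, c("B", "A"))
  grp <- factor(cm_groups(cm), levels = c("A", "B"))
  dge <- edgeR::DGEList(cm$counts, group = grp,
                        norm.factors = nf$factors)
  fit <- edgeR::glmFit(dge, model.matrix(~grp), dispersion = phi)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  expect_equal(ours$p_raw, lrt$table$PValue, tolerance = 1e-4)
  expect_equal(ours$log2FC, lrt$table$logFC, tolerance = 0.02)
})

test_that("BH adjustment and DE calling respect the stated thresholds", {
  res <- data.frame(feature = paste0("f", 1:4),
                    log2FC = c(2, -1, 0.69, 0.71),
                    logCPM = 5, dispersion = 0.1,
                    p_raw = c(0.01, 0.02, 0.03, 0.04))
  cl <- classify_de(res)
  expect_equal(cl$fdr, rep(0.04, 4))   # BH ties: 4 * p_i / i = 0.04 each
  expect_equal(cl$status, rep("not_DE", 4))   # fdr 0.04 >= 0.01

  res2 <- data.frame(feature = c("up", "edge", "down", "null"),
                     log2FC = c(1.2, 0.69, -0.8, 0.05),
                     logCPM = 5, dispersion = 0.1,
                     p_raw = c(1e-8, 1e-9, 1e-7, 0.6))
  cl2 <- classify_de(res2)
  expect_equal(cl2$status, c("up", "not_DE", "down", "not_DE"))
  expect_equal(cl2$status[cl2$feature == "edge"], "not_DE")  # 0.69 < 0.7

  empty <- res2[0, ]
  expect_equal(nrow(classify_de(empty)), 0L)
})

test_that("scaling one sample's counts shifts its effective size, not the calls", {
  set.seed(16)
  cm <- nb_counts(600, 4, mean_count = 150, phi = 0.05,
                  lfc = rep(c(1.5, 0), c(60, 540)))
  res1 <- de_pipeline(cm, c("B", "A"))
  y2 <- cm$counts; y2[, 3] <- 3L * y2[, 3]
  cm2 <- count_matrix(y2, cm_groups(cm))
  nf2 <- tmm_factors(cm2)
  expect_equal(unname(nf2$effective_lib_sizes[3] /
                      tmm_factors(cm)$effective_lib_sizes[3]),
               3, tolerance = 0.03)
  res2 <- de_pipeline(cm2, c("B", "A"))
  common <- intersect(res1$feature, res2$feature)
  s1 <- res1$status[match(common, res1$feature)]
  s2 <- res2$status[match(common, res2$feature)]
  expect_gte(mean(s1 == s2), 0.98)
})
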