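test_that("expression filtering matches a brute-force row scan", {
  set.seed(3)
  m <- matrix(rbinom(200, 3, 0.2), 20, 10,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  sub <- paste0("s", 1:4)
  f <- filter_expressed(m, sub)
  keep_oracle <- vapply(seq_len(nrow(m)), function(i)
    any(m[i, sub] >= 1), logical(1))
  expect_equal(rownames(f), rownames(m)[keep_oracle])
  expect_error(filter_expressed(m, character(0)), "no samples")
  expect_error(filter_expressed(m, "s99"), "not in matrix")
  zero <- m; zero["f1", ] <- 0
  expect_false("f1" %in% rownames(filter_expressed(zero)))
  single <- m; single["f2", ] <- 0; single["f2", "s1"] <- 1
  expect_true("f2" %in% rownames(filter_expressed(single, sub)))
})

test_that("size factors reproduce median-of-ratios by hand", {
  m <- matrix(c(10, 20, 40, 20, 40, 80), ncol = 2,
              dimnames = list(paste0("f", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)))
  ident <- cbind(a = c(3, 9, 5), b = c(3, 9, 5))
  rownames(ident) <- paste0("f", 1:3)
  expect_equal(unname(size_factors(ident)), c(1, 1))
})

test_that("size factors are scale-equivariant", {
  set.seed(8)
  m <- matrix(rnbinom(300, mu = 50, size = 5), 30, 10,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:10)))
  m[m == 0] <- 1
  s1 <- size_factors(m)
  s2 <- size_factors(m * 10)
  expect_equal(normalize_counts(m, s1) * 10, normalize_counts(m * 10, s2))
})

test_that("size factors match the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  m <- matrix(rnbinom(200 * 8, mu = 50, size = 5), 200, 8,
              dimnames = list(paste0("f", 1:200), paste0("s", 1:8)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)))
})

test_that("all-zero-feature matrices fail with guidance", {
  m <- rbind(f1 = c(5, 0), f2 = c(0, 7))
  colnames(m) <- c("a", "b")
  expect_error(size_factors(m), "poscounts")
  expect_silent(size_factors(m, type = "poscounts"))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # definitional brute force on short lists
  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
  withna <- c(0.01, NA, 0.04)
  expect_equal(is.na(bh_adjust(withna)), is.na(withna))
})

test_that("the NB Wald test is antisymmetric in the group labels", {
  sim <- small_cohort(seed = 14, n_features = 60)
  cs <- comparison_samples(sim$samples, "Control-vs-ID")
  mf <- filter_expressed(sim$counts, cs$sample_id)[, cs$sample_id]
  sf <- size_factors(mf, type = "poscounts")
  de1 <- nb_wald_test(mf, cs$label, sf)
  de2 <- nb_wald_test(mf, !cs$label, sf)
  expect_equal(de1$log2FoldChange, -de2$log2FoldChange)
  expect_equal(de1$pvalue, de2$pvalue)
  expect_true(all(de1$padj >= de1$pvalue, na.rm = TRUE))
})

test_that("null p-values are uniform and planted effects are recovered", {
  sim <- small_cohort(seed = 42, n_features = 2000)
  de <- run_de(sim$counts, sim$samples, "Control-vs-ID")
  p <- de$table$pvalue[!is.na(de$table$pvalue)]
  expect_lt(abs(mean(p) - 0.5), 0.02)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  # positive planted effects produce only "over" calls among true positives
  planted <- sprintf("syn-miR-%04d", 1:40)
  simp <- small_cohort(seed = 15, n_features = 400, lfc = 2,
                       planted = planted)
  dep <- run_de(simp$counts, simp$samples, "Control-vs-ID")
  hits <- dep$table[dep$table$feature_id %in% dep$significant &
                      dep$table$feature_id %in% planted, ]
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$direction == "over"))
})

test_that("degenerate all-zero groups yield NA rather than a crash", {
  sim <- small_cohort(seed = 16, n_features = 30)
  cs <- comparison_samples(sim$samples, "Control-vs-ID")
  m <- filter_expressed(sim$counts, cs$sample_id)[, cs$sample_id]
  m["syn-miR-0001", cs$label] <- 0
  de <- nb_wald_test(m, cs$label, size_factors(m, type = "poscounts"))
  row <- de[de$feature_id == "syn-miR-0001", ]
  expect_true(is.na(row$pvalue))
  expect_true(is.na(row$direction))
})

test_that("PCA returns normalised variance fractions and detects structure", {
  sim <- small_cohort(seed = 17, n_features = 200)
  expect_error(pca_counts(sim$counts[, 1:2]), ">= 3 samples")
  pc <- pca_counts(sim$counts)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  # duplicated sample => identical scores
  m <- sim$counts[, 1:10]
  m <- cbind(m, dup = m[, 1])
  sf <- size_factors(m, type = "poscounts")
  pc2 <- pca_counts(m, sf)
  expect_equal(unname(pc2$scores["dup", ]), unname(pc2$scores[1, ]))
  # strong planted structure separates groups on PC1
  planted <- sprintf("syn-miR-%04d", 1:60)
  simp <- small_cohort(seed = 18, n_features = 200, lfc = 4,
                       planted = planted)
  pcp <- pca_counts(simp$counts)
  grp <- simp$samples$group
  s1 <- pcp$scores[, 1]
  within <- c(s1[grp == "Control"] - mean(s1[grp == "Control"]),
              s1[grp == "ID"] - mean(s1[grp == "ID"]))
  between <- abs(mean(s1[grp == "ID"]) - mean(s1[grp == "Control"]))
  expect_gt(between, 2 * sd(within))
})
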