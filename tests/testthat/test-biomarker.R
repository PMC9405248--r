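test_that("the comparison registry enumerates the five contrasts", {
  reg <- tand_comparisons()
  expect_equal(reg$name, c("Control-vs-ID", "Control-vs-ASD",
                           "Control-vs-ASD+ID", "ID-vs-ASD+ID",
                           "ASD-vs-ASD+ID"))
  expect_equal(reg$positive, c("ID", "ASD", "ASD+ID", "ASD+ID", "ASD+ID"))
  expect_error(get_comparison("ID-vs-ASD"), "unknown comparison")
})

test_that("reference-gene selection applies the CV rule deterministically", {
  m <- rbind(const = c(5, 5, 5),
             steep = c(1, 2, 3),
             hi_stable = c(100, 103, 98),
             lo_stable = c(2, 2.1, 1.9))
  colnames(m) <- paste0("s", 1:3)
  # (1,2,3): CV = 1/2 = 0.5, excluded at 0.3
  expect_gt(sd(c(1, 2, 3)) / 2, 0.3)
  sel <- select_reference_gene(m)
  # qualifiers above the median mean: const(5) and hi_stable; hi_stable
  # and const are both stable, const has CV 0 but mean 5 > median? median
  # of means (5, 2, 100.33, 2) is 3.5 -> both qualify; const wins on CV 0
  expect_equal(sel, "const")
  noqual <- rbind(a = c(1, 5, 9), b = c(2, 9, 1))
  colnames(noqual) <- paste0("s", 1:3)
  expect_error(select_reference_gene(noqual), "lowest CVs")
})

test_that("ratio features follow the pseudocount arithmetic", {
  m <- rbind(f = 9, r = 4)
  colnames(m) <- "s1"
  rt <- ratio_features(m, "r")
  expect_equal(unname(rt["f", "s1"]), 2)
  expect_equal(unname(rt["r", "s1"]), 1)
  expect_error(ratio_features(m, "zz"), "not in matrix")
  # per-sample scaling cancels as the pseudocount vanishes
  set.seed(6)
  m2 <- matrix(rpois(40, 50) + 10, 4, 10,
               dimnames = list(c("a", "b", "c", "r"), paste0("s", 1:10)))
  r1 <- ratio_features(m2, "r", pseudocount = 1e-9)
  r2 <- ratio_features(m2 * 2, "r", pseudocount = 1e-9)
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("AUC equals Mann-Whitney pair counting on exhaustive arrangements", {
  values <- c(1, 2, 2, 3, 4, 4, 4, 7)  # ties on purpose
  n <- length(values)
  for (mask in 1:(2^n - 2)) {
    labels <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    r <- roc_auc(values, labels)
    expect_equal(r$auc_raw, pair_count_auc(values, labels),
                 tolerance = 1e-12)
    expect_equal(r$auc, max(r$auc_raw, 1 - r$auc_raw), tolerance = 1e-12)
  }
})

test_that("AUC matches pair counting on random tied instances", {
  set.seed(23)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    values <- sample(1:5, n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    expect_equal(roc_auc(values, labels)$auc_raw,
                 pair_count_auc(values, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC agrees with the field-standard implementation", {
  skip_if_not_installed("pROC")
  set.seed(24)
  for (i in 1:20) {
    v <- rnorm(15)
    l <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 13, TRUE))
    pr <- pROC::roc(l, v, direction = "<", quiet = TRUE)
    expect_equal(roc_auc(v, l)$auc_raw, as.numeric(pROC::auc(pr)),
                 tolerance = 1e-12)
  }
})

test_that("the Youden threshold matches an exhaustive scan", {
  set.seed(25)
  for (i in 1:25) {
    v <- round(c(rnorm(30), rnorm(10) + sample(0:2, 1)), 1)
    l <- rep(c(FALSE, TRUE), c(30, 10))
    r <- roc_auc(v, l)
    opt <- optimal_threshold(r)
    sgn <- if (r$direction == "up") 1 else -1
    cand <- sort(unique(c(sgn * v)))
    cand <- c(-Inf, (cand[-1] + cand[-length(cand)]) / 2, Inf)
    j_scan <- vapply(cand, function(t) {
      mean(sgn * v[l] > t) + mean(sgn * v[!l] <= t) - 1
    }, numeric(1))
    expect_equal(opt$youden_j, max(j_scan), tolerance = 1e-12)
    # the operating point recomputes from the confusion matrix
    called_pos <- sgn * v > sgn * opt$threshold
    expect_equal(opt$sensitivity, mean(called_pos[l]))
    expect_equal(opt$specificity, mean(!called_pos[!l]))
  }
  perf <- roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))
  optp <- optimal_threshold(perf)
  expect_equal(optp$youden_j, 1)
  expect_equal(optp$sensitivity, 1)
  expect_equal(optp$specificity, 1)
})

test_that("classifier ranking is deterministic and finds planted markers", {
  set.seed(26)
  R <- matrix(rnorm(20 * 40), 20, 40,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:40)))
  l <- rep(c(FALSE, TRUE), c(30, 10))
  R["f7", l] <- R["f7", l] + 4
  tab <- rank_classifiers(R, colnames(R), l, k = 10)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$feature_id[1], "f7")
  expect_true(all(diff(tab$auc) <= 0))
  # k beyond the feature count returns the full table without error
  tab_all <- rank_classifiers(R, colnames(R), l, k = 100)
  expect_equal(nrow(tab_all), 20)
})

test_that("the permutation estimator never returns zero and is seed-stable", {
  v <- c(rnorm(30), rnorm(10) + 5)
  l <- rep(c(FALSE, TRUE), c(30, 10))
  pt <- permutation_test(v, l, B = 2999, seed = 4)
  expect_equal(pt$p_value, 1 / 3000)
  expect_equal(permutation_test(v, l, B = 499, seed = 9)$p_value,
               permutation_test(v, l, B = 499, seed = 9)$p_value)
  # a null marker should not look significant
  set.seed(30)
  pnull <- permutation_test(rnorm(40), l, B = 999, seed = 2)$p_value
  expect_gt(pnull, 0.05)
})

test_that("the selection-aware test is calibrated under the null", {
  set.seed(31)
  rej <- logical(150)
  l <- rep(c(FALSE, TRUE), c(30, 10))
  for (i in seq_along(rej)) {
    R <- matrix(rnorm(20 * 40), 20, 40,
                dimnames = list(paste0("f", 1:20), NULL))
    rej[i] <- max_auc_permutation_test(R, l, B = 499,
                                       seed = 1000 + i)$p_value < 0.05
  }
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.1)
})

test_that("the end-to-end ROC screen reports a coherent table", {
  planted <- "syn-miR-0003"
  sim <- small_cohort(seed = 33, n_features = 40, lfc = 3,
                      planted = planted)
  out <- run_roc_screen(sim$counts, sim$samples, "Control-vs-ID",
                        B = 199, seed = 3)
  expect_equal(out$table$feature_id[1], planted)
  expect_gt(out$table$auc[1], 0.85)
  expect_lt(out$table$perm_p[1], 0.05)
  expect_lt(out$selection_aware_p, 0.05)
  expect_false(out$reference_gene %in% out$table$feature_id[1])
})
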