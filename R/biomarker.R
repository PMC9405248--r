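## Reference-gene ratio ROC screening.
##
## For each comparison a stably expressed reference feature (coefficient of
## variation of normalised expression < 0.3 across the comparison's
## samples) is selected; every feature is divided by it to form a
## scale-free ratio; each ratio is scored as a single-feature classifier by
## ROC/AUC with a Youden-index operating point; robustness is assessed by
## label-permutation (group sizes preserved), both per feature and
## selection-aware (null distribution of the cohort's maximum AUC).

#' Select a stably expressed reference feature
#'
#' @param m normalised count matrix.
#' @param sample_ids the comparison's samples.
#' @param cv_threshold qualification threshold on the coefficient of
#'   variation (sample sd / mean of normalised expression).
#' @return the selected feature id.  Among qualifiers (CV < threshold) the
#'   one with minimal CV among those whose mean expression exceeds the
#'   cohort median is chosen (falling back to minimal CV overall), ties
#'   broken by identifier.
#' @export
select_reference_gene <- function(m, sample_ids = colnames(m),
                                  cv_threshold = 0.3) {
  stop_if_not_count_matrix(m, "normalised matrix")
  x <- m[, sample_ids, drop = FALSE]
  mu <- rowMeans(x)
  cv <- apply(x, 1L, sd) / mu
  cv[!is.finite(cv)] <- Inf
  qual <- which(cv < cv_threshold)
  if (length(qual) == 0L) {
    worst <- sort(cv)[seq_len(min(5L, length(cv)))]
    stop("no feature qualifies at CV < ", cv_threshold, "; lowest CVs: ",
         paste(sprintf("%s=%.3f", names(worst), worst), collapse = ", "),
         call. = FALSE)
  }
  hi <- qual[mu[qual] > median(mu)]
  pool <- if (length(hi)) hi else qual
  ids <- rownames(m)[pool]
  ids[order(cv[pool], ids, method = "radix")][1L]
}

#' Reference-gene ratio features
#'
#' Each feature's per-sample expression is divided by the reference
#' feature's, after adding a pseudocount to guard zero denominators.  The
#' reference's own row is identically 1.
#'
#' @param m count matrix (normalised or raw).
#' @param ref_id reference feature id (a row of `m`).
#' @param pseudocount added to numerator and denominator.
#' @return matrix of ratios, same shape as `m`.
#' @export
ratio_features <- function(m, ref_id, pseudocount = 1) {
  stop_if_not_count_matrix(m)
  if (!ref_id %in% rownames(m)) {
    stop("reference feature '", ref_id, "' not in matrix", call. = FALSE)
  }
  denom <- m[ref_id, ] + pseudocount
  if (any(denom <= 0)) stop("non-positive reference denominator", call. = FALSE)
  sweep(m + pseudocount, 2L, denom, "/")
}

# midrank AUC of values against logical labels (TRUE = positive)
auc_rank <- function(values, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(values)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC for a single candidate marker
#'
#' AUC is computed by the midrank (Mann-Whitney) formula, equal to the
#' trapezoidal area under the empirical ROC.  The direction is folded so
#' the reported AUC is >= 0.5: `direction = "up"` means higher values in
#' the positive class.
#'
#' @param values per-sample marker values.
#' @param labels logical vector, TRUE = positive class.
#' @return object of class `roc_result`: list with `auc` (folded),
#'   `auc_raw`, `direction`, `curve` (data.frame `threshold`, `sensitivity`,
#'   `specificity`), `values`, `labels`.
#' @export
roc_auc <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  a <- auc_rank(values, labels)
  direction <- if (a >= 0.5) "up" else "down"
  v <- if (direction == "up") values else -values
  thr <- sort(unique(v))
  cand <- c(-Inf, (thr[-1] + thr[-length(thr)]) / 2, Inf)
  sens <- vapply(cand, function(t) mean(v[labels] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(v[!labels] <= t), numeric(1))
  curve <- data.frame(threshold = if (direction == "up") cand else -cand,
                      sensitivity = sens, specificity = spec)
  structure(list(auc = max(a, 1 - a), auc_raw = a, direction = direction,
                 curve = curve, values = values, labels = labels),
            class = "roc_result")
}

#' Youden-optimal operating point of a ROC curve
#'
#' Maximises Youden's J = sensitivity + specificity - 1 over all cut
#' points; ties are broken toward higher sensitivity.  Sensitivity and
#' specificity recompute exactly from the confusion matrix at the returned
#' threshold ("positive" call = value beyond the threshold in the folded
#' direction).
#'
#' @param roc a [roc_auc()] result.
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  best <- order(-j, -roc$curve$sensitivity)[1L]
  list(threshold = roc$curve$threshold[best],
       sensitivity = roc$curve$sensitivity[best],
       specificity = roc$curve$specificity[best],
       youden_j = j[best])
}

#' Rank single-feature ratio classifiers for a comparison
#'
#' @param ratios ratio matrix (features x samples, comparison samples
#'   included).
#' @param sample_ids,labels comparison samples and their logical labels.
#' @param k table size (default 10; the full table is returned when fewer
#'   features exist).
#' @return data.frame sorted by folded AUC (desc), then sensitivity,
#'   specificity and feature id: `feature_id`, `auc`, `direction`,
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
rank_classifiers <- function(ratios, sample_ids, labels, k = 10L) {
  x <- ratios[, sample_ids, drop = FALSE]
  rows <- lapply(rownames(x), function(f) {
    r <- roc_auc(x[f, ], labels)
    opt <- optimal_threshold(r)
    data.frame(feature_id = f, auc = r$auc, direction = r$direction,
               threshold = opt$threshold, sensitivity = opt$sensitivity,
               specificity = opt$specificity, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$auc, -tab$sensitivity, -tab$specificity, tab$feature_id,
               method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, k)
}

# permutation label matrix: B columns of n logicals with n1 TRUE each
perm_label_matrix <- function(n, n1, B) {
  P <- matrix(0, nrow = n, ncol = B)
  for (b in seq_len(B)) P[sample.int(n, n1), b] <- 1
  P
}

#' Permutation test for a single classifier's AUC
#'
#' Labels are permuted preserving group sizes; the folded AUC is recorded
#' each time and the empirical p is `(1 + #(AUC_perm >= AUC_obs)) /
#' (B + 1)`.
#'
#' @param values,labels as in [roc_auc()].
#' @param B number of permutations.
#' @param seed integer seed.
#' @return list with `p_value`, `auc_obs` (folded), `B`.
#' @export
permutation_test <- function(values, labels, B = 30000L, seed = 1L) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  n <- length(values); n1 <- sum(labels); n0 <- n - n1
  r <- rank(values)
  obs <- max(auc_rank(values, labels), 1 - auc_rank(values, labels))
  with_seed(seed, {
    P <- perm_label_matrix(n, n1, B)
    sums <- as.vector(r %*% P)
    a <- (sums - n1 * (n1 + 1) / 2) / (n1 * n0)
    af <- pmax(a, 1 - a)
    list(p_value = (1 + sum(af >= obs - 1e-12)) / (B + 1),
         auc_obs = obs, B = as.integer(B))
  })
}

#' Selection-aware permutation test for the top-ranked classifier
#'
#' Screening many features and then permutation-testing only the winner is
#' anti-conservative; here the null statistic is the maximum folded AUC
#' over all features under each label permutation, so the resulting p
#' accounts for the selection step.
#'
#' @param ratios features x samples value matrix.
#' @param labels logical labels for those samples.
#' @param B permutations.
#' @param seed integer seed.
#' @return list with `p_value`, `max_auc_obs`, `top_feature`, `B`.
#' @export
max_auc_permutation_test <- function(ratios, labels, B = 999L, seed = 1L) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  n <- length(labels); n1 <- sum(labels); n0 <- n - n1
  rk <- t(apply(ratios, 1L, rank))
  offs <- n1 * (n1 + 1) / 2
  fold <- function(a) pmax(a, 1 - a)
  a_obs <- fold((rowSums(rk[, labels, drop = FALSE]) - offs) / (n1 * n0))
  top <- which.max(a_obs)
  with_seed(seed, {
    P <- perm_label_matrix(n, n1, B)
    A <- fold((rk %*% P - offs) / (n1 * n0))
    max_perm <- apply(A, 2L, max)
    list(p_value = (1 + sum(max_perm >= max(a_obs) - 1e-12)) / (B + 1),
         max_auc_obs = max(a_obs),
         top_feature = rownames(ratios)[top],
         B = as.integer(B))
  })
}

#' Full single-marker screen for one comparison
#'
#' Normalise, select the reference feature, form ratios, rank the top-k
#' classifiers, attach per-feature permutation p for the table and a
#' selection-aware p for the cohort.
#'
#' @param m count matrix.
#' @param samples sample table.
#' @param comparison comparison name.
#' @param k table size.
#' @param B permutations.
#' @param seed integer seed.
#' @param reference_gene optional override of the reference feature id
#'   (e.g. a qPCR-established reference).
#' @return list: `table` (top-k with `perm_p`), `reference_gene`,
#'   `selection_aware_p`, `comparison`.
#' @export
run_roc_screen <- function(m, samples, comparison, k = 10L, B = 999L,
                           seed = 1L, reference_gene = NULL) {
  cs <- comparison_samples(samples, comparison)
  mf <- filter_expressed(m, cs$sample_id)[, cs$sample_id, drop = FALSE]
  sf <- size_factors(mf, type = "poscounts")
  z <- normalize_counts(mf, sf)
  ref_id <- if (is.null(reference_gene)) {
    select_reference_gene(z, cs$sample_id)
  } else {
    reference_gene
  }
  ratios <- ratio_features(z, ref_id)
  ratios <- ratios[rownames(ratios) != ref_id, , drop = FALSE]
  tab <- rank_classifiers(ratios, cs$sample_id, cs$label, k)
  tab$perm_p <- vapply(seq_len(nrow(tab)), function(i) {
    permutation_test(ratios[tab$feature_id[i], ], cs$label, B = B,
                     seed = derive_seed(seed, paste0("perm", i)))$p_value
  }, numeric(1))
  sel <- max_auc_permutation_test(ratios[, cs$sample_id, drop = FALSE],
                                  cs$label, B = B,
                                  seed = derive_seed(seed, "maxperm"))
  list(table = tab, reference_gene = ref_id,
       selection_aware_p = sel$p_value, comparison = cs$comparison)
}
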