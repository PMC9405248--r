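## Self-contained differential-expression stage: expression filter,
## median-of-ratios size factors, per-feature negative-binomial Wald test
## with method-of-moments dispersion, and Benjamini-Hochberg control.

#' Filter features expressed in a comparison
#'
#' Retains features with a read count of >= 1 in at least one of the
#' comparison's samples.
#'
#' @param m count matrix.
#' @param sample_ids samples participating in the comparison.
#' @param min_count expression threshold (default 1).
#' @return the filtered matrix.
#' @export
filter_expressed <- function(m, sample_ids = colnames(m), min_count = 1) {
  stop_if_not_count_matrix(m)
  if (length(sample_ids) == 0L) {
    stop("comparison contains no samples", call. = FALSE)
  }
  missing <- setdiff(sample_ids, colnames(m))
  if (length(missing)) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- rowSums(m[, sample_ids, drop = FALSE] >= min_count) > 0
  m[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample j, \eqn{s_j} is the median over features of
#' \eqn{k_{ij} / (\prod_j k_{ij})^{1/n}}, restricted to features whose
#' geometric mean is finite (i.e. no zero count).  `type = "poscounts"`
#' instead takes the geometric mean over positive counts only, for sparse
#' matrices with no all-nonzero feature.
#'
#' @param m count matrix.
#' @param type `"ratio"` (classic) or `"poscounts"`.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(m, type = c("ratio", "poscounts")) {
  stop_if_not_count_matrix(m)
  type <- match.arg(type)
  logm <- log(m)
  if (type == "ratio") {
    loggeo <- rowMeans(logm)
    usable <- is.finite(loggeo)
    if (!any(usable)) {
      stop("no feature has non-zero counts in every sample; ",
           "use type = \"poscounts\"", call. = FALSE)
    }
  } else {
    loggeo <- apply(logm, 1L, function(x) {
      f <- is.finite(x)
      if (!any(f)) -Inf else sum(x[f]) / length(x)
    })
    usable <- is.finite(loggeo)
  }
  sf <- apply(logm[usable, , drop = FALSE], 2L, function(lc) {
    r <- lc - loggeo[usable]
    exp(median(r[is.finite(r)]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("degenerate size factors; matrix too sparse", call. = FALSE)
  }
  sf
}

#' Normalised counts
#' @param m count matrix.
#' @param sf size factors (computed from `m` if missing).
#' @return matrix of counts divided by their sample's size factor.
#' @export
normalize_counts <- function(m, sf = size_factors(m)) {
  sweep(m, 2L, sf, "/")
}

#' Negative-binomial Wald test between two groups
#'
#' Per feature, group means are estimated on size-factor-normalised counts
#' and a common dispersion \eqn{\alpha} (variance \eqn{\mu + \alpha\mu^2})
#' is estimated by pooled method of moments, floored at 1e-8.  The Wald
#' statistic is the log2 fold change (positive vs reference group) over its
#' delta-method standard error, referred to a t distribution with
#' `nA + nB - 2` degrees of freedom: the per-feature dispersion is itself
#' estimated from the same few samples, and the t reference absorbs that
#' estimation noise where the asymptotic normal is anticonservative in the
#' far tail (exactly the region multiple-testing corrections read from).
#' Features with a zero mean in either group are reported as NA and
#' excluded from the Benjamini-Hochberg denominator.
#'
#' @param m count matrix (already filtered).
#' @param labels logical vector over `colnames(m)`'s order (or named),
#'   TRUE = positive group.
#' @param sf size factors for the tested samples.
#' @return data.frame: `feature_id`, `baseMean`, `log2FoldChange`, `lfcSE`,
#'   `stat`, `pvalue`, `padj`, `direction` ("over"/"under" for the positive
#'   group, NA when untestable).
#' @export
nb_wald_test <- function(m, labels, sf = size_factors(m)) {
  stop_if_not_count_matrix(m)
  stopifnot(is.logical(labels), length(labels) == ncol(m))
  if (sum(labels) < 2L || sum(!labels) < 2L) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  z <- normalize_counts(m, sf)
  zA <- z[, !labels, drop = FALSE]; zB <- z[, labels, drop = FALSE]
  sA <- sf[!labels]; sB <- sf[labels]
  nA <- ncol(zA); nB <- ncol(zB)

  qA <- rowMeans(zA); qB <- rowMeans(zB)
  vA <- apply(zA, 1L, var); vB <- apply(zB, 1L, var)

  # Var(z) = q/s + alpha q^2  =>  alpha = (v - q * mean(1/s)) / q^2
  invA <- mean(1 / sA); invB <- mean(1 / sB)
  aA <- (vA - qA * invA) / qA^2
  aB <- (vB - qB * invB) / qB^2
  w <- c(A = nA - 1L, B = nB - 1L)
  alpha <- (w["A"] * ifelse(is.finite(aA), aA, NA) +
              w["B"] * ifelse(is.finite(aB), aB, NA)) / sum(w)
  alpha[is.na(alpha)] <- ifelse(is.finite(aA), aA, aB)[is.na(alpha)]
  alpha <- pmax(alpha, 1e-8)

  testable <- qA > 0 & qB > 0 & is.finite(alpha)
  lfc <- se <- stat <- p <- rep(NA_real_, nrow(m))
  lfc[testable] <- log2(qB[testable] / qA[testable])
  varA <- sum(1 / sA) / (qA * nA^2) + alpha / nA
  varB <- sum(1 / sB) / (qB * nB^2) + alpha / nB
  se[testable] <- sqrt((varA + varB)[testable]) / log(2)
  stat[testable] <- lfc[testable] / se[testable]
  p[testable] <- 2 * stats::pt(-abs(stat[testable]), df = nA + nB - 2L)

  data.frame(
    feature_id = rownames(m),
    baseMean = rowMeans(z),
    log2FoldChange = lfc,
    lfcSE = se,
    stat = stat,
    pvalue = p,
    padj = bh_adjust(p),
    direction = ifelse(is.na(lfc), NA_character_,
                       ifelse(lfc >= 0, "over", "under")),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates inputs and applies the step-up FDR correction; NAs are kept in
#' place and excluded from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Run the full DE stage for one comparison
#'
#' Filter to features expressed among the comparison's samples, compute
#' size factors on those samples, and test positive vs negative group.
#'
#' @param m count matrix (any resolution).
#' @param samples sample table.
#' @param comparison comparison name (see [tand_comparisons()]).
#' @param alpha adjusted-p significance threshold.
#' @return list with `table` (the [nb_wald_test()] data.frame, ordered by
#'   p-value), `significant` (feature ids at `padj < alpha`),
#'   `size_factors`, `comparison`.
#' @export
run_de <- function(m, samples, comparison, alpha = 0.05) {
  cs <- comparison_samples(samples, comparison)
  mf <- filter_expressed(m, cs$sample_id)[, cs$sample_id, drop = FALSE]
  sf <- size_factors(mf, type = "poscounts")
  tab <- nb_wald_test(mf, cs$label, sf)
  tab <- tab[order(tab$pvalue, tab$feature_id, method = "radix"), ]
  rownames(tab) <- NULL
  list(table = tab,
       significant = tab$feature_id[!is.na(tab$padj) & tab$padj < alpha],
       size_factors = sf, comparison = cs$comparison)
}

#' PCA of log-normalised counts
#'
#' SVD of the feature-centred `log2(normalised count + 1)` matrix; used to
#' inspect cohort structure and batch effects before testing.
#'
#' @param m count matrix.
#' @param sf size factors.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `var_explained`
#'   (fractions summing to 1 over all components).
#' @export
pca_counts <- function(m, sf = size_factors(m, type = "poscounts"),
                       n_components = 2L) {
  stop_if_not_count_matrix(m)
  if (ncol(m) < 3L) stop("PCA needs >= 3 samples", call. = FALSE)
  x <- t(log2(normalize_counts(m, sf) + 1))
  x <- x[, apply(x, 2L, var) > 0, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE], var_explained = ve)
}
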