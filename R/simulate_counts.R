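## Synthetic serum-cohort generator: group-structured negative-binomial
## count matrices with planted effects, plus a ground-truth ledger.

#' Configure a synthetic serum cohort
#'
#' Defaults reproduce the study conditions the pipeline targets: a four-group
#' infant TSC cohort of 30 Control / 10 ID / 6 ASD / 13 ASD+ID serum
#' samples, negative-binomial feature counts with variance
#' \eqn{\mu + \alpha\mu^2}, and log-normal per-sample depth factors.
#'
#' @param group_sizes named integer vector of samples per group (all >= 2).
#' @param n_features number of miRNA features.
#' @param baseline_mean expected baseline count per feature.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param planted_effects data.frame with columns `feature_id`, `comparison`
#'   (one of the five registry names) and `log2fc`; the effect multiplies
#'   the mean by `2^log2fc` in the comparison's positive group.  NULL for a
#'   global-null cohort.
#' @param library_size_spread sd of log depth factors (log-normal, median 1).
#' @param seed integer seed.
#' @return object of class `cohort_config` (a list of the above).
#' @export
cohort_config <- function(group_sizes = c(Control = 30L, ID = 10L, ASD = 6L,
                                          "ASD+ID" = 13L),
                          n_features = 300L,
                          baseline_mean = 100,
                          dispersion = 0.1,
                          planted_effects = NULL,
                          library_size_spread = 0.25,
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    stop("group_sizes must be named", call. = FALSE)
  }
  if (any(group_sizes < 2L)) stop("all group sizes must be >= 2", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (baseline_mean <= 0) stop("baseline_mean must be > 0", call. = FALSE)
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("feature_id", "comparison", "log2fc") %in%
                    names(planted_effects)))
    lapply(planted_effects$comparison, get_comparison)
  }
  structure(list(group_sizes = group_sizes,
                 n_features = as.integer(n_features),
                 baseline_mean = baseline_mean,
                 dispersion = dispersion,
                 planted_effects = planted_effects,
                 library_size_spread = library_size_spread,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a miRNA-level count matrix with planted group effects
#'
#' Counts are drawn NB with mean `baseline * depth_j * 2^log2fc` (the fold
#' change applied only to samples of the positive group of the planted
#' comparison) and variance `mu + dispersion * mu^2`.  Per-feature baselines
#' are jittered around `baseline_mean` (log-normal, sd 0.5) so the feature
#' panel spans a realistic abundance range.
#'
#' @param config a [cohort_config()].
#' @param baseline_jitter_sd sd of per-feature log baseline jitter; 0 gives
#'   every feature exactly `baseline_mean`.
#' @return list with `counts` (features x samples integer matrix),
#'   `samples` (data.frame `sample_id`, `group`), `truth` (data.frame
#'   `feature_id`, `comparison`, `log2fc`, `direction`) and `depth`
#'   (per-sample depth factors).
#' @export
simulate_counts <- function(config, baseline_jitter_sd = 0.5) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = groups,
    stringsAsFactors = FALSE
  )
  m <- config$n_features
  feature_ids <- sprintf("syn-miR-%04d", seq_len(m))

  with_seed(config$seed, {
    depth <- rlnorm(n, meanlog = 0, sdlog = config$library_size_spread)
    base <- config$baseline_mean *
      rlnorm(m, meanlog = 0, sdlog = baseline_jitter_sd)

    lfc <- matrix(0, nrow = m, ncol = n,
                  dimnames = list(feature_ids, samples$sample_id))
    truth <- data.frame(feature_id = character(0), comparison = character(0),
                        log2fc = numeric(0), direction = character(0),
                        stringsAsFactors = FALSE)
    if (!is.null(config$planted_effects)) {
      pe <- config$planted_effects
      bad <- !(pe$feature_id %in% feature_ids)
      if (any(bad)) {
        stop("planted feature id(s) not in the simulated matrix: ",
             paste(pe$feature_id[bad], collapse = ", "), call. = FALSE)
      }
      for (k in seq_len(nrow(pe))) {
        cmp <- get_comparison(pe$comparison[k])
        affected <- samples$group == cmp$positive
        lfc[pe$feature_id[k], affected] <-
          lfc[pe$feature_id[k], affected] + pe$log2fc[k]
      }
      truth <- data.frame(feature_id = pe$feature_id,
                          comparison = pe$comparison,
                          log2fc = pe$log2fc,
                          direction = ifelse(pe$log2fc >= 0, "over", "under"),
                          stringsAsFactors = FALSE)
    }

    mu <- base * 2^lfc * rep(depth, each = m)
    counts <- matrix(rnbinom(m * n, mu = mu, size = 1 / config$dispersion),
                     nrow = m, ncol = n,
                     dimnames = list(feature_ids, samples$sample_id))
    list(counts = counts, samples = samples, truth = truth, depth = depth)
  })
}
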