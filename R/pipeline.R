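## Orchestration: simulate/load -> quantify -> DE -> ROC screen -> panel,
## across the five comparisons at miRNA and/or isomiR resolution, with a
## deterministic machine-readable summary.

#' Build a validated run configuration
#'
#' @param counts_mirna,counts_isomir paths to count TSVs (either may be
#'   NULL; at least one resolution must be available), or in-memory
#'   matrices.
#' @param samples path to the sample CSV, or a data.frame.
#' @param comparisons comparison names to run (subset of the five).
#' @param resolution `"mirna"`, `"isomir"` or `"both"`.
#' @param B permutations for the ROC stage.
#' @param seed root seed; every stage derives a named substream from it.
#' @param k top-k classifier table size.
#' @param de_alpha DE significance threshold on adjusted p.
#' @return object of class `run_config`.
#' @export
run_config <- function(counts_mirna = NULL, counts_isomir = NULL,
                       samples, comparisons = tand_comparisons()$name,
                       resolution = c("both", "mirna", "isomir"),
                       B = 999L, seed = 1L, k = 10L, de_alpha = 0.05) {
  resolution <- match.arg(resolution)
  lapply(comparisons, get_comparison)  # validates before any compute
  load_counts <- function(x) {
    if (is.null(x)) NULL
    else if (is.character(x)) read_count_matrix(x)
    else { stop_if_not_count_matrix(x); x }
  }
  cm <- load_counts(counts_mirna)
  ci <- load_counts(counts_isomir)
  if (is.character(samples)) samples <- read_sample_table(samples)
  if (resolution %in% c("both", "mirna") && is.null(cm) && !is.null(ci)) {
    cm <- collapse_to_mirna(ci)
  }
  want <- c(mirna = resolution %in% c("both", "mirna"),
            isomir = resolution %in% c("both", "isomir"))
  if (want["mirna"] && is.null(cm)) {
    stop("miRNA resolution requested but no counts available", call. = FALSE)
  }
  if (want["isomir"] && is.null(ci)) {
    stop("isomiR resolution requested but no counts available", call. = FALSE)
  }
  structure(list(counts = list(mirna = cm, isomir = ci)[want],
                 samples = samples, comparisons = comparisons,
                 B = as.integer(B), seed = as.integer(seed),
                 k = as.integer(k), de_alpha = de_alpha),
            class = "run_config")
}

#' Run the full analysis bundle
#'
#' For each requested comparison and resolution: differential expression
#' (filter, median-of-ratios, NB Wald, BH), the reference-gene-ratio ROC
#' screen with per-feature and selection-aware permutation p, and the
#' LASSO panel.  Intermediate tables are written under `out_dir` along
#' with a deterministic `summary.json`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return the summary list, invisibly; written as `summary.json`.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- config$samples
  summary <- list(comparisons = list(), group_sizes = as.list(
    table(samples$group)[unique(samples$group)]))

  for (res in names(config$counts)) {
    m <- config$counts[[res]]
    for (cmp in config$comparisons) {
      tag <- paste0(res, "_", gsub("[^A-Za-z0-9]+", "_", cmp))
      stage_seed <- derive_seed(config$seed, tag)
      de <- run_de(m, samples, cmp, alpha = config$de_alpha)
      roc <- run_roc_screen(m, samples, cmp, k = config$k, B = config$B,
                            seed = stage_seed)
      panel <- fit_panel(m, samples, cmp,
                         seed = derive_seed(config$seed, paste0(tag, "_p")))

      write.table(de$table, file.path(out_dir, paste0("de_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(roc$table, file.path(out_dir, paste0("roc_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)

      cs <- comparison_samples(samples, cmp)
      top <- roc$table[1L, ]
      summary$comparisons[[tag]] <- list(
        comparison = cmp,
        resolution = res,
        n_negative = sum(!cs$label),
        n_positive = sum(cs$label),
        n_features_tested = nrow(de$table),
        n_de = length(de$significant),
        de_features = de$significant,
        reference_gene = roc$reference_gene,
        top_classifier = list(
          feature_id = top$feature_id,
          auc = round(top$auc, 6),
          sensitivity = round(top$sensitivity, 6),
          specificity = round(top$specificity, 6),
          perm_p = round(top$perm_p, 6)
        ),
        selection_aware_p = round(roc$selection_aware_p, 6),
        panel = list(
          selected = panel$selected,
          lambda = signif(panel$lambda, 8),
          auc_insample = if (is.na(panel$auc_insample)) NULL else
            round(panel$auc_insample, 6),
          auc_cv = if (is.na(panel$auc_cv)) NULL else round(panel$auc_cv, 6)
        )
      )
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
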