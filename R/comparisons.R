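#' The five neuropsychiatric outcome comparisons
#'
#' The cohort is stratified into Control (no neuropsychiatric comorbidity),
#' ID (intellectual disability), ASD (autism spectrum disorder) and ASD+ID.
#' Screening runs five pairwise comparisons; the second-named group is the
#' positive (case) class for ROC purposes.
#'
#' @return data.frame with columns `name`, `negative`, `positive`.
#' @examples
#' tand_comparisons()
#' @export
tand_comparisons <- function() {
  data.frame(
    name = c("Control-vs-ID", "Control-vs-ASD", "Control-vs-ASD+ID",
             "ID-vs-ASD+ID", "ASD-vs-ASD+ID"),
    negative = c("Control", "Control", "Control", "ID", "ASD"),
    positive = c("ID", "ASD", "ASD+ID", "ASD+ID", "ASD+ID"),
    stringsAsFactors = FALSE
  )
}

#' Resolve a comparison name to its group pair
#' @param name one of the five comparison names.
#' @return one-row data.frame (`name`, `negative`, `positive`).
#' @export
get_comparison <- function(name) {
  reg <- tand_comparisons()
  i <- match(name, reg$name)
  if (is.na(i)) {
    stop("unknown comparison '", name, "'; must be one of: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  }
  reg[i, , drop = FALSE]
}

#' Samples participating in a comparison, with binary labels
#'
#' @param samples sample table (`sample_id`, `group`).
#' @param comparison comparison name or one-row registry entry.
#' @return list with `sample_id`, `label` (logical, TRUE = positive group),
#'   `comparison`.
#' @export
comparison_samples <- function(samples, comparison) {
  if (is.character(comparison)) comparison <- get_comparison(comparison)
  keep <- samples$group %in% c(comparison$negative, comparison$positive)
  if (!any(samples$group == comparison$negative) ||
      !any(samples$group == comparison$positive)) {
    stop("comparison ", comparison$name, ": a group has no samples",
         call. = FALSE)
  }
  list(sample_id = samples$sample_id[keep],
       label = samples$group[keep] == comparison$positive,
       comparison = comparison$name)
}
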