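#' @importFrom stats median model.matrix pnorm prcomp quantile rbinom rlnorm
#'   rmultinom rnbinom rnorm runif sd setNames p.adjust binomial coef glm
#'   predict var
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions are deterministic without clobbering the
#' session seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a named substream seed from a root seed
#'
#' All pipeline stages draw their seeds from a single root so a run is
#' replayable stage by stage.  The derived value stays inside the 32-bit
#' integer range.
#'
#' @param seed root integer seed.
#' @param stream character stream label (e.g. "counts", "reads").
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483587 + 1)
}

#' First TRUE per row of a logical matrix (NA if none)
#' @keywords internal
first_true <- function(m) {
  idx <- max.col(m, ties.method = "first")
  idx[!m[cbind(seq_len(nrow(m)), idx)]] <- NA_integer_
  idx
}

stop_if_not_count_matrix <- function(m, what = "count matrix") {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must be a matrix with feature rownames and sample colnames",
         call. = FALSE)
  }
  if (any(m < 0)) stop(what, " contains negative cells", call. = FALSE)
  if (anyDuplicated(rownames(m))) {
    stop(what, " has duplicated feature ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop(what, " has duplicated sample ids", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a count matrix as TSV
#'
#' First column `feature_id`, remaining columns one per sample.
#'
#' @param m integer matrix, features x samples.
#' @param path file path.
#' @return `read_count_matrix` returns the matrix; `write_count_matrix`
#'   returns `path` invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stop_if_not_count_matrix(m)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  stop_if_not_count_matrix(m)
  m
}

#' Read / write the per-sample table (sample_id, group)
#' @param path CSV path.
#' @param samples data.frame with columns `sample_id` and `group`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("sample table needs columns sample_id and group", call. = FALSE)
  }
  df
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
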