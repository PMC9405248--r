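## Read QC and exact-match isomiR quantification.
##
## QC follows the classic small-RNA recipe: remove low-quality leading and
## trailing bases, cut at the first sliding window (width 4) whose mean
## phred falls below 15, strip the 3' adapter, and discard anything
## shorter than 17 nt.  Surviving reads are assigned to an isomiR variant
## only on exact sequence equality ("no mismatches"); sequences claimed by
## several identifiers resolve to the reference's deterministic winner.

#' QC parameters for read trimming
#'
#' @param window sliding-window width (bases).
#' @param phred_threshold minimum mean window quality.
#' @param min_length minimum surviving read length; shorter reads are
#'   discarded.
#' @param quality_floor leading/trailing per-base quality floor.
#' @param adapter 3' adapter sequence.
#' @param adapter_min_overlap minimum exact 3' adapter overlap (bases).
#' @return object of class `qc_params`.
#' @export
qc_params <- function(window = 4L, phred_threshold = 15,
                      min_length = 17L, quality_floor = 3L,
                      adapter = TRUSEQ_SMALL_RNA_ADAPTER,
                      adapter_min_overlap = 8L) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (phred_threshold < 0 || quality_floor < 0) {
    stop("quality thresholds must be >= 0", call. = FALSE)
  }
  structure(list(window = as.integer(window),
                 phred_threshold = phred_threshold,
                 min_length = as.integer(min_length),
                 quality_floor = as.integer(quality_floor),
                 adapter = normalize_sequence(adapter),
                 adapter_min_overlap = as.integer(adapter_min_overlap)),
            class = "qc_params")
}

# phred33 quality strings -> integer matrix (rows padded with NA)
quality_to_matrix <- function(quality) {
  lens <- nchar(quality)
  L <- max(lens, 1L)
  q <- matrix(NA_integer_, nrow = length(quality), ncol = L)
  if (all(lens == L)) {
    big <- paste(quality, collapse = "")
    q[] <- matrix(utf8ToInt(big) - 33L, nrow = length(quality), ncol = L,
                  byrow = TRUE)
  } else {
    for (i in seq_along(quality)) {
      if (lens[i] > 0L) q[i, seq_len(lens[i])] <- utf8ToInt(quality[i]) - 33L
    }
  }
  q
}

#' Quality-trim reads (leading/trailing floor + sliding window)
#'
#' Leading and trailing bases with quality below `quality_floor` are
#' removed; the remainder is scanned with a sliding window of
#' `window` bases and cut just before the first window whose mean quality
#' drops below `phred_threshold`.  Reads ending up shorter than
#' `min_length` are discarded.
#'
#' @param sequence,quality parallel character vectors (phred33).
#' @param params a [qc_params()].
#' @return list with `sequence`, `quality` (trimmed, survivors only),
#'   `kept` (logical over the input) and `n_in`, `n_out`.
#' @export
trim_reads <- function(sequence, quality, params = qc_params()) {
  if (length(sequence) != length(quality) ||
      any(nchar(sequence) != nchar(quality))) {
    stop("sequence/quality length mismatch", call. = FALSE)
  }
  n <- length(sequence)
  if (n == 0L) {
    return(list(sequence = character(0), quality = character(0),
                kept = logical(0), n_in = 0L, n_out = 0L))
  }
  q <- quality_to_matrix(quality)
  L <- ncol(q)
  lens <- nchar(sequence)
  ok <- !is.na(q) & q >= params$quality_floor

  start <- first_true(ok)
  end <- L + 1L - first_true(ok[, L:1, drop = FALSE])
  empty <- is.na(start)
  start[empty] <- 1L; end[empty] <- 0L

  w <- params$window
  if (L >= w) {
    qz <- q
    if (anyNA(qz)) qz[is.na(qz)] <- 0L
    # row-wise cumulative sums by column accumulation (no per-row apply)
    cs <- matrix(0, nrow = n, ncol = L + 1L)
    for (j in seq_len(L)) cs[, j + 1L] <- cs[, j] + qz[, j]
    nw <- L - w + 1L
    wmean <- (cs[, (w + 1L):(L + 1L), drop = FALSE] -
                cs[, 1L:nw, drop = FALSE]) / w
    fail <- wmean < params$phred_threshold
    ffail <- first_true(fail)
    # bounds only matter for reads with a failing window somewhere: the
    # first failing window must start inside the floor-trimmed subread
    recheck <- which(!is.na(ffail))
    for (i in recheck) {
      js <- which(fail[i, ])
      js <- js[js >= start[i] & js <= end[i] - w + 1L]
      if (length(js)) end[i] <- js[1L] - 1L
    }
  }
  newlen <- pmax(end - start + 1L, 0L)
  kept <- newlen >= params$min_length
  list(sequence = substr(sequence[kept], start[kept], end[kept]),
       quality = substr(quality[kept], start[kept], end[kept]),
       kept = kept, n_in = n, n_out = sum(kept))
}

#' Strip the 3' adapter from reads
#'
#' The read is truncated at the leftmost position where an exact match to a
#' prefix of the adapter begins, provided the match extends over at least
#' `adapter_min_overlap` bases (a full-adapter occurrence anywhere also
#' truncates).  Matching is exact; qualities are truncated in lockstep.
#'
#' @inheritParams trim_reads
#' @return list with `sequence`, `quality`.
#' @export
strip_adapter <- function(sequence, quality, params = qc_params()) {
  adapter <- params$adapter
  ov <- min(params$adapter_min_overlap, nchar(adapter))
  seed_kmer <- substr(adapter, 1L, ov)
  lens <- nchar(sequence)
  cut <- rep(NA_integer_, length(sequence))

  cand <- which(grepl(seed_kmer, sequence, fixed = TRUE))
  if (length(cand)) {
    pos <- regexpr(seed_kmer, sequence[cand], fixed = TRUE)
    mlen <- pmin(lens[cand] - pos + 1L, nchar(adapter))
    full <- substr(sequence[cand], pos, pos + mlen - 1L) ==
      substr(rep(adapter, length(cand)), 1L, mlen)
    cut[cand[full]] <- pos[full]
    # leftmost seed occurrence did not extend into an adapter prefix:
    # scan the remaining occurrences read by read (rare)
    for (i in cand[!full]) {
      hits <- gregexpr(seed_kmer, sequence[i], fixed = TRUE)[[1]]
      for (p in hits[-1L]) {
        ml <- min(lens[i] - p + 1L, nchar(adapter))
        if (substr(sequence[i], p, p + ml - 1L) == substr(adapter, 1L, ml)) {
          cut[i] <- p
          break
        }
      }
    }
  }
  has <- !is.na(cut)
  sequence[has] <- substr(sequence[has], 1L, cut[has] - 1L)
  quality[has] <- substr(quality[has], 1L, cut[has] - 1L)
  list(sequence = sequence, quality = quality)
}

#' Assign reads to isomiR variants by exact match
#'
#' @param sequence character vector of trimmed read sequences.
#' @param ref an `isomir_reference`.
#' @return character vector of variant identifiers, `NA` for unassigned
#'   reads.
#' @export
assign_reads <- function(sequence, ref) {
  stopifnot(inherits(ref, "isomir_reference"))
  ref$assigned_id[match(sequence, ref$sequences)]
}

#' Tabulate per-sample assignments into an isomiR count matrix
#'
#' @param assignments named list: one character vector of variant
#'   identifiers (NAs ignored) per sample.
#' @param ref an `isomir_reference`; the matrix covers its full variant
#'   universe.
#' @return integer count matrix, variants x samples.
#' @export
count_reads <- function(assignments, ref) {
  stopifnot(inherits(ref, "isomir_reference"), is.list(assignments))
  universe <- ref$variants$identifier
  m <- vapply(assignments, function(a) {
    a <- a[!is.na(a)]
    bad <- setdiff(unique(a), universe)
    if (length(bad)) {
      stop("assignment to unknown identifier(s): ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    }
    tabulate(match(a, universe), nbins = length(universe))
  }, integer(length(universe)))
  m <- matrix(m, nrow = length(universe),
              dimnames = list(universe, names(assignments)))
  storage.mode(m) <- "double"
  m
}

#' Collapse an isomiR count matrix to miRNA resolution
#'
#' All variants of a canonical miRNA are summed; the grand total is
#' conserved exactly.
#'
#' @param m isomiR-level count matrix (rownames parseable by
#'   [parse_isomir_id()]).
#' @return miRNA-level count matrix (rownames = parent ids, order of first
#'   appearance).
#' @export
collapse_to_mirna <- function(m) {
  stop_if_not_count_matrix(m, "isomiR count matrix")
  parents <- parse_isomir_id(rownames(m))$parent_id
  out <- rowsum(m, factor(parents, levels = unique(parents)))
  out <- as.matrix(out)
  stop_if_not_count_matrix(out, "collapsed matrix")
  out
}

#' Quantify a set of FASTQ files against an isomiR reference
#'
#' Full QC + assignment: quality trimming, adapter stripping, a second
#' length filter (adapter removal can shorten a read below `min_length`),
#' exact-match assignment, counting, and collapsing.
#'
#' @param fastq named character vector of FASTQ paths (names = sample ids).
#' @param ref an `isomir_reference`.
#' @param params a [qc_params()].
#' @return list with `isomir` and `mirna` count matrices and `qc` summary
#'   data.frame (input / surviving / assigned reads per sample).
#' @export
quantify_fastq <- function(fastq, ref, params = qc_params()) {
  stopifnot(inherits(ref, "isomir_reference"))
  if (is.null(names(fastq)) || any(names(fastq) == "")) {
    stop("fastq paths must be named by sample id", call. = FALSE)
  }
  assignments <- list()
  qc <- data.frame(sample_id = names(fastq), n_input = 0L, n_surviving = 0L,
                   n_assigned = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(fastq)) {
    rec <- read_fastq(fastq[[i]])
    tr <- trim_reads(rec$sequence, rec$quality, params)
    st <- strip_adapter(tr$sequence, tr$quality, params)
    keep <- nchar(st$sequence) >= params$min_length
    a <- assign_reads(st$sequence[keep], ref)
    assignments[[names(fastq)[i]]] <- a
    qc$n_input[i] <- tr$n_in
    qc$n_surviving[i] <- sum(keep)
    qc$n_assigned[i] <- sum(!is.na(a))
  }
  isomir <- count_reads(assignments, ref)
  list(isomir = isomir, mirna = collapse_to_mirna(isomir), qc = qc)
}
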