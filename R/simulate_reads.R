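## Read-level simulation: isomiR-resolution counts are materialised as
## adapter-carrying FASTQ reads, the input format the quantifier consumes.

#' TruSeq small-RNA 3' adapter
#' @export
TRUSEQ_SMALL_RNA_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Configure the read simulator
#'
#' Reads emulate a single-end view of a 151-nt small-RNA sequencing run:
#' each read is the isomiR insert, followed by the 3' adapter, padded with
#' random bases to the full read length, with phred33 base qualities drawn
#' per base from a clamped normal.  Class probabilities control how a
#' miRNA-level count is split over its variant space.
#'
#' @param p_canonical,p_ext3,p_ext5,p_trim3 class probabilities (sum to 1).
#' @param adapter 3' adapter sequence.
#' @param read_length read length in nt.
#' @param base_quality_mean,base_quality_sd phred quality distribution.
#' @param seed integer seed.
#' @return object of class `read_sim_profile`.
#' @export
read_sim_profile <- function(p_canonical = 0.70, p_ext3 = 0.15,
                             p_ext5 = 0.05, p_trim3 = 0.10,
                             adapter = TRUSEQ_SMALL_RNA_ADAPTER,
                             read_length = 151L,
                             base_quality_mean = 35,
                             base_quality_sd = 3,
                             seed = 1L) {
  p <- c(canonical = p_canonical, ext3 = p_ext3, ext5 = p_ext5,
         p_trim3 = p_trim3)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
    stop("class probabilities must lie in [0,1] and sum to 1", call. = FALSE)
  }
  if (nchar(adapter) == 0L) stop("adapter must be non-empty", call. = FALSE)
  structure(list(p_canonical = p_canonical, p_ext3 = p_ext3,
                 p_ext5 = p_ext5, p_trim3 = p_trim3,
                 adapter = normalize_sequence(adapter),
                 read_length = as.integer(read_length),
                 base_quality_mean = base_quality_mean,
                 base_quality_sd = base_quality_sd,
                 seed = as.integer(seed)),
            class = "read_sim_profile")
}

#' Distribute miRNA-level counts over the isomiR variant space
#'
#' Each miRNA x sample count cell is split multinomially: first over the
#' four variant classes by the profile probabilities, then uniformly within
#' a class (classes with no variants, e.g. trim3 for an 18-nt canonical,
#' have their mass reassigned to the canonical).
#'
#' @param counts miRNA-level count matrix (rownames = canonical ids).
#' @param ref an [build_reference()] object covering those ids.
#' @param profile a [read_sim_profile()].
#' @return isomiR-level count matrix over the full variant universe of the
#'   referenced canonicals; column sums equal the input's.
#' @export
distribute_to_isomirs <- function(counts, ref, profile) {
  stop_if_not_count_matrix(counts)
  stopifnot(inherits(ref, "isomir_reference"),
            inherits(profile, "read_sim_profile"))
  missing <- setdiff(rownames(counts), ref$canonicals$id)
  if (length(missing)) {
    stop("counted miRNAs absent from reference: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  v <- ref$variants
  with_seed(profile$seed, {
    out <- lapply(rownames(counts), function(mir) {
      vi <- v[v$parent_id == mir, , drop = FALSE]
      p_class <- c(canonical = profile$p_canonical, trim3 = profile$p_trim3,
                   ext3 = profile$p_ext3, ext5 = profile$p_ext5)
      n_class <- table(factor(vi$klass, levels = names(p_class)))
      p_class[n_class == 0] <- 0
      p_class["canonical"] <- p_class["canonical"] + (1 - sum(p_class))
      pv <- p_class[vi$klass] / as.numeric(n_class[vi$klass])
      cells <- vapply(colnames(counts), function(s) {
        k <- counts[mir, s]
        if (k == 0) integer(nrow(vi)) else rmultinom(1, k, pv)[, 1]
      }, integer(nrow(vi)))
      cells <- matrix(cells, nrow = nrow(vi),
                      dimnames = list(vi$identifier, colnames(counts)))
      cells
    })
    do.call(rbind, out)
  })
}

#' Write isomiR counts as per-sample FASTQ files
#'
#' Every count cell becomes exactly that many reads; no sequencing error is
#' injected, so with a collision-free reference the quantifier reproduces
#' the input matrix cell for cell.
#'
#' @param isomir_counts isomiR-level count matrix (rownames = identifiers).
#' @param ref the `isomir_reference` resolving those identifiers.
#' @param profile a [read_sim_profile()].
#' @param out_dir output directory; one `<sample_id>.fastq` per column.
#' @param gzip write gzip-compressed FASTQ.
#' @return named character vector of written paths.
#' @export
simulate_reads <- function(isomir_counts, ref, profile, out_dir,
                           gzip = FALSE) {
  stop_if_not_count_matrix(isomir_counts)
  stopifnot(inherits(ref, "isomir_reference"),
            inherits(profile, "read_sim_profile"))
  idx <- match(rownames(isomir_counts), ref$variants$identifier)
  if (anyNA(idx)) {
    stop("isomiR id(s) not in reference: ",
         paste(utils::head(rownames(isomir_counts)[is.na(idx)], 3),
               collapse = ", "), call. = FALSE)
  }
  insert <- ref$variants$sequence[idx]
  # insert + adapter precomputed once per variant
  core <- paste0(insert, profile$adapter)
  core_len <- nchar(core)
  L <- profile$read_length
  if (L < max(core_len)) {
    stop("read_length ", L, " is shorter than the longest variant plus ",
         "adapter (", max(core_len), ")", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qual_chars <- function(n_reads) {
    q <- as.integer(round(rnorm(n_reads * L, profile$base_quality_mean,
                                profile$base_quality_sd)))
    q <- pmin(pmax(q, 2L), 41L)
    big <- rawToChar(as.raw(q + 33L))
    substring(big, seq(1L, n_reads * L, by = L), seq(L, n_reads * L, by = L))
  }
  base_raw <- charToRaw(paste(DNA_BASES, collapse = ""))
  random_bases <- function(k) {
    rawToChar(base_raw[sample.int(4L, k, replace = TRUE)])
  }
  with_seed(profile$seed + 1L, {
    paths <- setNames(
      file.path(out_dir, paste0(colnames(isomir_counts), ".fastq",
                                if (gzip) ".gz" else "")),
      colnames(isomir_counts))
    for (s in colnames(isomir_counts)) {
      k <- isomir_counts[, s]
      vrows <- rep.int(seq_along(k), k)
      n_reads <- length(vrows)
      if (n_reads > 0L) {
        vrows <- sample(vrows)  # interleave variants as a sequencer would
        pad_len <- L - core_len[vrows]
        total_pad <- sum(pad_len)
        pad <- if (total_pad > 0L) {
          bigpad <- random_bases(total_pad)
          ends <- cumsum(pad_len)
          substring(bigpad, ends - pad_len + 1L, ends)
        } else {
          character(n_reads)
        }
        seqs <- paste0(core[vrows], pad)
        quals <- qual_chars(n_reads)
        rec <- paste0("@", s, ":", seq_len(n_reads), "\n", seqs, "\n+\n",
                      quals)
      } else {
        rec <- character(0)
      }
      con <- if (gzip) gzfile(paths[s], "wb") else file(paths[s], "wb")
      writeLines(rec, con)
      close(con)
    }
    paths
  })
}

#' Read a phred33 FASTQ file
#'
#' @param path FASTQ path (gzip transparently supported).
#' @return list with `id`, `sequence`, `quality` (character vectors).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ (line count not a multiple of 4): ", path,
         call. = FALSE)
  }
  n <- length(lines) %/% 4L
  i <- seq_len(n)
  list(id = sub("^@", "", sub("\\s.*$", "", lines[4L * i - 3L])),
       sequence = lines[4L * i - 2L],
       quality = lines[4L * i])
}

#' Simulate a complete cohort bundle on disk
#'
#' Convenience wrapper: canonical set, isomiR reference, miRNA counts,
#' isomiR counts, per-sample FASTQ, sample table and truth ledger, all
#' written under `out_dir`.
#'
#' @param config a [cohort_config()]; `n_features` is the number of
#'   canonical miRNAs.
#' @param profile a [read_sim_profile()].
#' @param out_dir output directory.
#' @param write_fastq also materialise reads (slowest step).
#' @return list with the in-memory objects and a `paths` vector.
#' @export
simulate_cohort <- function(config, profile = read_sim_profile(),
                            out_dir, write_fastq = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  canonicals <- generate_canonical_set(config$n_features,
                                       seed = derive_seed(config$seed,
                                                          "canonicals"))
  sim <- simulate_counts(config)
  rownames(sim$counts) <- canonicals$id
  if (nrow(sim$truth)) {
    sim$truth$feature_id <- canonicals$id[
      match(sim$truth$feature_id, sprintf("syn-miR-%04d",
                                          seq_len(config$n_features)))]
  }
  ref <- build_reference(canonicals)
  profile$seed <- derive_seed(config$seed, "reads")
  isomir_counts <- distribute_to_isomirs(sim$counts, ref, profile)

  paths <- c(
    canonicals = file.path(out_dir, "canonicals.fasta"),
    reference = file.path(out_dir, "isomir_reference.fasta"),
    collisions = file.path(out_dir, "collisions.tsv"),
    mirna_counts = file.path(out_dir, "mirna_counts.tsv"),
    isomir_counts = file.path(out_dir, "isomir_counts.tsv"),
    samples = file.path(out_dir, "samples.csv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_canonical_fasta(canonicals, paths["canonicals"])
  write_reference_fasta(ref, paths["reference"], paths["collisions"])
  write_count_matrix(sim$counts, paths["mirna_counts"])
  write_count_matrix(isomir_counts, paths["isomir_counts"])
  write_sample_table(sim$samples, paths["samples"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  fastq <- NULL
  if (write_fastq) {
    fastq <- simulate_reads(isomir_counts, ref, profile,
                            file.path(out_dir, "fastq"))
  }
  list(canonicals = canonicals, reference = ref, counts = sim$counts,
       isomir_counts = isomir_counts, samples = sim$samples,
       truth = sim$truth, fastq = fastq, paths = paths)
}
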