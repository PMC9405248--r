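#' Generate a synthetic set of canonical mature miRNAs
#'
#' Draws `n` distinct random DNA sequences in the mature-miRNA length range
#' and assigns miRBase-style identifiers (`syn-miR-<k>-5p` / `-3p`).  This is
#' a synthetic stand-in for a canonical catalogue: real analyses should load
#' one with [read_canonical_fasta()].
#'
#' @param n number of miRNAs (>= 1).
#' @param length_range integer pair, min/max sequence length; must lie in
#'   \[18, 25\], the mature-miRNA range the variant enumerator supports.
#' @param seed integer seed; the set is deterministic given the seed.
#' @return data.frame with columns `id`, `sequence`.
#' @examples
#' head(generate_canonical_set(5, seed = 1))
#' @export
generate_canonical_set <- function(n, length_range = c(18L, 25L), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a single count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  lo <- as.integer(length_range[1]); hi <- as.integer(length_range[2])
  if (lo < 18L || hi > 25L || lo > hi) {
    stop("length_range must satisfy 18 <= min <= max <= 25", call. = FALSE)
  }
  if (log(n) > lo * log(4)) {
    stop("cannot draw ", n, " distinct sequences of minimum length ", lo,
         call. = FALSE)
  }
  with_seed(seed, {
    seqs <- character(0)
    while (length(seqs) < n) {
      need <- n - length(seqs)
      lens <- if (lo == hi) rep(lo, need) else sample(lo:hi, need,
                                                      replace = TRUE)
      new <- vapply(lens, function(L) {
        paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
      }, character(1))
      seqs <- unique(c(seqs, new))
    }
    seqs <- seqs[seq_len(n)]
    arm <- sample(c("5p", "3p"), n, replace = TRUE)
    data.frame(
      id = sprintf("syn-miR-%d-%s", seq_len(n), arm),
      sequence = seqs,
      stringsAsFactors = FALSE
    )
  })
}

#' Normalise a nucleotide sequence to upper-case DNA
#'
#' RNA input (U) is transliterated to T; case is folded.  Any residual
#' non-ACGT character is an error: the variant space is defined over the
#' unambiguous DNA alphabet.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,T\}.
#' @export
normalize_sequence <- function(x) {
  x <- chartr("U", "T", toupper(x))
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-ACGT characters in sequence(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  x
}

#' Read / write a canonical miRNA set as FASTA
#'
#' Sequences are normalised with [normalize_sequence()] on read (miRBase
#' distributes mature sequences as RNA).
#'
#' @param path FASTA file.
#' @param canonicals data.frame with `id`, `sequence`.
#' @return `read_canonical_fasta` returns a data.frame (`id`, `sequence`);
#'   `write_canonical_fasta` returns `path` invisibly.
#' @export
read_canonical_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate ids in canonical FASTA", call. = FALSE)
  data.frame(id = ids,
             sequence = unname(normalize_sequence(as.character(ss))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_canonical_fasta
#' @export
write_canonical_fasta <- function(canonicals, path) {
  ss <- Biostrings::DNAStringSet(setNames(canonicals$sequence, canonicals$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
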