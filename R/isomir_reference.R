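## isomiR variant-space enumeration and nomenclature.
##
## For a canonical mature miRNA of length L (18 <= L <= 25) the variant
## space is the disjoint union of:
##   * the canonical sequence itself,
##   * 5'-extensions: every non-templated addition of 1-3 bases (4+16+64
##     = 84 combinations) prepended to the canonical,
##   * 3'-extensions: the same 84 combinations appended,
##   * 3'-trims: removal of 1..(L-18) bases from the 3' end, never below
##     18 nt.
## Identifiers follow the <parent>_miRNA / <parent>_<added>_5prime /
## <parent>_<added>_3prime / <parent>_trim<N> convention.

# all non-templated additions of length 1..3, C-locale lexicographic order
all_extensions <- function(max_len = 3L) {
  out <- unlist(lapply(seq_len(max_len), function(k) {
    g <- do.call(expand.grid,
                 c(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
    do.call(paste0, g)
  }))
  sort(out, method = "radix")
}

ISOMIR_CLASSES <- c("canonical", "trim3", "ext3", "ext5")

#' Enumerate the isomiR variant space of one canonical miRNA
#'
#' @param id canonical miRNA identifier.
#' @param sequence canonical mature sequence (DNA or RNA; normalised
#'   internally), length >= 18.
#' @return data.frame with one row per variant and columns `identifier`,
#'   `parent_id`, `klass` (one of canonical/ext5/ext3/trim3), `added`
#'   (extension bases, NA otherwise), `trim_n` (NA unless trim3) and
#'   `sequence`.  Order is deterministic: canonical, then 5'-extensions
#'   (lexicographic by added bases), 3'-extensions, 3'-trims by increasing
#'   trim length.
#' @examples
#' v <- enumerate_isomirs("hsa-miR-221-3p", "AGCTACATTGTCTGCTGGGTTTC")
#' nrow(v)  # 2*(4+16+64) + (23-18) + 1
#' @export
enumerate_isomirs <- function(id, sequence) {
  stopifnot(length(id) == 1L, length(sequence) == 1L)
  sequence <- normalize_sequence(sequence)
  L <- nchar(sequence)
  if (L < 18L) {
    stop("canonical sequence of ", id, " is ", L,
         " nt; the 18-nt trim floor requires length >= 18", call. = FALSE)
  }
  ext <- all_extensions()
  trims <- if (L > 18L) seq_len(L - 18L) else integer(0)
  klass <- c("canonical", rep("ext5", length(ext)), rep("ext3", length(ext)),
             rep("trim3", length(trims)))
  added <- c(NA_character_, ext, ext, rep(NA_character_, length(trims)))
  trim_n <- c(rep(NA_integer_, 1L + 2L * length(ext)), trims)
  seqs <- c(sequence,
            paste0(ext, sequence),
            paste0(sequence, ext),
            substr(rep(sequence, length(trims)), 1L, L - trims))
  data.frame(
    identifier = format_isomir_id(id, klass, added, trim_n),
    parent_id = id,
    klass = klass,
    added = added,
    trim_n = trim_n,
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' Format an isomiR identifier
#'
#' Canonical variants are `<parent>_miRNA`; extensions append the added
#' bases and the modified end (`<parent>_AT_3prime`, `<parent>_G_5prime`);
#' 3'-trims are `<parent>_trim<N>`.
#'
#' @param parent_id canonical miRNA id (recycled).
#' @param klass one of `"canonical"`, `"ext5"`, `"ext3"`, `"trim3"`.
#' @param added extension bases (ext5/ext3 only).
#' @param trim_n trim length (trim3 only).
#' @return character vector of identifiers.
#' @examples
#' format_isomir_id("hsa-miR-409-3p", "ext3", added = "AT")
#' @export
format_isomir_id <- function(parent_id, klass, added = NA, trim_n = NA) {
  n <- max(length(parent_id), length(klass), length(added), length(trim_n))
  parent_id <- rep_len(parent_id, n); klass <- rep_len(klass, n)
  added <- rep_len(as.character(added), n)
  trim_n <- rep_len(as.integer(trim_n), n)
  if (!all(klass %in% ISOMIR_CLASSES)) {
    stop("unknown isomiR class: ",
         paste(setdiff(unique(klass), ISOMIR_CLASSES), collapse = ", "),
         call. = FALSE)
  }
  ext <- klass %in% c("ext5", "ext3")
  if (any(ext & (is.na(added) | !grepl("^[ACGT]{1,3}$", added)))) {
    stop("extension variants need 1-3 added bases over {A,C,G,T}",
         call. = FALSE)
  }
  if (any(klass == "trim3" & (is.na(trim_n) | trim_n < 1L))) {
    stop("trim3 variants need trim_n >= 1", call. = FALSE)
  }
  out <- character(n)
  out[klass == "canonical"] <- paste0(parent_id[klass == "canonical"], "_miRNA")
  out[klass == "ext5"] <- paste0(parent_id[klass == "ext5"], "_",
                                 added[klass == "ext5"], "_5prime")
  out[klass == "ext3"] <- paste0(parent_id[klass == "ext3"], "_",
                                 added[klass == "ext3"], "_3prime")
  out[klass == "trim3"] <- paste0(parent_id[klass == "trim3"], "_trim",
                                  trim_n[klass == "trim3"])
  out
}

#' Parse isomiR identifiers back to variant descriptors
#'
#' Inverse of [format_isomir_id()]: `format_isomir_id` applied to the result
#' reproduces the input exactly.
#'
#' @param ids character vector of isomiR identifiers.
#' @return data.frame with columns `identifier`, `parent_id`, `klass`,
#'   `added`, `trim_n`.
#' @examples
#' parse_isomir_id("hsa-miR-221-3p_trim3")
#' @export
parse_isomir_id <- function(ids) {
  parent <- rep(NA_character_, length(ids))
  klass <- rep(NA_character_, length(ids))
  added <- rep(NA_character_, length(ids))
  trim_n <- rep(NA_integer_, length(ids))

  is_can <- grepl("_miRNA$", ids)
  parent[is_can] <- sub("_miRNA$", "", ids[is_can])
  klass[is_can] <- "canonical"

  re_ext <- "^(.*)_([ACGT]{1,3})_(3prime|5prime)$"
  is_ext <- !is_can & grepl(re_ext, ids)
  parent[is_ext] <- sub(re_ext, "\\1", ids[is_ext])
  added[is_ext] <- sub(re_ext, "\\2", ids[is_ext])
  klass[is_ext] <- ifelse(sub(re_ext, "\\3", ids[is_ext]) == "3prime",
                          "ext3", "ext5")

  re_trim <- "^(.*)_trim([1-9][0-9]*)$"
  is_trim <- !is_can & !is_ext & grepl(re_trim, ids)
  parent[is_trim] <- sub(re_trim, "\\1", ids[is_trim])
  trim_n[is_trim] <- as.integer(sub(re_trim, "\\2", ids[is_trim]))
  klass[is_trim] <- "trim3"

  bad <- is.na(klass) | parent == ""
  if (any(bad)) {
    stop("unparseable isomiR identifier(s): ",
         paste(utils::head(ids[bad], 3), collapse = ", "), call. = FALSE)
  }
  data.frame(identifier = ids, parent_id = parent, klass = klass,
             added = added, trim_n = trim_n, stringsAsFactors = FALSE)
}

#' Build the exact-match isomiR reference over a canonical set
#'
#' Enumerates every variant of every canonical miRNA and prepares the
#' exact-lookup structure used for read assignment.  Identical sequences
#' claimed by more than one identifier (within or across families) are
#' listed in the collision report; for assignment each such sequence is
#' resolved to a single winner by a deterministic tie-break that prefers the
#' least-modified explanation of a read: canonical > trim3 > ext3 > ext5,
#' then lexicographic identifier.
#'
#' @param canonicals data.frame with unique `id` and `sequence` columns.
#' @return an object of class `isomir_reference`: list with `variants`
#'   (data.frame as from [enumerate_isomirs()], all families), `sequences`
#'   (unique variant sequences), `assigned_id` (the winning identifier per
#'   unique sequence), `collisions` (data.frame `sequence`,
#'   `identifiers` comma-joined) and `canonicals`.
#' @export
build_reference <- function(canonicals) {
  if (!is.data.frame(canonicals) || nrow(canonicals) == 0L) {
    stop("canonical set is empty", call. = FALSE)
  }
  if (anyDuplicated(canonicals$id)) {
    stop("duplicate canonical ids", call. = FALSE)
  }
  canonicals$sequence <- normalize_sequence(canonicals$sequence)
  variants <- do.call(rbind, lapply(seq_len(nrow(canonicals)), function(i) {
    enumerate_isomirs(canonicals$id[i], canonicals$sequence[i])
  }))
  rownames(variants) <- NULL

  # resolve each distinct sequence to one identifier
  rank_klass <- match(variants$klass, ISOMIR_CLASSES)
  ord <- order(variants$sequence, rank_klass,
               variants$identifier, method = "radix")
  vs <- variants$sequence[ord]
  keep <- !duplicated(vs)
  sequences <- vs[keep]
  assigned_id <- variants$identifier[ord][keep]

  dup_seq <- unique(vs[duplicated(vs)])
  collisions <- if (length(dup_seq)) {
    idx <- variants$sequence %in% dup_seq
    ids_by_seq <- split(variants$identifier[idx], variants$sequence[idx])
    ids_by_seq <- ids_by_seq[dup_seq]
    data.frame(sequence = dup_seq,
               identifiers = vapply(ids_by_seq, function(x)
                 paste(sort(x, method = "radix"), collapse = ","),
                 character(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(sequence = character(0), identifiers = character(0),
               stringsAsFactors = FALSE)
  }

  structure(list(variants = variants, sequences = sequences,
                 assigned_id = assigned_id, collisions = collisions,
                 canonicals = canonicals),
            class = "isomir_reference")
}

#' @export
print.isomir_reference <- function(x, ...) {
  cat("isomiR reference:", nrow(x$canonicals), "canonical miRNAs,",
      nrow(x$variants), "variants,",
      length(x$sequences), "distinct sequences,",
      nrow(x$collisions), "collisions\n")
  invisible(x)
}

#' Write the isomiR reference as FASTA (one record per variant)
#'
#' @param ref an `isomir_reference`.
#' @param path output FASTA path.
#' @param collisions_path optional TSV path for the collision report.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, collisions_path = NULL) {
  stopifnot(inherits(ref, "isomir_reference"))
  ss <- Biostrings::DNAStringSet(
    setNames(ref$variants$sequence, ref$variants$identifier))
  Biostrings::writeXStringSet(ss, path)
  if (!is.null(collisions_path)) {
    write.table(ref$collisions, collisions_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
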