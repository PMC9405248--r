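# brute-force sliding-window oracle: literal per-read scan
brute_trim <- function(q, window = 4, thr = 15, floor = 3) {
  s <- which(q >= floor)[1]
  e <- length(q) + 1 - which(rev(q) >= floor)[1]
  if (is.na(s) || is.na(e) || e < s) return(integer(0))
  if (e - s + 1 >= window) {
    for (j in s:(e - window + 1)) {
      if (mean(q[j:(j + window - 1)]) < thr) {
        e <- j - 1
        break
      }
    }
  }
  if (e < s) integer(0) else s:e
}

test_that("quality trimming applies floor, window and length rules", {
  r <- trim_reads("ACGTACGTACGTACGTACGT", qstr(rep(40, 20)))
  expect_equal(r$sequence, "ACGTACGTACGTACGTACGT")
  # trailing floor trim leaves 15 nt < 17 => discard
  r2 <- trim_reads("ACGTACGTACGTACGTACGT",
                   qstr(c(rep(40, 15), rep(2, 5))))
  expect_equal(r2$n_out, 0)
  # window of four Q10 bases cuts the read at its start
  q <- c(rep(40, 20), rep(10, 4), rep(40, 6))
  r3 <- trim_reads(strrep("A", 30), qstr(q))
  expect_equal(nchar(r3$sequence), 20)
  expect_error(trim_reads("ACGT", "II"), "mismatch")
})

test_that("vectorised trimming agrees with a per-read brute-force scan", {
  set.seed(31)
  for (i in 1:50) {
    L <- sample(20:60, 1)
    seqc <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    q <- sample(0:41, L, TRUE, prob = (1:42)^2)  # mostly decent quality
    r <- trim_reads(seqc, qstr(q))
    keep <- brute_trim(q)
    if (length(keep) >= 17) {
      expect_equal(r$sequence, substr(seqc, keep[1], keep[length(keep)]))
    } else {
      expect_equal(r$n_out, 0)
    }
  }
})

test_that("adapter stripping respects the minimum-overlap contract", {
  ad <- TRUSEQ_SMALL_RNA_ADAPTER
  insert <- "ACGTACGTACGTACGTACGTAC"
  s <- paste0(insert, ad, "GGGG")
  out <- strip_adapter(s, strrep("I", nchar(s)))
  expect_equal(out$sequence, insert)
  expect_equal(nchar(out$quality), nchar(insert))
  # no adapter anywhere
  out2 <- strip_adapter(insert, strrep("I", nchar(insert)))
  expect_equal(out2$sequence, insert)
  # a 7-nt coincidental suffix match is below the minimum overlap
  s7 <- paste0(insert, substr(ad, 1, 7))
  expect_equal(strip_adapter(s7, strrep("I", nchar(s7)))$sequence, s7)
  s8 <- paste0(insert, substr(ad, 1, 8))
  expect_equal(strip_adapter(s8, strrep("I", nchar(s8)))$sequence, insert)
})

test_that("assignment is exact-match only with a deterministic tie-break", {
  can <- tiny_canonicals()
  ref <- build_reference(can)
  expect_equal(assign_reads(can$sequence[1], ref), "hsa-miR-221-3p_miRNA")
  mism <- paste0("T", substr(can$sequence[1], 2, nchar(can$sequence[1])))
  # single substitution: not equal to the canonical; may only match if it
  # coincides with some other enumerated variant, which it does not here
  expect_true(is.na(assign_reads(mism, ref)))
  # collision fixture: canonical of B == A + "G"; canonical id wins
  a_seq <- "ACGTACGTACGTACGTACGTA"
  ref2 <- build_reference(data.frame(id = c("mirA", "mirB"),
                                     sequence = c(a_seq, paste0(a_seq, "G"))))
  expect_equal(assign_reads(paste0(a_seq, "G"), ref2), "mirB_miRNA")
})

test_that("counting covers the variant universe and conserves totals", {
  ref <- build_reference(tiny_canonicals()[1:2, ])
  asg <- list(s1 = c("hsa-miR-221-3p_miRNA", "hsa-miR-221-3p_miRNA", NA,
                     "hsa-miR-410-3p_trim1"),
              s2 = c(NA, NA))
  m <- count_reads(asg, ref)
  expect_equal(nrow(m), nrow(ref$variants))
  expect_equal(m["hsa-miR-221-3p_miRNA", "s1"], 2)
  expect_equal(sum(m[, "s1"]), 3)
  expect_equal(sum(m[, "s2"]), 0)
  expect_error(count_reads(list(s = "bogus_id_banana"), ref), "unparse|unknown")
})

test_that("collapsing to miRNA level conserves grand totals", {
  ref <- build_reference(tiny_canonicals())
  set.seed(5)
  m <- matrix(rpois(nrow(ref$variants) * 3, 2),
              nrow = nrow(ref$variants),
              dimnames = list(ref$variants$identifier, c("a", "b", "c")))
  cm <- collapse_to_mirna(m)
  expect_equal(nrow(cm), 3)
  expect_equal(colSums(cm), colSums(m))
  expect_equal(sum(cm), sum(m))
  one <- collapse_to_mirna(
    matrix(c(5, 2, 3), 3,
           dimnames = list(c("x_miRNA", "x_A_3prime", "x_trim1"), "s")))
  expect_equal(unname(one["x", "s"]), 10)
})

test_that("raising the quality threshold never lengthens surviving reads", {
  set.seed(77)
  n <- 200
  seqs <- vapply(1:n, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
    character(1))
  quals <- vapply(1:n, function(i) qstr(sample(5:41, 40, TRUE)), character(1))
  lax <- trim_reads(seqs, quals, qc_params(phred_threshold = 10))
  strict <- trim_reads(seqs, quals, qc_params(phred_threshold = 25))
  expect_lte(strict$n_out, lax$n_out)
  both <- which(lax$kept & strict$kept)
  len_lax <- setNames(nchar(lax$sequence), which(lax$kept))
  len_strict <- setNames(nchar(strict$sequence), which(strict$kept))
  expect_true(all(len_strict[as.character(both)] <=
                    len_lax[as.character(both)]))
})

test_that("simulated cohorts round-trip through quantification exactly", {
  cfg <- cohort_config(group_sizes = c(Control = 3L, ID = 2L),
                       n_features = 8L, baseline_mean = 40, seed = 13)
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(cfg, out_dir = dir)
  expect_equal(nrow(coh$reference$collisions), 0)
  q <- quantify_fastq(coh$fastq, coh$reference)
  got <- q$isomir[rownames(coh$isomir_counts), colnames(coh$isomir_counts)]
  expect_equal(got, coh$isomir_counts, ignore_attr = TRUE)
  expect_equal(sum(q$mirna), sum(coh$isomir_counts))
  expect_equal(q$qc$n_assigned, unname(colSums(coh$isomir_counts)))
})
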