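# shared test helpers: all fixtures are built in code

# phred33 quality string from integer scores
qstr <- function(v) intToUtf8(v + 33L)

# deterministic tiny canonical set with fixed, hand-readable sequences
tiny_canonicals <- function() {
  data.frame(
    id = c("hsa-miR-221-3p", "hsa-miR-410-3p", "hsa-miR-28-3p"),
    sequence = c("AGCTACATTGTCTGCTGGGTTTC",   # 23 nt
                 "AATATAACACAGATGGCCTGT",     # 21 nt
                 "CACTAGATTGTGAGCTCCTGGA"),   # 22 nt
    stringsAsFactors = FALSE
  )
}

# brute-force isomiR enumeration oracle: nested loops, no shared code with
# enumerate_isomirs()
brute_force_isomirs <- function(sequence) {
  bases <- c("A", "C", "G", "T")
  out <- sequence
  for (k in 1:3) {
    combos <- do.call(expand.grid,
                      c(rep(list(bases), k), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(combos))) {
      add <- paste(unlist(combos[i, ]), collapse = "")
      out <- c(out, paste0(add, sequence), paste0(sequence, add))
    }
  }
  L <- nchar(sequence)
  if (L > 18) {
    for (tn in 1:(L - 18)) out <- c(out, substr(sequence, 1, L - tn))
  }
  out
}

# Mann-Whitney AUC by exhaustive pair counting (independent of roc_auc)
pair_count_auc <- function(values, labels) {
  pos <- values[labels]
  neg <- values[!labels]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# small two-group count cohort used across statistics tests
small_cohort <- function(seed = 1L, n_features = 50L, lfc = 0,
                         planted = character(0)) {
  pe <- if (length(planted)) {
    data.frame(feature_id = planted, comparison = "Control-vs-ID",
               log2fc = lfc)
  } else NULL
  cfg <- cohort_config(group_sizes = c(Control = 30L, ID = 10L),
                       n_features = n_features, baseline_mean = 100,
                       dispersion = 0.1, planted_effects = pe, seed = seed)
  simulate_counts(cfg)
}
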