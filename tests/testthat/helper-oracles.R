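# Independent brute-force oracles used to cross-check the implementations.

# N50: walk the sorted lengths and return the first length at which the
# running sum reaches half the total.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(as.numeric(s)) / 2
  run <- 0
  for (x in s) {
    run <- run + x
    if (run >= half) return(x)
  }
}

# exact clustering: all-pairs string comparison
oracle_transferred_exact <- function(old_seqs, new_seqs) {
  hits <- character(0)
  for (ot in names(old_seqs)) {
    for (nt in names(new_seqs)) {
      if (nchar(old_seqs[[ot]]) == nchar(new_seqs[[nt]]) &&
          old_seqs[[ot]] == new_seqs[[nt]]) {
        hits <- c(hits, ot)
        break
      }
    }
  }
  hits
}

# reciprocal best hits: enumerate every (q, s) pair and test the definition
# directly against full scans of both tables.
oracle_rbh <- function(fwd, rev, evalue_max = 0.001) {
  is_best <- function(tab, q, s) {
    rows <- tab[tab$query == q, ]
    rows <- rows[order(rows$evalue, -rows$bitscore, rows$subject), ]
    nrow(rows) > 0 && rows$subject[1] == s && rows$evalue[1] <= evalue_max
  }
  pairs <- unique(fwd[c("query", "subject")])
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    is_best(fwd, pairs$query[i], pairs$subject[i]) &&
      is_best(rev, pairs$subject[i], pairs$query[i])
  }, logical(1))
  out <- pairs[keep, , drop = FALSE]
  out[order(out$query), , drop = FALSE]
}

# beta-signal scan: regex built from the residue classes
oracle_beta_scan <- function(protein, cterm_window = 15) {
  cls <- beta_signal_classes()
  pat <- sprintf("(?=([%s].G[%s].[%s].[%s]))",
                 paste(cls$polar_set, collapse = ""),
                 paste(cls$hydrophobic_set, collapse = ""),
                 paste(cls$hydrophobic_set, collapse = ""),
                 paste(cls$hydrophobic_set, collapse = ""))
  m <- gregexpr(pat, protein, perl = TRUE)[[1]]
  starts <- as.integer(m[m > 0])
  n <- nchar(protein)
  sort(starts[(n - (starts + 7)) <= cterm_window])
}

random_hit_table <- function(n, queries, subjects) {
  data.frame(
    query = sample(queries, n, replace = TRUE),
    subject = sample(subjects, n, replace = TRUE),
    pct_identity = round(runif(n, 20, 100), 1),
    aln_len = sample(50:400, n, replace = TRUE),
    mismatches = sample(0:30, n, replace = TRUE),
    gapopen = sample(0:4, n, replace = TRUE),
    qstart = rep(1L, n), qend = sample(50:400, n, replace = TRUE),
    sstart = rep(1L, n), send = sample(50:400, n, replace = TRUE),
    evalue = 10^runif(n, -12, 0),
    bitscore = round(runif(n, 30, 400), 1),
    stringsAsFactors = FALSE
  )
}

random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# small shared synthetic corpus, built once per test run
small_spec <- function(seed = 7, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_genes = 60, n_contigs = 5,
                   n_both_telomeres = 2, n_one_telomere = 3,
                   proteome = list(n_total = 300, n_targeting = 5, n_ta = 3,
                                   n_ta_decoy = 3, n_mbomp_pos = 2,
                                   n_mbomp_decoy = 6, rbh_pairs = 4,
                                   n_hmm = 5, n_hmm_with_db = 2))
  defaults[names(args)] <- args
  do.call(synthesis_spec, defaults)
}

dinuc_counts <- function(s) {
  n <- nchar(s)
  table(substring(s, 1:(n - 1), 2:n))
}
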