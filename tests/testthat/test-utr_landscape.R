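mk_gene <- function(tag, utr_start, utr_end, strand = "+",
                    span = c(utr_start - 300L, utr_end)) {
  gene_models(data.frame(
    locus_tag = tag, contig = "c1", strand = strand,
    type = c("exon", "CDS", "three_prime_UTR"),
    start = c(span[1], span[1], utr_start),
    end = c(span[2], utr_start - 1L, utr_end),
    complete = FALSE, stringsAsFactors = FALSE), validate = FALSE)
}

test_that("full-length flagging needs an exact boundary and full coverage", {
  m <- mk_gene("g1", 4801L, 5000L)
  utrs <- data.frame(gene_tag = "g1", kind = "three_prime",
                     seq = strrep("A", 200), length = 200L, introns = 0L,
                     stringsAsFactors = FALSE)
  rd <- function(a, b, bound) data.frame(
    read_id = "r1", gene_tag = "g1", aln_start = a, aln_end = b,
    polya_boundary = bound, full_length = TRUE, stringsAsFactors = FALSE)
  # boundary exactly at the UTR end, full coverage
  expect_true(flag_full_length_3utr(utrs, rd(4500L, 5000L, 5000L),
                                    m)$full_length)
  # boundary 20 bp inside the UTR at tolerance 5
  expect_false(flag_full_length_3utr(utrs, rd(4500L, 5000L, 4980L), m,
                                     tolerance = 5)$full_length)
  # full boundary but partial coverage
  expect_false(flag_full_length_3utr(utrs, rd(4900L, 5000L, 5000L),
                                     m)$full_length)
  # unknown gene in the read table
  bad <- rd(4500L, 5000L, 5000L)
  bad$gene_tag <- "ghost"
  expect_error(flag_full_length_3utr(utrs, bad, m), "unknown gene")
})

test_that("terminal windows clip to the last 100 bp and mark short UTRs", {
  utrs <- data.frame(gene_tag = c("a", "b"),
                     seq = c(random_dna(312), random_dna(60)),
                     stringsAsFactors = FALSE)
  tw <- terminal_window(utrs, 100)
  expect_equal(tw$length, c(100L, 60L))
  expect_equal(tw$seq[1], substr(utrs$seq[1], 213, 312))
  expect_equal(tw$short, c(FALSE, TRUE))
  expect_error(terminal_window(utrs, 0), "positive")
})

test_that("dinucleotide shuffling preserves dinucleotide composition", {
  set.seed(31)
  for (i in 1:25) {
    s <- random_dna(sample(20:120, 1), gc = runif(1, 0.2, 0.8))
    sh <- dinuc_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
})

test_that("a hexamer planted in 80% of tails ranks first with high z", {
  set.seed(7)
  tails <- vapply(rep(100, 200), random_dna, character(1))
  plant <- sample(200, 160)
  for (i in plant) {
    o <- sample(20:30, 1)
    substr(tails[i], 100 - o + 1, 100 - o + 6) <- "AATAAA"
  }
  enr <- kmer_enrichment(tails, k = 6, n_shuffles = 100, seed = 7)
  expect_equal(enr$kmer[1], "AATAAA")
  expect_equal(enr$kmer_rna[1], "AAUAAA")
  expect_gt(enr$z[1], 5)
})

test_that("two motifs planted at 40% each both reach the top three", {
  set.seed(8)
  tails <- vapply(rep(100, 200), random_dna, character(1))
  for (i in 1:80) {
    o <- sample(20:30, 1)
    substr(tails[i], 100 - o + 1, 100 - o + 6) <- "AATAAA"
  }
  for (i in 81:160) {
    o <- sample(20:30, 1)
    substr(tails[i], 100 - o + 1, 100 - o + 6) <- "AAATAA"
  }
  enr <- kmer_enrichment(tails, k = 6, n_shuffles = 100, seed = 8)
  expect_true(all(c("AATAAA", "AAATAA") %in% enr$kmer[1:3]))
})

test_that("uniform random tails produce no strong enrichment", {
  set.seed(7)
  tails <- vapply(rep(100, 200), random_dna, character(1))
  enr <- kmer_enrichment(tails, k = 6, n_shuffles = 100, seed = 7)
  # the maximum over ~4^6 k-mers sits near 4.6 under the null here
  # (multiplicity); well below the z > 5 scale of a planted motif
  expect_lt(max(enr$z), 5)
})

test_that("kmer enrichment validates its inputs", {
  expect_error(kmer_enrichment(c("ACGTACGT"), 6), "at least 20")
  expect_error(kmer_enrichment(rep("ACGTACGT", 25), 3), "k must be")
  expect_error(kmer_enrichment(rep("ACG", 25), 6), "shorter than k")
})

test_that("positional profile localises planted offsets", {
  set.seed(9)
  seqs <- vapply(rep(100, 150), random_dna, character(1))
  for (i in seq_along(seqs)) {
    o <- sample(20:30, 1)
    substr(seqs[i], 100 - o + 1, 100 - o + 6) <- "GGCGCC"  # rare motif
  }
  pp <- positional_profile(seqs, "GGCGCC")
  expect_true(pp$window[1] >= -30 && pp$window[2] <= -20)
  occ_in <- sum(pp$values[pp$positions >= pp$window[1] &
                          pp$positions <= pp$window[2]])
  expect_gte(occ_in * length(seqs), pp$n_occurrences / 2)

  # point mass
  seqs2 <- vapply(rep(60, 50), random_dna, character(1))
  for (i in seq_along(seqs2)) substr(seqs2[i], 60 - 25 + 1, 60 - 20) <-
      "GGCGCC"
  pp2 <- positional_profile(seqs2, "GGCGCC")
  expect_equal(pp2$peak_position, -25L)

  expect_warning(pp3 <- positional_profile(c("AAAA", "AAAT"), "GGCGCC"),
                 "absent")
  expect_true(all(pp3$values == 0))
  expect_true(all(pp$values >= 0 & pp$values <= 1))
})

test_that("U content profile reflects planted T-rich flanks", {
  expect_true(all(u_profile(rep(strrep("A", 50), 3))$values == 0))
  expect_true(all(u_profile(strrep("T", 100))$values == 1))
  s <- small_spec(seed = 7, n_genes = 200, polya_offset_range = c(25, 25))
  g <- make_genome(s)
  u3 <- extract_utrs(g$contigs, g$models, "three_prime")
  planted <- g$manifest$genes$locus_tag[!is.na(g$manifest$genes$polya_offset)]
  tails <- terminal_window(u3[u3$gene_tag %in% planted, ], 100)
  up <- u_profile(tails$seq)
  # with the motif fixed at -25..-20 the downstream flank is -19..-10
  flank_vals <- up$values[up$positions >= -19 & up$positions <= -10]
  base_vals <- up$values[up$positions >= -95 & up$positions <= -60]
  expect_gt(mean(flank_vals), 0.5)
  expect_lt(mean(base_vals), 0.45)
})

test_that("Kozak matrix columns are stochastic and consensus behaves", {
  genome <- c(c1 = paste0(strrep("T", 10), "ATG", strrep("C", 10)))
  m1 <- gene_models(data.frame(
    locus_tag = "g1", contig = "c1", strand = "+",
    type = c("exon", "five_prime_UTR", "CDS"),
    start = c(1L, 1L, 11L), end = c(23L, 10L, 23L), complete = FALSE),
    validate = FALSE)
  kz <- kozak_matrix(genome, m1)
  expect_true(all(abs(colSums(kz$matrix) - 1) < 1e-9))
  expect_true(all(kz$matrix %in% c(0, 1)))  # single gene: one-hot
  expect_equal(substr(kz$consensus, 11, 13), "atg")
  expect_equal(kz$upstream_at_fraction, 1)

  # two genes differing at one position -> 0.5/0.5 column
  genome2 <- c(c1 = paste0(strrep("T", 10), "ATG", strrep("C", 10)),
               c2 = paste0("G", strrep("T", 9), "ATG", strrep("C", 10)))
  feats2 <- data.frame(
    locus_tag = c(rep("g1", 3), rep("g2", 3)),
    contig = rep(c("c1", "c2"), each = 3), strand = "+",
    type = rep(c("exon", "five_prime_UTR", "CDS"), 2),
    start = c(1L, 1L, 11L, 1L, 1L, 11L),
    end = c(23L, 10L, 23L, 23L, 10L, 23L), complete = FALSE)
  kz2 <- kozak_matrix(genome2, gene_models(feats2, validate = FALSE))
  expect_equal(sort(kz2$matrix[, 1][kz2$matrix[, 1] > 0]), c(0.5, 0.5),
               ignore_attr = TRUE)
})

test_that("AT-rich upstream context yields no strong consensus letter", {
  s <- synthesis_spec(seed = 7, n_genes = 180, n_contigs = 5, gc = 0.3,
                      utr5_fraction = 1)
  g <- make_genome(s)
  kz <- kozak_matrix(g$contigs, g$models)
  expect_equal(kz$upstream_at_fraction, 0.7, tolerance = 0.05 / 0.7)
  up_cons <- strsplit(substr(kz$consensus, 1, 10), "")[[1]]
  single <- up_cons[up_cons %in% c("a", "c", "g", "t")]
  expect_true(all(single %in% c("a", "t")))
})

test_that("UTR statistics match the generator manifest", {
  s <- small_spec(seed = 13)
  g <- make_genome(s)
  u3 <- extract_utrs(g$contigs, g$models, "three_prime")
  u5 <- extract_utrs(g$contigs, g$models, "five_prime")
  st <- utr_stats(rbind(u3, u5))
  man <- g$manifest$genes
  expect_equal(st$three_prime$n, sum(man$utr3_len > 0))
  expect_equal(st$three_prime$mean_length,
               mean(man$utr3_len[man$utr3_len > 0]))
  expect_equal(st$five_prime$n, sum(man$utr5_len > 0))
  expect_equal(sum(st$three_prime$hist), st$three_prime$n)
  expect_true(st$gc3_percent > 0 && st$gc3_percent < 100)
  # two plain UTRs: mean of 100 and 200 is 150
  plain <- data.frame(gene_tag = c("x", "y"), kind = "three_prime",
                      seq = c(random_dna(100), random_dna(200)),
                      length = c(100L, 200L), introns = 0L,
                      stringsAsFactors = FALSE)
  expect_equal(utr_stats(plain)$three_prime$mean_length, 150)
})
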