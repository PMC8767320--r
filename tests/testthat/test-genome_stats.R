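test_that("N50 follows the cumulative >= half convention", {
  expect_equal(n50(c(40, 30, 20, 10)), 30)
  expect_equal(n50(c(10, 20, 30, 40)), 30)  # order-free
  expect_equal(n50(500), 500)
  expect_error(n50(integer(0)), "empty")
})

test_that("N50 equals the brute-force oracle on random length sets", {
  set.seed(42)
  for (i in 1:1000) {
    lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    expect_identical(n50(lens), oracle_n50(lens))
  }
})

test_that("assembly statistics are consistent and GC skips ambiguous bases", {
  st <- assembly_stats(c(a = "GGCC", b = "ATATNN"))
  expect_equal(st$n_contigs, 2L)
  expect_equal(st$total_len, 10L)
  expect_equal(st$gc_percent, 50)  # 4 GC over 8 unambiguous
  expect_equal(st$largest, 6L)
  expect_true(st$n50 <= st$largest && st$largest <= st$total_len)
  expect_error(assembly_stats(character(0)), "empty")
})

test_that("telomere detection needs a tandem run, tolerates 2 mismatches", {
  set.seed(7)
  plain <- random_dna(10000)
  tc <- detect_telomeric_ends(plain, "TTAGGG", min_units = 5)
  expect_false(tc$five_prime || tc$three_prime)

  capped <- paste0(strrep("TTAGGG", 12), plain)
  tc <- detect_telomeric_ends(capped, "TTAGGG", min_units = 5)
  expect_true(tc$five_prime)
  expect_equal(tc$units_5, 12L)
  expect_false(tc$three_prime)

  # two mismatches across the run still count, three break it
  unit <- "TTAGGG"
  run <- strrep(unit, 12)
  substr(run, 15, 15) <- "C"; substr(run, 33, 33) <- "C"
  tc <- detect_telomeric_ends(paste0(run, plain), unit, min_units = 10)
  expect_true(tc$five_prime)
  # a third mismatch, spaced so every 10-unit run holds all three
  substr(run, 51, 51) <- "C"
  tc <- detect_telomeric_ends(paste0(run, plain), unit, min_units = 10)
  expect_false(tc$five_prime)
})

test_that("reverse-complementing a contig swaps the end flags", {
  set.seed(3)
  fixtures <- c(
    paste0(strrep("TTAGGG", 12), random_dna(3000)),
    paste0(random_dna(3000), strrep("CCCTAA", 12)),
    paste0(strrep("TTAGGG", 8), random_dna(2000), strrep("CCCTAA", 8)),
    random_dna(3000)
  )
  for (s in fixtures) {
    a <- detect_telomeric_ends(s, "TTAGGG", min_units = 5)
    b <- detect_telomeric_ends(revcomp(s), "TTAGGG", min_units = 5)
    expect_equal(a$five_prime, b$three_prime)
    expect_equal(a$three_prime, b$five_prime)
  }
})

test_that("chromosome estimate combines both- and one-ended contigs", {
  est <- estimate_chromosomes(10, 65)
  expect_equal(est$point, 42.5)
  expect_equal(c(est$low, est$high), c(40L, 50L))
  expect_true(est$low <= est$point && est$point <= est$high)
  expect_equal(estimate_chromosomes(0, 0)$point, 0)
  expect_equal(estimate_chromosomes(2, 4)$point, 4)
  expect_error(estimate_chromosomes(-1, 3), "non-negative")
})

test_that("coding density handles null, half-covered and partial windows", {
  lens <- c(c1 = 10000L)
  empty <- gene_models(data.frame(locus_tag = character(),
                                  contig = character(),
                                  strand = character(), type = character(),
                                  start = integer(), end = integer()),
                       validate = FALSE)
  cd <- coding_density(empty, lens)
  expect_true(all(cd$windows$fraction == 0))

  m <- gene_models(data.frame(
    locus_tag = "g1", contig = "c1", strand = "+",
    type = c("exon", "CDS"), start = c(1001L, 1001L),
    end = c(3500L, 3500L), complete = FALSE))
  cd <- coding_density(m, c(c1 = 5000L))
  expect_equal(cd$windows$fraction[1], 0.5)
  expect_error(coding_density(m, c(other = 5000L)), "unknown contig")
})

test_that("window fractions conserve total CDS coverage", {
  g <- make_genome(small_spec(seed = 9))
  lens <- stats::setNames(nchar(g$contigs$seq), g$contigs$id)
  cd <- coding_density(g$models, lens, window = 5000)
  per_window <- tapply(cd$windows$fraction *
                         (cd$windows$window_end - cd$windows$window_start + 1),
                       cd$windows$contig, sum)
  expect_equal(as.numeric(per_window[cd$per_contig$contig]),
               as.numeric(cd$per_contig$cds_bases),
               ignore_attr = TRUE)
})

test_that("generator tuned to the study coding fraction reproduces it", {
  # mean CDS ~2132 bp (truncated geometric codon count) against
  # ~444 bp of introns+UTRs and an 800 bp mean gap targets
  # 2132/3405 = 0.626 of contig length covered by CDS
  s <- synthesis_spec(seed = 7, n_genes = 800, n_contigs = 10,
                      intergenic_mean_len = 800)
  g <- make_genome(s)
  lens <- stats::setNames(nchar(g$contigs$seq), g$contigs$id)
  cd <- coding_density(g$models, lens)
  overall <- sum(cd$per_contig$cds_bases) / sum(lens)
  expect_equal(overall, 0.626, tolerance = 0.01 / 0.626)
})

test_that("gene metrics: spans, intergenic gaps and null intron cases", {
  m <- gene_models(data.frame(
    locus_tag = rep(c("g1", "g2"), each = 2),
    contig = "c1", strand = "+",
    type = rep(c("exon", "CDS"), 2),
    start = c(1L, 1L, 201L, 201L), end = c(100L, 99L, 300L, 299L)),
    validate = FALSE)
  gm <- gene_metrics(m)
  expect_equal(gm$mean_intergenic_length, 100)
  expect_equal(gm$n_introns, 0L)
  expect_equal(gm$introns_per_gene, 0)
  expect_equal(gm$mean_gene_length, 100)
})

test_that("gene metrics match the generator manifest exactly", {
  g <- make_genome(small_spec(seed = 4))
  man <- g$manifest$genes
  gm <- gene_metrics(g$models, g$contigs)
  expect_equal(gm$n_genes, nrow(man))
  expect_equal(gm$n_introns, sum(man$n_introns))
  expect_equal(gm$introns_per_gene, sum(man$n_introns) / nrow(man))
  expect_equal(gm$mean_gene_length, mean(man$end - man$start + 1))
  expect_equal(gm$n_genes_utr3, sum(man$utr3_len > 0))
  expect_equal(gm$n_genes_utr5, sum(man$utr5_len > 0))
  expect_equal(gm$mean_utr3_length,
               mean(man$utr3_len[man$utr3_len > 0]))
  expect_equal(gm$mean_utr5_length,
               mean(man$utr5_len[man$utr5_len > 0]))
  # intron GC is pulled toward the generator's AT-rich intron composition
  expect_lt(gm$intron_gc_percent, 33)
})
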