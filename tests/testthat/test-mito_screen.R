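test_that("reciprocal best hits require mutual best and the e-value cap", {
  empty <- random_hit_table(0, "q", "s")
  expect_equal(nrow(reciprocal_best_hits(empty, empty)), 0L)

  fwd <- random_hit_table(3, "x", "y")
  fwd$query <- c("p1", "p1", "p2")
  fwd$subject <- c("d1", "d2", "d1")
  fwd$evalue <- c(1e-10, 1e-4, 1e-8)
  rev <- random_hit_table(2, "x", "y")
  rev$query <- c("d1", "d2")
  rev$subject <- c("p1", "p1")
  rev$evalue <- c(1e-9, 1e-5)
  rb <- reciprocal_best_hits(fwd, rev)
  expect_equal(rb$query, "p1")
  expect_equal(rb$subject, "d1")

  # mutual best pair at e = 0.01 is excluded by the 0.001 threshold
  fwd$evalue <- c(0.01, 0.5, 0.9)
  rev$evalue <- c(0.01, 0.5)
  expect_equal(nrow(reciprocal_best_hits(fwd, rev)), 0L)
  # e-value exactly at 0.001 is included
  fwd$evalue <- c(0.001, 0.5, 0.9)
  rev$evalue <- c(0.001, 0.5)
  expect_equal(nrow(reciprocal_best_hits(fwd, rev)), 1L)
})

test_that("RBH is symmetric and matches the brute-force oracle", {
  set.seed(50)
  for (i in 1:20) {
    qs <- paste0("p", 1:8)
    ss <- paste0("d", 1:8)
    fwd <- random_hit_table(sample(10:40, 1), qs, ss)
    rev <- random_hit_table(sample(10:40, 1), ss, qs)
    got <- reciprocal_best_hits(fwd, rev)
    exp <- oracle_rbh(fwd, rev)
    expect_equal(got$query, exp$query)
    expect_equal(got$subject, exp$subject)
    # swap tables and orientation
    swapped <- reciprocal_best_hits(rev, fwd)
    expect_setequal(paste(got$query, got$subject),
                    paste(swapped$subject, swapped$query))
  }
})

test_that("targeting consensus uses strict AND logic above 0.5", {
  sa <- data.frame(protein_id = c("p1", "p2", "p3"), tool = "a",
                   probability = c(0.6, 0.51, 0.5))
  sb <- data.frame(protein_id = c("p1", "p2", "p3"), tool = "b",
                   probability = c(0.4, 0.51, 0.5))
  tc <- targeting_consensus(sa, sb)
  expect_equal(tc$ids, "p2")     # (0.6, 0.4) out; (0.51, 0.51) in
  expect_equal(tc$n_total, 3L)   # (0.5, 0.5) out: strict >
  # missing protein counts as probability 0
  tc2 <- targeting_consensus(sa[1:2, ], sb, proteome_ids = paste0("p", 1:4))
  expect_equal(tc2$ids, "p2")
  expect_equal(tc2$n_total, 4L)
  sa$probability[1] <- 1.2
  expect_error(targeting_consensus(sa, sb), "\\[0, 1\\]")
  # raising the threshold never adds ids
  set.seed(51)
  sa <- data.frame(protein_id = paste0("p", 1:50), tool = "a",
                   probability = runif(50))
  sb <- data.frame(protein_id = paste0("p", 1:50), tool = "b",
                   probability = runif(50))
  lo <- targeting_consensus(sa, sb, threshold = 0.3)$ids
  hi <- targeting_consensus(sa, sb, threshold = 0.7)$ids
  expect_true(all(hi %in% lo))
})

test_that("the published flagged/analysed counts give the published rate", {
  s <- synthesis_spec(seed = 1)
  p <- make_proteome(s)  # 24 planted among 4665, the study's counts
  tc <- targeting_consensus(p$scores_a, p$scores_b,
                            proteome_ids = p$proteins$id)
  expect_equal(tc$n_flagged, 24L)
  expect_equal(tc$n_total, 4665L)
  expect_equal(tc$rate_percent, 0.5)
})

test_that("tail-anchor distance is measured from the TMD end, inclusive", {
  lens <- c(p1 = 100L, p2 = 100L, p3 = 100L)
  tmds <- data.frame(protein_id = c("p1", "p2", "p3"),
                     start = c(70L, 30L, 49L), end = c(90L, 50L, 68L),
                     stringsAsFactors = FALSE)
  kept <- tail_anchor_filter(lens, tmds, window = 32)
  expect_true("p1" %in% kept)   # distance 10
  expect_false("p2" %in% kept)  # distance 50
  expect_true("p3" %in% kept)   # distance exactly 32
  tmds$end[1] <- 120L
  expect_error(tail_anchor_filter(lens, tmds), "bounds")
})

test_that("hydropathy fallback finds hydrophobic runs only", {
  prot <- paste0(strrep("D", 20), strrep("L", 30), strrep("E", 20))
  tmd <- hydropathy_tmd_fallback(prot)
  expect_equal(nrow(tmd), 1L)
  expect_true(tmd$start <= 25 && tmd$end >= 45)  # covers the L-run core
  expect_equal(tmd$source, "hydropathy_fallback")
  expect_equal(nrow(hydropathy_tmd_fallback(strrep("D", 60))), 0L)
  expect_equal(nrow(hydropathy_tmd_fallback(prot, threshold = Inf)), 0L)
})

test_that("beta-signal scan matches classes and the C-terminal window", {
  hits <- beta_signal_scan(paste0(strrep("M", 20), "SAGLALIL"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$residues, "SAGLALIL")
  expect_true(hits$primary)
  # same 8-mer 40 residues from the end: out of the window
  far <- paste0(strrep("M", 20), "SAGLALIL", strrep("D", 40))
  expect_equal(nrow(beta_signal_scan(far)), 0L)
  expect_equal(nrow(beta_signal_scan("MKLV")), 0L)
})

test_that("beta-signal scan equals the regex oracle on random proteins", {
  set.seed(52)
  for (i in 1:300) {
    p <- random_protein(sample(30:200, 1))
    expect_equal(beta_signal_scan(p)$start, oracle_beta_scan(p))
  }
})

test_that("MBOMP filters use inclusive 25/10/50 percent thresholds", {
  mk <- function(nE, nH, sig_ss, ctx = 300L) {
    ss_ctx <- paste(c(rep("E", nE), rep("H", nH),
                      rep("C", ctx - nE - nH)), collapse = "")
    prot <- paste0(random_protein(ctx), "SAGLALIL")
    ss <- paste0(ss_ctx, sig_ss)
    mbomp_filter(prot, ctx + 1L, ss)
  }
  # 80 E / 20 H / 200 C with a non-helical signal passes
  r <- mk(80L, 20L, "CCCCEEEE")
  expect_true(r$pass)
  expect_equal(r$strand_frac, 80 / 300)
  # exactly at the boundaries: 25% strand, 10% helix, 4/8 helical signal
  expect_true(mk(75L, 30L, "HHHHCCCC")$pass)
  # one residue beyond each boundary fails
  expect_false(mk(74L, 30L, "HHHHCCCC")$pass)
  expect_false(mk(75L, 31L, "HHHHCCCC")$pass)
  expect_false(mk(75L, 30L, "HHHHHCCC")$pass)  # 5/8 = 62.5% > 50%
  expect_error(mbomp_filter("MKLV", 1L, "CCC"), "length")
})

test_that("a short protein truncates the secondary-structure context", {
  prot <- paste0(random_protein(60), "SAGLALIL")
  ss <- paste0(paste(rep(c("E", "C"), 30), collapse = ""), "CCCCEEEE")
  r <- mbomp_filter(prot, 61L, ss)
  expect_equal(r$context_len, 60L)
  expect_true(r$short_context)
  expect_true(r$pass)  # 50% strand, 0% helix
})

test_that("HMM join counts candidates and database homologs", {
  none <- data.frame(protein_id = character(), profile = character(),
                     evalue = numeric())
  expect_equal(nrow(hmm_candidate_join(none, none)), 0L)
  hmm <- data.frame(protein_id = paste0("p", 1:28),
                    profile = paste0("PF", 1:28), evalue = 1e-6)
  db <- data.frame(protein_id = paste0("p", 1:6),
                   subject = paste0("MM_", 1:6), evalue = 1e-5)
  j <- hmm_candidate_join(hmm, db)
  expect_equal(nrow(j), 28L)
  expect_equal(sum(j$has_db_homolog), 6L)
  # duplicated (protein, profile) rows count once
  j2 <- hmm_candidate_join(rbind(hmm, hmm[1, ]), db)
  expect_equal(j2$n_profiles[j2$protein_id == "p1"], 1L)
  # a db hit above the e-value cap is not a homolog
  db$evalue[1] <- 0.01
  expect_equal(sum(hmm_candidate_join(hmm, db)$has_db_homolog), 5L)
})

test_that("the aggregate report unions channels and never auto-accepts", {
  ids <- paste0("p", 1:10)
  rep0 <- aggregate_report(ids)
  expect_true(all(rep0$table$verdict == "rejected"))
  expect_equal(rep0$summary$n_flagged[rep0$summary$channel == "union"], 0L)

  rep1 <- aggregate_report(ids, rbh = "p1", targeting = "p1",
                           tail_anchor = "p1", mbomp = "p1", hmm = "p1")
  expect_equal(sum(rep1$table$verdict == "manual_review"), 1L)
  expect_equal(rep1$summary$n_flagged[rep1$summary$channel == "union"], 1L)
  expect_false("candidate" %in% rep1$table$verdict)
  expect_error(aggregate_report(ids, rbh = "ghost"), "unknown")
})

test_that("per-channel counts on the generated proteome equal the manifest", {
  s <- small_spec(seed = 1)
  p <- make_proteome(s)
  tc <- targeting_consensus(p$scores_a, p$scores_b,
                            proteome_ids = p$proteins$id)
  ta <- tail_anchor_filter(p$proteins, p$tmd)
  rb <- reciprocal_best_hits(p$hits_fwd, p$hits_rev)
  mb <- mbomp_screen(p$proteins, p$ss3)
  hj <- hmm_candidate_join(p$hmm_hits,
                           data.frame(protein_id = p$hits_fwd$query,
                                      subject = p$hits_fwd$subject,
                                      evalue = p$hits_fwd$evalue))
  rep <- aggregate_report(p$proteins$id, rbh = rb$query,
                          hmm = hj$protein_id, targeting = tc$ids,
                          tail_anchor = ta, mbomp = mb)
  sm <- stats::setNames(rep$summary$n_flagged, rep$summary$channel)
  man <- p$manifest
  expect_equal(unname(sm["targeting"]), length(man$targeting))
  expect_equal(unname(sm["tail_anchor"]), length(man$tail_anchor))
  expect_equal(unname(sm["mbomp"]), length(man$mbomp))
  expect_equal(unname(sm["rbh"]), nrow(man$rbh))
  expect_equal(unname(sm["hmm"]), length(man$hmm))
})
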