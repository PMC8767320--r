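test_that("exact clustering requires equal length and full identity", {
  old <- c(A = "ATGAAATAA")
  new <- c(N1 = "ATGAAATAA")
  res <- cluster_exact(old, new)
  expect_equal(res$transferred, "A")
  expect_equal(res$matches$A, "N1")

  res <- cluster_exact(c(A = "ATGAAATAA"), c(N1 = "ATGAAGTAA"))
  expect_length(res$transferred, 0)

  # one old sequence identical to two new copies: transferred, noted
  res <- cluster_exact(c(A = "ATGAAATAA"),
                       c(N1 = "ATGAAATAA", N2 = "ATGAAATAA"))
  expect_equal(res$transferred, "A")
  expect_equal(res$duplicated, "A")
  expect_error(cluster_exact(c(A = "AT", A = "GC"), new), "duplicate")
})

test_that("exact clustering agrees with the all-pairs oracle", {
  set.seed(20)
  for (i in 1:25) {
    n_old <- sample(5:40, 1)
    pool <- vapply(rep(30, 12), random_dna, character(1))
    old <- stats::setNames(sample(pool, n_old, replace = TRUE),
                           paste0("o", seq_len(n_old)))
    new <- stats::setNames(sample(pool, n_old, replace = TRUE),
                           paste0("n", seq_len(n_old)))
    expect_setequal(cluster_exact(old, new)$transferred,
                    oracle_transferred_exact(old, new))
  }
})

test_that("clustering is invariant to input order", {
  set.seed(21)
  old <- stats::setNames(vapply(rep(60, 15), random_dna, character(1)),
                         paste0("o", 1:15))
  new <- c(old[sample(15, 8)], N = random_dna(60))
  names(new)[1:8] <- paste0("n", 1:8)
  for (i in 1:5) {
    perm_o <- sample(length(old))
    perm_n <- sample(length(new))
    expect_setequal(cluster_exact(old[perm_o], new[perm_n])$transferred,
                    cluster_exact(old, new)$transferred)
    expect_setequal(cluster_near(old[perm_o], new[perm_n])$transferred,
                    cluster_near(old, new)$transferred)
  }
})

test_that("near clustering applies the 0.95 identity and equal-length rules", {
  set.seed(22)
  base <- random_dna(100)
  mutate <- function(s, k) {
    pos <- sample(nchar(s), k)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  # 4 substitutions in 100 -> identity 0.96
  res <- cluster_near(c(o = mutate(base, 4)), c(n = base))
  expect_equal(res$transferred, "o")
  # 6 substitutions -> 0.94
  res <- cluster_near(c(o = mutate(base, 6)), c(n = base))
  expect_length(res$transferred, 0)
  # equal-length rule dominates identity
  res <- cluster_near(c(o = substr(base, 1, 99)), c(n = base))
  expect_length(res$transferred, 0)
  expect_equal(seq_identity(base, base), 1)
})

test_that("lowering the near-identity threshold never shrinks transfers", {
  set.seed(23)
  for (i in 1:5) {
    base <- vapply(rep(60, 10), random_dna, character(1))
    old <- stats::setNames(vapply(base, function(s) {
      k <- sample(0:6, 1)
      if (k == 0) return(s)
      ch <- strsplit(s, "")[[1]]
      pos <- sample(60, k)
      ch[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE), paste0("o", 1:10))
    new <- stats::setNames(base, paste0("n", 1:10))
    t_hi <- cluster_near(old, new, identity = 0.97)$transferred
    t_lo <- cluster_near(old, new, identity = 0.90)$transferred
    expect_true(all(t_hi %in% t_lo))
  }
})

test_that("fusion and split events are detected from CDS overlaps", {
  mk <- function(tag, s, e, strand = "+") data.frame(
    locus_tag = tag, contig = "c1", strand = strand,
    type = c("exon", "CDS"), start = s, end = e, stringsAsFactors = FALSE)
  old <- gene_models(rbind(mk("MONOS_13233", 101L, 400L),
                           mk("MONOS_15373", 601L, 900L)),
                     validate = FALSE)
  new <- gene_models(mk("X1", 101L, 900L), validate = FALSE)
  ev <- detect_fusion_split(old, new)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "fusion")
  expect_setequal(ev[[1]]$old_tags, c("MONOS_13233", "MONOS_15373"))

  old2 <- gene_models(mk("MONOS_1266", 101L, 900L), validate = FALSE)
  new2 <- gene_models(rbind(mk("Y1", 101L, 400L), mk("Y2", 601L, 900L)),
                      validate = FALSE)
  ev2 <- detect_fusion_split(old2, new2)
  expect_equal(ev2[[1]]$type, "split")
  expect_equal(ev2[[1]]$new_tags, c("Y1", "Y2"))

  # perfect one-to-one: no events
  expect_length(detect_fusion_split(old, old), 0)
  # opposite strands never pair
  new3 <- gene_models(mk("Z1", 101L, 900L, strand = "-"), validate = FALSE)
  expect_length(detect_fusion_split(old, new3), 0)
})

test_that("locus-tag naming follows the fu / p conventions", {
  ev <- list(list(type = "fusion",
                  old_tags = c("MONOS_13233", "MONOS_15373"),
                  new_tags = "X1"))
  expect_equal(assign_locus_tags(ev)[[1]]$new_names, "MONOS_13233fu15373")
  # numeric sort, not input order
  ev[[1]]$old_tags <- c("MONOS_15373", "MONOS_13233")
  expect_equal(assign_locus_tags(ev)[[1]]$new_names, "MONOS_13233fu15373")
  ev2 <- list(list(type = "split", old_tags = "MONOS_1266",
                   new_tags = c("Y1", "Y2")))
  expect_equal(assign_locus_tags(ev2)[[1]]$new_names,
               c("MONOS_1266p1", "MONOS_1266p2"))
  ev3 <- list(list(type = "fusion", old_tags = c("WEIRD13", "MONOS_2"),
                   new_tags = "X"))
  expect_error(assign_locus_tags(ev3, prefix = "MONOS"), "not matching")
})

test_that("an identity corpus transfers completely at the first stage", {
  s <- small_spec(seed = 11, n_fusion_events = 0, n_split_events = 0,
                  n_frameshift_events = 0)
  g <- make_genome(s)
  old <- derive_old_assembly(g, s)
  oc <- extract_cds(old$contigs, old$models)
  nc <- extract_cds(g$contigs, g$models)
  rec <- run_transfer(stats::setNames(oc$seq, oc$id),
                      list(denovo_evm = stats::setNames(nc$seq, nc$id)))
  expect_true(all(rec$outcome == "transferred"))
  expect_true(all(rec$stage == "denovo_evm"))
})

test_that("planted fusions, splits and frameshifts are recovered exactly", {
  s <- small_spec(seed = 7)
  g <- make_genome(s)
  old <- derive_old_assembly(g, s)
  oc <- extract_cds(old$contigs, old$models)
  nc <- extract_cds(g$contigs, g$models)
  ev <- assign_locus_tags(detect_fusion_split(old$mapped_models, g$models))
  rec <- run_transfer(stats::setNames(oc$seq, oc$id),
                      list(stage1 = stats::setNames(nc$seq, nc$id)),
                      events = ev)
  m <- merge(rec, old$correspondence, by = "old_tag")
  expect_equal(nrow(m), nrow(rec))
  expect_equal(m$outcome, m$expected_outcome)
  sm <- transfer_summary(rec)
  expect_equal(unname(sm$by_outcome["split"]), s$n_fusion_events)
  expect_equal(unname(sm$by_outcome["fused"]), 2L * s$n_split_events)
  expect_equal(sm$fused_models, s$n_split_events)
  expect_equal(sm$split_models, 2L * s$n_fusion_events)
  expect_equal(sum(sm$by_outcome), sm$n_old)
  # split products are named from the old tag in coordinate order
  split_names <- unlist(lapply(ev[vapply(ev, function(e)
    e$type == "split", logical(1))], `[[`, "new_names"))
  expect_true(all(grepl("^MONOS_[0-9]+p[12]$", split_names)))
})

test_that("transfer summary enforces conservation", {
  empty <- run_transfer(character(0) |> stats::setNames(character(0)),
                        list(stage1 = c(n = "ATG")))
  sm <- transfer_summary(empty)
  expect_true(all(sm$by_outcome == 0))
  dup <- data.frame(old_tag = c("a", "a"), outcome = "transferred",
                    stage = "s1", new_tags = "n", stringsAsFactors = FALSE)
  expect_error(transfer_summary(dup), "conservation")
  bad <- data.frame(old_tag = "a", outcome = "mystery", stage = "s1",
                    new_tags = "", stringsAsFactors = FALSE)
  expect_error(transfer_summary(bad), "conservation")
})
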