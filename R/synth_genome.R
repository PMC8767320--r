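#' Generate a synthetic genome with annotation and ground truth
#'
#' Builds contigs carrying telomeric caps at 0/1/2 ends, places
#' non-overlapping genes with introns and 5'/3'UTRs on both strands, and
#' plants the polyadenylation hexamer (with optional T-rich flanks) at a
#' uniform offset upstream of each planted gene's cleavage site. Identical
#' spec and seed give byte-identical output.
#'
#' @param spec \code{\link{synthesis_spec}}.
#' @return list: \code{contigs} (\code{\link{seq_records}}), \code{models}
#'   (\code{\link{gene_models}}), \code{manifest} (list with \code{contigs}
#'   and \code{genes} data.frames and the spec).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  set.seed(spec$seed)
  pool <- .codon_pool()
  n <- spec$n_genes
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    cds_len <- 3L * (150L + min(stats::rgeom(1L, 1 / 580), 2000L))
    n_int <- stats::rpois(1L, spec$intron_rate)
    intron_lens <- if (n_int) 60L + stats::rgeom(n_int, 1 / 60) else integer(0)
    u5 <- if (stats::runif(1) < spec$utr5_fraction)
      15L + stats::rgeom(1L, 1 / 47) else 0L
    u3 <- if (stats::runif(1) < spec$utr3_fraction)
      50L + stats::rgeom(1L, 1 / 262) else 0L
    cds_seq <- paste0("ATG",
                      paste(sample(pool, cds_len / 3L - 2L, replace = TRUE),
                            collapse = ""),
                      sample(.STOPS, 1L))
    # intron insertion points: strictly inside the CDS
    cuts <- if (n_int) sort(sample(seq_len(cds_len - 1L), n_int)) else integer(0)
    piece_bounds <- cbind(c(1L, cuts + 1L), c(cuts, cds_len))
    # walk local coordinates: UTR5 | (CDS piece, intron)* | UTR3
    feats <- list()
    pos <- 1L
    add <- function(type, len) {
      if (len > 0L) {
        feats[[length(feats) + 1L]] <<- c(type = type, start = pos,
                                          end = pos + len - 1L)
        pos <<- pos + len
      }
    }
    seq_parts <- character(0)
    if (u5 > 0L) {
      add("five_prime_UTR", u5)
      seq_parts <- c(seq_parts, .rand_dna(u5, spec$gc))
    }
    for (p in seq_len(nrow(piece_bounds))) {
      plen <- piece_bounds[p, 2L] - piece_bounds[p, 1L] + 1L
      add("CDS", plen)
      seq_parts <- c(seq_parts, substr(cds_seq, piece_bounds[p, 1L],
                                       piece_bounds[p, 2L]))
      if (p <= length(intron_lens)) {
        add("intron", intron_lens[p])
        seq_parts <- c(seq_parts, .rand_dna(intron_lens[p], spec$intron_gc))
      }
    }
    if (u3 > 0L) {
      add("three_prime_UTR", u3)
      seq_parts <- c(seq_parts, .rand_dna(u3, spec$gc))
    }
    L <- pos - 1L
    gseq <- paste(seq_parts, collapse = "")
    # plant the polyadenylation signal
    polya_offset <- NA_integer_
    if (u3 > 0L && stats::runif(1) < spec$polya_plant_fraction) {
      off_rng <- seq(spec$polya_offset_range[1L],
                     spec$polya_offset_range[2L])
      o <- off_rng[sample.int(length(off_rng), 1L)]
      mstart <- L - o + 1L
      mlen <- nchar(spec$polya_motif)
      substr(gseq, mstart, mstart + mlen - 1L) <- spec$polya_motif
      if (spec$u_rich_flank) {
        t_rich <- function(k) paste(sample(c("T", "A", "C", "G"), k,
                                           replace = TRUE,
                                           prob = c(0.6, 0.4 / 3, 0.4 / 3,
                                                    0.4 / 3)), collapse = "")
        f1 <- max(L - u3 + 1L, mstart - 10L)
        if (f1 < mstart)
          substr(gseq, f1, mstart - 1L) <- t_rich(mstart - f1)
        f2 <- min(L, mstart + mlen + 9L)
        if (f2 >= mstart + mlen)
          substr(gseq, mstart + mlen, f2) <- t_rich(f2 - mstart - mlen + 1L)
      }
      polya_offset <- o
    }
    fm <- do.call(rbind, lapply(feats, function(x)
      data.frame(type = x[["type"]], start = as.integer(x[["start"]]),
                 end = as.integer(x[["end"]]), stringsAsFactors = FALSE)))
    genes[[i]] <- list(seq = gseq, len = L, feats = fm, cds_len = cds_len,
                       n_introns = n_int, u5 = u5, u3 = u3,
                       polya_offset = polya_offset, cds_seq = cds_seq)
  }
  # batch translation and strand assignment (one S4 call each)
  prots <- as.character(Biostrings::translate(Biostrings::DNAStringSet(
    vapply(genes, `[[`, character(1), "cds_seq"))))
  prots <- sub("\\*$", "", prots)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  placed_seqs <- vapply(genes, `[[`, character(1), "seq")
  minus <- which(strands == "-")
  if (length(minus))
    placed_seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(placed_seqs[minus])))
  # assign genes to contigs round-robin, then lay out each contig
  contig_of <- rep(seq_len(spec$n_contigs), length.out = n)
  tel5_flag <- tel3_flag <- rep(FALSE, spec$n_contigs)
  if (spec$n_both_telomeres > 0L) {
    tel5_flag[seq_len(spec$n_both_telomeres)] <- TRUE
    tel3_flag[seq_len(spec$n_both_telomeres)] <- TRUE
  }
  if (spec$n_one_telomere > 0L) {
    idx <- spec$n_both_telomeres + seq_len(spec$n_one_telomere)
    at5 <- rep(c(TRUE, FALSE), length.out = spec$n_one_telomere)
    tel5_flag[idx] <- at5
    tel3_flag[idx] <- !at5
  }
  tel5_seq <- strrep(spec$telomere_unit, spec$telomere_units_per_end)
  tel3_seq <- strrep(revcomp(spec$telomere_unit), spec$telomere_units_per_end)
  feat_rows <- list()
  gene_rows <- list()
  contig_seqs <- character(spec$n_contigs)
  contig_ids <- sprintf("ctg_%02d", seq_len(spec$n_contigs))
  gi <- 0L
  for (ci in seq_len(spec$n_contigs)) {
    parts <- character(0)
    pos <- 1L
    if (tel5_flag[ci]) {
      parts <- c(parts, tel5_seq)
      pos <- pos + nchar(tel5_seq)
    }
    lead <- 300L + sample(500L, 1L)
    parts <- c(parts, .rand_dna(lead, spec$gc))
    pos <- pos + lead
    for (k in which(contig_of == ci)) {
      gi <- gi + 1L
      tag <- paste0("MONOS_", gi)
      g <- genes[[k]]
      strand <- strands[k]
      placed <- placed_seqs[k]
      g_start <- pos
      g_end <- pos + g$len - 1L
      fm <- g$feats
      if (strand == "+") {
        gs <- g_start + fm$start - 1L
        ge <- g_start + fm$end - 1L
      } else {
        gs <- g_start + (g$len - fm$end)
        ge <- g_start + (g$len - fm$start)
      }
      keep <- fm$type != "intron"
      feat_rows[[gi]] <- data.frame(
        locus_tag = tag, contig = contig_ids[ci], strand = strand,
        type = c(fm$type[keep], rep("exon", 0L)),
        start = gs[keep], end = ge[keep], stringsAsFactors = FALSE)
      # exons = complement of introns over the gene span
      ints <- fm[fm$type == "intron", , drop = FALSE]
      if (nrow(ints)) {
        local_ex <- data.frame(start = c(1L, ints$end + 1L),
                               end = c(ints$start - 1L, g$len))
      } else {
        local_ex <- data.frame(start = 1L, end = g$len)
      }
      if (strand == "+") {
        ex_s <- g_start + local_ex$start - 1L
        ex_e <- g_start + local_ex$end - 1L
      } else {
        ex_s <- g_start + (g$len - local_ex$end)
        ex_e <- g_start + (g$len - local_ex$start)
      }
      feat_rows[[gi]] <- rbind(feat_rows[[gi]], data.frame(
        locus_tag = tag, contig = contig_ids[ci], strand = strand,
        type = "exon", start = ex_s, end = ex_e, stringsAsFactors = FALSE))
      cleavage <- if (g$u3 > 0L) {
        if (strand == "+") g_end else g_start
      } else NA_integer_
      gene_rows[[gi]] <- data.frame(
        locus_tag = tag, contig = contig_ids[ci], strand = strand,
        start = g_start, end = g_end, cds_len = g$cds_len,
        n_introns = g$n_introns, utr5_len = g$u5, utr3_len = g$u3,
        polya_offset = g$polya_offset, cleavage = cleavage,
        protein = prots[k], stringsAsFactors = FALSE)
      parts <- c(parts, placed)
      pos <- g_end + 1L
      gap <- 300L + min(stats::rgeom(1L, 1 / (spec$intergenic_mean_len -
                                              300)), 6000L)
      parts <- c(parts, .rand_dna(gap, spec$gc))
      pos <- pos + gap
    }
    if (tel3_flag[ci]) parts <- c(parts, tel3_seq)
    contig_seqs[ci] <- paste(parts, collapse = "")
  }
  models <- gene_models(do.call(rbind, feat_rows))
  manifest <- list(
    spec = spec,
    contigs = data.frame(contig_id = contig_ids,
                         length = nchar(contig_seqs),
                         tel5 = tel5_flag, tel3 = tel3_flag,
                         stringsAsFactors = FALSE),
    genes = do.call(rbind, gene_rows)
  )
  rownames(manifest$genes) <- NULL
  list(contigs = seq_records(contig_ids, contig_seqs),
       models = models, manifest = manifest)
}
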