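# apply a single-base insertion (delta = +1) or deletion (delta = -1) at
# position pos of a contig sequence, shifting feature coordinates
.apply_indel <- function(seq, feats, pos, delta, base = "A") {
  if (delta == 1L) {
    seq <- paste0(substr(seq, 1L, pos - 1L), base,
                  substr(seq, pos, nchar(seq)))
    feats$end[feats$end >= pos] <- feats$end[feats$end >= pos] + 1L
    feats$start[feats$start >= pos] <- feats$start[feats$start >= pos] + 1L
  } else {
    seq <- paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + 1L,
                                                    nchar(seq)))
    feats$end[feats$end >= pos] <- feats$end[feats$end >= pos] - 1L
    feats$start[feats$start > pos] <- feats$start[feats$start > pos] - 1L
  }
  list(seq = seq, feats = feats)
}

#' Derive an "old" assembly and annotation from a synthetic genome
#'
#' Emulates the relationship between a fragmented legacy assembly and its
#' long-read successor: contigs are cut into shorter pieces; for each
#' fusion event two adjacent same-strand genes are merged into one old
#' model through a fake intron (that old tag is expected to split on
#' transfer); for each split event one gene is broken into two old models
#' at a codon boundary (those old tags are expected to fuse on transfer);
#' frameshift events put a single-base indel into the old copy of a CDS
#' (those old tags can never satisfy the equal-length clustering rule and
#' are expected to fail). Besides the old assembly itself, the old models
#' are also returned lifted onto the new coordinate system, standing in for
#' the output of an external mapper.
#'
#' @param genome output of \code{\link{make_genome}}.
#' @param spec the \code{\link{synthesis_spec}} used to build it.
#' @return list: \code{contigs} (old assembly), \code{models} (old
#'   annotation, old coordinates), \code{mapped_models} (old models on new
#'   coordinates), \code{correspondence} (data.frame old_tag,
#'   expected_outcome, new_tags, event_id, expected_name).
#' @export
derive_old_assembly <- function(genome, spec) {
  set.seed(spec$seed + 101L)
  models <- genome$models
  spans <- model_spans(models)
  spans <- spans[order(spans$contig, spans$start), ]
  taken <- character(0)
  # fusion events: adjacent same-strand, same-contig pairs
  pairs <- list()
  for (ctg in unique(spans$contig)) {
    s <- spans[spans$contig == ctg, ]
    if (nrow(s) < 2L) next
    for (j in seq_len(nrow(s) - 1L)) {
      a <- s$locus_tag[j]; b <- s$locus_tag[j + 1L]
      if (s$strand[j] == s$strand[j + 1L] && !(a %in% taken) &&
          !(b %in% taken)) {
        pairs[[length(pairs) + 1L]] <- c(a, b)
        taken <- c(taken, a, b)
      }
    }
  }
  if (length(pairs) < spec$n_fusion_events)
    stop("insufficient adjacent same-strand gene pairs for ",
         spec$n_fusion_events, " fusion events")
  fusion_pairs <- if (spec$n_fusion_events)
    pairs[sort(sample(length(pairs), spec$n_fusion_events))] else list()
  taken <- unlist(fusion_pairs)
  free <- function(min_cds) {
    cand <- spans$locus_tag[!(spans$locus_tag %in% taken) &
                            spans$cds_len >= min_cds]
    cand
  }
  cand <- free(300L)
  if (length(cand) < spec$n_split_events)
    stop("insufficient genes for ", spec$n_split_events, " split events")
  split_tags <- if (spec$n_split_events)
    sort(sample(cand, spec$n_split_events)) else character(0)
  taken <- c(taken, split_tags)
  cand <- free(150L)
  if (length(cand) < spec$n_frameshift_events)
    stop("insufficient genes for frameshift events")
  fs_tags <- if (spec$n_frameshift_events)
    sort(sample(cand, spec$n_frameshift_events)) else character(0)
  taken <- c(taken, fs_tags)

  tag_num <- function(t) as.integer(sub("^.*_", "", t))
  fresh_num <- max(tag_num(spans$locus_tag))
  keep_cols <- c("locus_tag", "contig", "strand", "type", "start", "end",
                 "complete")
  base_feats <- models[models$type %in% c("exon", "CDS"), keep_cols]

  mapped_rows <- list()   # old models on new coordinates
  corr_rows <- list()
  ev_id <- 0L
  add_corr <- function(old_tag, outcome, new_tags, eid, name = "") {
    corr_rows[[length(corr_rows) + 1L]] <<- data.frame(
      old_tag = old_tag, expected_outcome = outcome,
      new_tags = new_tags, event_id = eid, expected_name = name,
      stringsAsFactors = FALSE)
  }
  handled <- character(0)
  for (pr in fusion_pairs) {
    ev_id <- ev_id + 1L
    a <- pr[1L]; b <- pr[2L]
    old_tag <- a   # the legacy model that will split into a and b
    f <- base_feats[base_feats$locus_tag %in% pr, ]
    f$locus_tag <- old_tag
    mapped_rows[[length(mapped_rows) + 1L]] <- f
    nums <- sort(tag_num(pr))
    add_corr(old_tag, "split", paste(pr, collapse = ";"), ev_id,
             paste(paste0("MONOS_", nums[1L], "p", 1:2), collapse = ";"))
    handled <- c(handled, a, b)
  }
  for (tg in split_tags) {
    ev_id <- ev_id + 1L
    fresh_num <- fresh_num + 1L
    tag2 <- paste0("MONOS_", fresh_num)
    f <- base_feats[base_feats$locus_tag == tg, ]
    cds <- f[f$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    lens <- cds$end - cds$start + 1L
    total <- sum(lens)
    # genomic cut so the left part is a positive multiple of 3, roughly half
    cut_left <- 3L * floor(total / 6L) * 1L
    cut_left <- max(3L, min(total - 3L, 3L * round(total / 6L)))
    cum <- cumsum(lens)
    seg <- which(cum >= cut_left)[1L]
    within <- cut_left - c(0L, cum)[seg]
    cut_pos <- cds$start[seg] + within - 1L  # last genomic CDS base of part 1
    split_feats <- function(df, left) {
      if (left) {
        df <- df[df$start <= cut_pos, ]
        df$end <- pmin(df$end, cut_pos)
      } else {
        df <- df[df$end > cut_pos, ]
        df$start <- pmax(df$start, cut_pos + 1L)
      }
      df
    }
    f1 <- split_feats(f, TRUE); f1$locus_tag <- tg
    f2 <- split_feats(f, FALSE); f2$locus_tag <- tag2
    mapped_rows[[length(mapped_rows) + 1L]] <- rbind(f1, f2)
    nums <- sort(c(tag_num(tg), fresh_num))
    nm <- paste0("MONOS_", nums[1L], "fu", nums[2L])
    add_corr(tg, "fused", tg, ev_id, nm)
    add_corr(tag2, "fused", tg, ev_id, nm)
    handled <- c(handled, tg)
  }
  for (tg in fs_tags) {
    f <- base_feats[base_feats$locus_tag == tg, ]
    mapped_rows[[length(mapped_rows) + 1L]] <- f
    add_corr(tg, "failed", "", 0L)
    handled <- c(handled, tg)
  }
  rest <- setdiff(spans$locus_tag, handled)
  for (tg in rest) {
    mapped_rows[[length(mapped_rows) + 1L]] <-
      base_feats[base_feats$locus_tag == tg, ]
    add_corr(tg, "transferred", tg, 0L)
  }
  mapped <- do.call(rbind, mapped_rows)
  # legacy annotations carry no UTRs: clip exons to the CDS span
  cds_lo <- tapply(mapped$start[mapped$type == "CDS"],
                   mapped$locus_tag[mapped$type == "CDS"], min)
  cds_hi <- tapply(mapped$end[mapped$type == "CDS"],
                   mapped$locus_tag[mapped$type == "CDS"], max)
  is_ex <- mapped$type == "exon"
  mapped$start[is_ex] <- pmax(mapped$start[is_ex],
                              as.integer(cds_lo[mapped$locus_tag[is_ex]]))
  mapped$end[is_ex] <- pmin(mapped$end[is_ex],
                            as.integer(cds_hi[mapped$locus_tag[is_ex]]))
  mapped <- mapped[mapped$start <= mapped$end, ]
  mapped$complete[mapped$locus_tag %in% fs_tags] <- FALSE
  # the fused old models concatenate two stop-terminated CDSs; the internal
  # stop is the realistic consequence, the length still divides by 3

  # ---- cut contigs into old pieces and lift coordinates ----
  contigs <- .as_genome(genome$contigs)
  old_seqs <- character(0)
  old_feat_rows <- list()
  piece_i <- 0L
  mspan <- model_spans(gene_models(mapped, validate = FALSE))
  for (ctg in names(contigs)) {
    clen <- nchar(contigs[[ctg]])
    ms <- mspan[mspan$contig == ctg, ]
    ms <- ms[order(ms$start), ]
    n_cuts <- max(0L, spec$contig_pieces - 1L)
    cuts <- integer(0)
    if (n_cuts > 0L && nrow(ms) > 1L) {
      gaps_lo <- ms$end[-nrow(ms)] + 2L
      gaps_hi <- ms$start[-1L] - 2L
      ok <- gaps_hi >= gaps_lo
      if (any(ok)) {
        pick <- sample(which(ok), min(n_cuts, sum(ok)))
        cuts <- sort(vapply(pick, function(j)
          as.integer(gaps_lo[j] + sample(gaps_hi[j] - gaps_lo[j] + 1L, 1L)
                     - 1L), integer(1)))
      }
    }
    bounds <- cbind(c(1L, cuts + 1L), c(cuts, clen))
    for (p in seq_len(nrow(bounds))) {
      piece_i <- piece_i + 1L
      pid <- sprintf("octg_%03d", piece_i)
      pseq <- substr(contigs[[ctg]], bounds[p, 1L], bounds[p, 2L])
      inside <- ms$locus_tag[ms$start >= bounds[p, 1L] &
                             ms$end <= bounds[p, 2L]]
      f <- mapped[mapped$locus_tag %in% inside, ]
      if (nrow(f)) {
        f$start <- f$start - bounds[p, 1L] + 1L
        f$end <- f$end - bounds[p, 1L] + 1L
        f$contig <- pid
        # frameshift edits on this piece
        for (tg in intersect(fs_tags, inside)) {
          cds <- f[f$locus_tag == tg & f$type == "CDS", ]
          big <- which.max(cds$end - cds$start)
          pos <- cds$start[big] + (cds$end[big] - cds$start[big]) %/% 2L
          delta <- if (stats::runif(1) < 0.5) 1L else -1L
          ed <- .apply_indel(pseq, f, pos, delta,
                             base = sample(c("A", "C", "G", "T"), 1L))
          pseq <- ed$seq
          f <- ed$feats
        }
        old_feat_rows[[length(old_feat_rows) + 1L]] <- f
      }
      old_seqs[pid] <- pseq
    }
  }
  old_models <- gene_models(do.call(rbind, old_feat_rows))
  corr <- do.call(rbind, corr_rows)
  rownames(corr) <- NULL
  list(contigs = seq_records(names(old_seqs), unname(old_seqs)),
       models = old_models,
       mapped_models = gene_models(mapped, validate = FALSE),
       correspondence = corr)
}

#' Generate transcript-read alignment evidence
#'
#' For a planted fraction of 3'UTR-bearing genes, emits full-length reads
#' whose polyA boundary sits exactly at the annotated cleavage site and
#' whose alignment covers the whole gene; the remaining genes get only
#' 5'-truncated reads whose alignments start inside the 3'UTR, so they fail
#' the full-length criterion.
#'
#' @param genome output of \code{\link{make_genome}}.
#' @param spec the \code{\link{synthesis_spec}}.
#' @return list: \code{reads} (data.frame read_id, gene_tag, aln_start,
#'   aln_end, polya_boundary, full_length), \code{full_length_tags}
#'   (character, the planted truth).
#' @export
make_transcript_evidence <- function(genome, spec) {
  set.seed(spec$seed + 202L)
  g <- genome$manifest$genes
  g <- g[g$utr3_len > 0L, ]
  if (!nrow(g))
    return(list(reads = data.frame(read_id = character(),
                                   gene_tag = character(),
                                   aln_start = integer(),
                                   aln_end = integer(),
                                   polya_boundary = integer(),
                                   full_length = logical()),
                full_length_tags = character(0)))
  n_full <- round(spec$full_length_fraction * nrow(g))
  full_tags <- if (n_full) sort(sample(g$locus_tag, n_full)) else character(0)
  rows <- list()
  rid <- 0L
  for (i in seq_len(nrow(g))) {
    tag <- g$locus_tag[i]
    plus <- g$strand[i] == "+"
    cleavage <- g$cleavage[i]
    u3 <- g$utr3_len[i]
    n_reads <- 1L + stats::rbinom(1L, 1L, 0.5)
    for (r in seq_len(n_reads)) {
      rid <- rid + 1L
      if (tag %in% full_tags && r == 1L) {
        a <- g$start[i]; b <- g$end[i]; fl <- TRUE
      } else {
        # 5'-truncated: the alignment begins inside the 3'UTR
        cut <- 5L + sample(max(1L, u3 - 20L), 1L)
        if (plus) { a <- g$end[i] - u3 + cut; b <- g$end[i] }
        else { a <- g$start[i]; b <- g$start[i] + u3 - cut }
        fl <- FALSE
      }
      rows[[rid]] <- data.frame(
        read_id = sprintf("read_%06d", rid), gene_tag = tag,
        aln_start = a, aln_end = b, polya_boundary = cleavage,
        full_length = fl, stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, rows)
  rownames(reads) <- NULL
  list(reads = reads, full_length_tags = full_tags)
}
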