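#' Assembly-level statistics
#'
#' N50 is the length of the contig at which the cumulative length, taken in
#' descending length order, first reaches at least half the assembly total
#' (ties resolved with \code{>=}, the dominant convention). GC is computed
#' over unambiguous bases only.
#'
#' @param contigs \code{\link{seq_records}} (nucleotide) or named character.
#' @return list: n_contigs, total_len, gc_percent, n50, largest.
#' @export
assembly_stats <- function(contigs) {
  seqs <- .as_genome(contigs)
  if (!length(seqs)) stop("empty assembly")
  lens <- nchar(seqs)
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs))
  acgt <- sum(freq[, c("A", "C", "G", "T")])
  gc <- if (acgt > 0) 100 * sum(freq[, c("G", "C")]) / acgt else NA_real_
  list(
    n_contigs = length(seqs),
    total_len = sum(lens),
    gc_percent = gc,
    n50 = n50(lens),
    largest = max(lens)
  )
}

#' N50 of a set of lengths
#' @param lengths integer vector of contig lengths.
#' @return the N50 length.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length set")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]]
}

# Longest tandem run of `unit` starting anywhere in `window_seq`, allowing
# at most `max_mismatch` mismatches summed across the whole run.
.max_tandem_units <- function(window_seq, unit, max_mismatch) {
  u <- nchar(unit)
  n <- nchar(window_seq)
  if (n < u) return(0L)
  wchars <- strsplit(window_seq, "", fixed = TRUE)[[1L]]
  uchars <- strsplit(unit, "", fixed = TRUE)[[1L]]
  # mismatch count of the unit placed at each start position
  n_pos <- n - u + 1L
  mm_at <- integer(n_pos)
  for (j in seq_len(u)) {
    mm_at <- mm_at + as.integer(wchars[seq(j, j + n_pos - 1L)] != uchars[j])
  }
  best <- 0L
  for (s in seq_len(n_pos)) {
    k <- 0L
    mm <- 0L
    pos <- s
    while (pos <= n_pos && mm + mm_at[pos] <= max_mismatch) {
      mm <- mm + mm_at[pos]
      k <- k + 1L
      pos <- pos + u
    }
    if (k > best) best <- k
    if (best >= (n_pos - s + u) %/% u) break  # cannot improve further right
  }
  best
}

#' Classify telomeric contig ends
#'
#' An end is telomeric when at least \code{min_units} tandem copies of the
#' repeat unit (or its reverse complement) occur within the terminal
#' \code{search_window} bases, tolerating at most \code{max_mismatch}
#' mismatches summed across the tandem run. The 3' end is scanned
#' symmetrically (equivalent to scanning the reverse complement's 5' end),
#' so reverse-complementing a contig swaps the two flags.
#'
#' @param seq one contig sequence (character).
#' @param unit telomeric repeat unit.
#' @param min_units minimum tandem copies.
#' @param search_window bases examined at each end.
#' @param max_mismatch total mismatches tolerated across a run.
#' @return list: five_prime, three_prime (logical), units_5, units_3.
#' @export
detect_telomeric_ends <- function(seq, unit = "TTAGGG", min_units = 5L,
                                  search_window = 500L, max_mismatch = 2L) {
  unit <- toupper(unit)
  if (nchar(unit) < 4L) stop("telomere unit must be at least 4 bp")
  if (search_window < min_units * nchar(unit))
    stop("search_window smaller than min_units * unit length")
  seq <- toupper(seq)
  n <- nchar(seq)
  units_in <- function(s) max(.max_tandem_units(s, unit, max_mismatch),
                              .max_tandem_units(s, revcomp(unit),
                                                max_mismatch))
  head_seq <- substr(seq, 1L, min(search_window, n))
  tail_seq <- substr(seq, max(1L, n - search_window + 1L), n)
  u5 <- units_in(head_seq)
  u3 <- units_in(tail_seq)
  list(five_prime = u5 >= min_units, three_prime = u3 >= min_units,
       units_5 = if (u5 >= min_units) u5 else 0L,
       units_3 = if (u3 >= min_units) u3 else 0L)
}

#' Telomere calls for a whole assembly
#'
#' @param contigs \code{seq_records} or named character.
#' @inheritParams detect_telomeric_ends
#' @return data.frame: contig_id, five_prime, three_prime, units_5, units_3.
#' @export
telomere_calls <- function(contigs, unit = "TTAGGG", min_units = 5L,
                           search_window = 500L, max_mismatch = 2L) {
  seqs <- .as_genome(contigs)
  rows <- lapply(names(seqs), function(id) {
    tc <- detect_telomeric_ends(seqs[[id]], unit, min_units,
                                search_window, max_mismatch)
    data.frame(contig_id = id, five_prime = tc$five_prime,
               three_prime = tc$three_prime, units_5 = tc$units_5,
               units_3 = tc$units_3, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chromosome-number estimate from telomeric-end counts
#'
#' Each contig capped at both ends is one complete chromosome; each contig
#' with a single telomeric end represents one chromosome end, so two such
#' contigs make up (at most) one further chromosome. The point estimate is
#' \code{n_both + n_one / 2}; the reported range rounds it down/up to the
#' nearest multiple of 10, matching the loose way such counts are quoted.
#'
#' @param n_both contigs with telomeric repeats at both ends.
#' @param n_one contigs with a telomeric repeat at exactly one end.
#' @return list: n_both, n_one, point, low, high.
#' @export
estimate_chromosomes <- function(n_both, n_one) {
  if (n_both < 0 || n_one < 0) stop("counts must be non-negative")
  point <- n_both + n_one / 2
  list(n_both = as.integer(n_both), n_one = as.integer(n_one),
       point = point,
       low = as.integer(10 * floor(point / 10)),
       high = as.integer(10 * ceiling(point / 10)))
}

#' Coding density in fixed windows
#'
#' Tiles each contig with windows of \code{window} bp (final partial window
#' kept at its true length) and reports the fraction of window bases covered
#' by the union of CDS intervals.
#'
#' @param models \code{gene_models}.
#' @param contig_lengths named integer vector of contig lengths.
#' @param window window size in bp.
#' @return list with \code{windows} (contig, window_start, window_end,
#'   fraction) and \code{per_contig} (contig, mean_fraction, cds_bases).
#' @export
coding_density <- function(models, contig_lengths, window = 5000L) {
  cds <- models[models$type == "CDS", ]
  unknown <- setdiff(unique(cds$contig), names(contig_lengths))
  if (length(unknown))
    stop("gene(s) on unknown contig(s): ", paste(unknown, collapse = ", "))
  win_rows <- list()
  ctg_rows <- list()
  for (ctg in names(contig_lengths)) {
    len <- as.integer(contig_lengths[[ctg]])
    starts <- seq(1L, len, by = window)
    ends <- pmin(starts + window - 1L, len)
    cov <- integer(len)
    m <- cds[cds$contig == ctg, ]
    if (nrow(m)) {
      red <- IRanges::reduce(IRanges::IRanges(m$start, pmin(m$end, len)))
      for (i in seq_along(red)) {
        cov[IRanges::start(red)[i]:IRanges::end(red)[i]] <- 1L
      }
    }
    cs <- c(0L, cumsum(cov))
    covered <- cs[ends + 1L] - cs[starts]
    frac <- covered / (ends - starts + 1L)
    win_rows[[ctg]] <- data.frame(contig = ctg, window_start = starts,
                                  window_end = ends, fraction = frac,
                                  stringsAsFactors = FALSE)
    ctg_rows[[ctg]] <- data.frame(contig = ctg,
                                  mean_fraction = sum(covered) / len,
                                  cds_bases = sum(covered),
                                  stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, win_rows)
  per_contig <- do.call(rbind, ctg_rows)
  rownames(windows) <- rownames(per_contig) <- NULL
  list(windows = windows, per_contig = per_contig)
}

#' Annotation-level gene metrics
#'
#' Gene length is the genomic span from first to last exon base (introns and
#' UTRs included); intergenic length is the gap between consecutive gene
#' spans on the same contig. Intron GC is only computed when the genome
#' sequence is supplied.
#'
#' @param models \code{gene_models}.
#' @param genome optional \code{seq_records}/named character for intron GC.
#' @return list of summary metrics.
#' @export
gene_metrics <- function(models, genome = NULL) {
  spans <- model_spans(models)
  introns <- model_introns(models)
  n_genes <- nrow(spans)
  # intergenic gaps between consecutive spans per contig
  gaps <- unlist(lapply(split(spans, spans$contig), function(s) {
    s <- s[order(s$start), ]
    if (nrow(s) < 2L) return(numeric(0))
    g <- s$start[-1L] - s$end[-nrow(s)] - 1L
    g[g > 0L]
  }), use.names = FALSE)
  intron_gc <- NA_real_
  if (!is.null(genome) && nrow(introns)) {
    contigs <- .as_genome(genome)
    iseq <- substring(contigs[introns$contig], introns$start, introns$end)
    freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(iseq))
    acgt <- sum(freq[, c("A", "C", "G", "T")])
    intron_gc <- if (acgt) 100 * sum(freq[, c("G", "C")]) / acgt else NA_real_
  }
  utr_counts <- function(type) {
    u <- models[models$type == type, ]
    if (!nrow(u)) return(list(n = 0L, mean_len = NA_real_, introns = 0L))
    per_tag_len <- tapply(u$end - u$start + 1L, u$locus_tag, sum)
    n_int <- 0L
    if (nrow(introns)) {
      for (tag in names(per_tag_len)) {
        ui <- u[u$locus_tag == tag, ]
        ii <- introns[introns$locus_tag == tag, ]
        if (nrow(ii))
          n_int <- n_int + sum(ii$start >= min(ui$start) &
                               ii$end <= max(ui$end))
      }
    }
    list(n = length(per_tag_len), mean_len = mean(per_tag_len),
         introns = n_int)
  }
  u5 <- utr_counts("five_prime_UTR")
  u3 <- utr_counts("three_prime_UTR")
  list(
    n_genes = n_genes,
    mean_gene_length = mean(spans$end - spans$start + 1),
    mean_intergenic_length = if (length(gaps)) mean(gaps) else NA_real_,
    n_introns = nrow(introns),
    introns_per_gene = nrow(introns) / n_genes,
    mean_intron_length = if (nrow(introns))
      mean(introns$end - introns$start + 1) else NA_real_,
    intron_gc_percent = intron_gc,
    n_genes_utr5 = u5$n, mean_utr5_length = u5$mean_len,
    n_introns_utr5 = u5$introns,
    n_genes_utr3 = u3$n, mean_utr3_length = u3$mean_len,
    n_introns_utr3 = u3$introns
  )
}
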