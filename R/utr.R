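#' Flag full-length 3'UTRs from oligo-dT read boundaries
#'
#' A 3'UTR is full length iff at least one read's polyA/oligo-dT boundary
#' lies within \code{tolerance} bases of the annotated UTR end (the
#' cleavage site) and that read's alignment covers the whole annotated UTR.
#'
#' @param utrs data.frame from \code{\link{extract_utrs}} (three_prime).
#' @param reads read-alignment table (see \code{\link{read_reads}}).
#' @param models \code{gene_models} providing the UTR coordinates.
#' @param tolerance maximum boundary distance in bp.
#' @return \code{utrs} with a logical \code{full_length} column.
#' @export
flag_full_length_3utr <- function(utrs, reads, models, tolerance = 0L) {
  u3 <- models[models$type == "three_prime_UTR", ]
  unknown <- setdiff(unique(reads$gene_tag), unique(models$locus_tag))
  if (length(unknown))
    stop("read(s) reference unknown gene(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  flag <- logical(nrow(utrs))
  for (i in seq_len(nrow(utrs))) {
    tag <- utrs$gene_tag[i]
    m <- u3[u3$locus_tag == tag, ]
    if (!nrow(m)) next
    lo <- min(m$start); hi <- max(m$end)
    cleavage <- if (m$strand[1L] == "+") hi else lo
    r <- reads[reads$gene_tag == tag, ]
    if (!nrow(r)) next
    ok <- abs(r$polya_boundary - cleavage) <= tolerance &
      r$aln_start <= lo & r$aln_end >= hi
    flag[i] <- any(ok)
  }
  utrs$full_length <- flag
  utrs
}

#' Terminal window of each UTR
#'
#' The last \code{window} bases (transcript orientation, i.e. the bases
#' immediately upstream of the cleavage site). Shorter sequences are kept
#' whole and marked.
#'
#' @param utrs data.frame with columns gene_tag, seq.
#' @param window window size (bp), must be positive.
#' @return data.frame gene_tag, seq (the tail), length, short (logical).
#' @export
terminal_window <- function(utrs, window = 100L) {
  if (window <= 0L) stop("window must be positive")
  n <- nchar(utrs$seq)
  tails <- substring(utrs$seq, pmax(1L, n - window + 1L), n)
  data.frame(gene_tag = utrs$gene_tag, seq = tails, length = nchar(tails),
             short = n < window, stringsAsFactors = FALSE)
}

#' Dinucleotide-preserving shuffle
#'
#' Uniform random shuffle preserving the exact dinucleotide counts (and
#' hence mononucleotide counts, first and last base) of the input, by a
#' random Eulerian path through the dinucleotide multigraph: each non-final
#' vertex is assigned a random last outgoing edge, resampled until the last
#' edges form an arborescence into the final vertex; remaining edges are
#' randomly permuted.
#'
#' @param seq one sequence string.
#' @return a shuffled string with identical dinucleotide composition.
#' @export
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n <= 3L) return(seq)
  verts <- unique(ch)
  last <- ch[n]
  succ <- split(ch[-1L], factor(ch[-n], levels = verts))
  nonfinal <- setdiff(names(succ)[lengths(succ) > 0L], last)
  repeat {
    last_edge <- vapply(nonfinal, function(v) {
      e <- succ[[v]]
      e[sample.int(length(e), 1L)]
    }, character(1))
    # do all chosen last edges lead (transitively) to the final vertex?
    ok <- TRUE
    for (v in nonfinal) {
      cur <- v
      seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !(cur %in% names(last_edge))) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  queues <- lapply(stats::setNames(names(succ), names(succ)), function(v) {
    e <- succ[[v]]
    if (v %in% nonfinal) {
      idx <- which(e == last_edge[[v]])[1L]
      rest <- e[-idx]
      c(if (length(rest) > 1L) rest[sample.int(length(rest))] else rest,
        e[idx])
    } else {
      if (length(e) > 1L) e[sample.int(length(e))] else e
    }
  })
  out <- character(n)
  out[1L] <- ch[1L]
  ptr <- stats::setNames(rep(1L, length(queues)), names(queues))
  cur <- ch[1L]
  for (i in 2L:n) {
    nxt <- queues[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

.kmer_presence <- function(seqs, k) {
  # per-sequence presence (zero-or-one) counts of every k-mer observed
  km <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1L:(n - k + 1L), k:n))
  }))
  if (!length(km)) return(integer(0))
  table(km)
}

#' K-mer enrichment against a dinucleotide-shuffle null
#'
#' For every k-mer, the observed statistic is the number of sequences
#' containing it at least once. The null distribution comes from
#' \code{n_shuffles} rounds of per-sequence dinucleotide-preserving
#' shuffling; z = (observed - null mean) / null sd. Where the null sd is
#' zero a binomial fallback sd is used. Ranking: z descending, ties by
#' observed count then lexicographic.
#'
#' @param seqs character vector (at least 20 sequences).
#' @param k k-mer size (>= 4).
#' @param n_shuffles shuffle rounds.
#' @param seed RNG seed for the shuffles.
#' @return data.frame: kmer (DNA), kmer_rna (T shown as U), observed,
#'   expected, sd, z, ranked.
#' @export
kmer_enrichment <- function(seqs, k = 6L, n_shuffles = 100L, seed = 1L) {
  if (length(seqs) < 20L) stop("need at least 20 sequences")
  if (k < 4L) stop("k must be >= 4")
  if (all(nchar(seqs) < k)) stop("all sequences shorter than k")
  set.seed(seed)
  obs <- .kmer_presence(seqs, k)
  null_counts <- matrix(0L, nrow = n_shuffles, ncol = 0)
  acc <- list()
  for (r in seq_len(n_shuffles)) {
    sh <- vapply(seqs, dinuc_shuffle, character(1), USE.NAMES = FALSE)
    acc[[r]] <- .kmer_presence(sh, k)
  }
  all_k <- sort(unique(c(names(obs), unlist(lapply(acc, names)))))
  obs_v <- stats::setNames(rep(0, length(all_k)), all_k)
  obs_v[names(obs)] <- as.numeric(obs)
  null_m <- matrix(0, nrow = n_shuffles, ncol = length(all_k),
                   dimnames = list(NULL, all_k))
  for (r in seq_len(n_shuffles)) null_m[r, names(acc[[r]])] <-
    as.numeric(acc[[r]])
  mu <- colMeans(null_m)
  sdv <- apply(null_m, 2L, stats::sd)
  n <- length(seqs)
  p <- (mu + 0.5) / (n + 1)
  fallback <- sqrt(n * p * (1 - p))
  sd_eff <- ifelse(sdv > 0, sdv, fallback)
  z <- (obs_v - mu) / sd_eff
  out <- data.frame(kmer = all_k,
                    kmer_rna = chartr("T", "U", all_k),
                    observed = as.integer(obs_v), expected = mu,
                    sd = sdv, z = z, stringsAsFactors = FALSE)
  out <- out[order(-out$z, -out$observed, out$kmer), ]
  rownames(out) <- NULL
  out
}

#' Positional profile of a k-mer upstream of the cleavage site
#'
#' Sequences are right-anchored: the base immediately before the cleavage
#' site is position -1. The value at position p is the fraction of
#' sequences whose first k-mer occurrence starts at p. Also reports the
#' modal position and the shortest contiguous window holding at least half
#' of all occurrences.
#'
#' @param seqs terminal-window sequences (3' ends aligned at the cleavage
#'   site).
#' @param kmer the motif (DNA alphabet).
#' @param upstream profile depth in bp (positions -upstream .. -1).
#' @return list: positions, values, peak_position, peak_probability,
#'   window (c(p1, p2) or NULL), n_occurrences.
#' @export
positional_profile <- function(seqs, kmer, upstream = 100L) {
  k <- nchar(kmer)
  positions <- seq(-upstream, -1L)
  counts <- stats::setNames(rep(0L, length(positions)), positions)
  n_occ <- 0L
  for (s in seqs) {
    L <- nchar(s)
    hit <- regexpr(kmer, s, fixed = TRUE)[1L]
    if (hit > 0L) {
      p <- hit - L - 1L  # start position relative to cleavage
      if (p >= -upstream) {
        counts[as.character(p)] <- counts[as.character(p)] + 1L
        n_occ <- n_occ + 1L
      }
    }
  }
  values <- as.numeric(counts) / length(seqs)
  if (n_occ == 0L) {
    warning("k-mer ", kmer, " absent from all sequences")
    return(list(positions = positions, values = values,
                peak_position = NA_integer_, peak_probability = 0,
                window = NULL, n_occurrences = 0L))
  }
  peak <- positions[which.max(values)]
  # shortest contiguous window containing >= 50% of occurrences
  cnt <- as.numeric(counts)
  target <- n_occ / 2
  best <- NULL
  for (i in seq_along(cnt)) {
    run <- cumsum(cnt[i:length(cnt)])
    j <- which(run >= target)[1L]
    if (!is.na(j) && (is.null(best) || j < best$len))
      best <- list(len = j, i = i)
  }
  window <- c(positions[best$i], positions[best$i + best$len - 1L])
  list(positions = positions, values = values, peak_position = peak,
       peak_probability = max(values), window = window,
       n_occurrences = n_occ)
}

#' Positional U(T) content
#'
#' Right-anchored like \code{\link{positional_profile}}; the value at p is
#' the fraction of sequences carrying U/T at p, among sequences long enough
#' to cover p.
#'
#' @param seqs terminal-window sequences.
#' @param upstream profile depth in bp.
#' @return list: positions, values.
#' @export
u_profile <- function(seqs, upstream = 100L) {
  positions <- seq(-upstream, -1L)
  hit <- cov <- rep(0L, length(positions))
  for (s in seqs) {
    L <- nchar(s)
    span <- max(1L, upstream - L + 1L):length(positions)
    idx <- L + positions[span] + 1L
    b <- substring(s, idx, idx)
    cov[span] <- cov[span] + 1L
    hit[span] <- hit[span] + as.integer(b == "T" | b == "U")
  }
  list(positions = positions,
       values = ifelse(cov > 0L, hit / cov, 0))
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
            ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Kozak position-frequency matrix around the start codon
#'
#' Uses genes whose 5'UTR is at least \code{flank} bp (shorter contexts are
#' excluded and counted). Columns cover positions -flank..-1, the start
#' codon, and +1..+flank downstream of it; each column sums to 1. The
#' consensus letter per column is the base with frequency >= 0.4, else the
#' IUPAC code of all bases >= 0.25, else "n". Also reports the mean A+T
#' frequency over the upstream columns.
#'
#' @param genome \code{seq_records}/named character.
#' @param models \code{gene_models}.
#' @param flank bases up- and downstream of the start codon.
#' @return list: matrix (4 x (2*flank+3)), consensus, upstream_at_fraction,
#'   n_used, n_excluded.
#' @export
kozak_matrix <- function(genome, models, flank = 10L) {
  utr5 <- extract_utrs(genome, models, "five_prime")
  cds <- extract_cds(genome, models, unique(utr5$gene_tag))
  cds_seq <- stats::setNames(cds$seq, cds$id)
  keep <- utr5$length >= flank & nchar(cds_seq[utr5$gene_tag]) >= flank + 3L
  used <- utr5[keep, ]
  contexts <- paste0(substring(used$seq, used$length - flank + 1L,
                               used$length),
                     substr(cds_seq[used$gene_tag], 1L, flank + 3L))
  ncol_m <- 2L * flank + 3L
  m <- matrix(0, nrow = 4L, ncol = ncol_m,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pos_labels <- c(seq(-flank, -1L), "+1", "+2", "+3",
                  paste0("+", 3L + seq_len(flank)))
  colnames(m) <- pos_labels
  if (nrow(used)) {
    for (j in seq_len(ncol_m)) {
      b <- substring(contexts, j, j)
      tab <- table(factor(b, levels = c("A", "C", "G", "T")))
      m[, j] <- as.numeric(tab) / sum(tab)
    }
  }
  consensus <- vapply(seq_len(ncol_m), function(j) {
    col <- m[, j]
    if (any(col >= 0.4)) return(tolower(names(col)[which.max(col)]))
    amb <- sort(names(col)[col >= 0.25])
    if (length(amb)) return(tolower(.IUPAC[[paste(amb, collapse = "")]]))
    "n"
  }, character(1))
  upstream_at <- mean(m["A", seq_len(flank)] + m["T", seq_len(flank)])
  list(matrix = m, consensus = paste(consensus, collapse = ""),
       upstream_at_fraction = upstream_at,
       n_used = nrow(used), n_excluded = sum(!keep))
}

#' UTR summary statistics
#'
#' @param utrs data.frame from \code{\link{extract_utrs}} (either kind or
#'   both row-bound).
#' @param bin histogram bin width (bp).
#' @return list per kind: n, mean_length, intron count, length histogram
#'   (25 bp bins); plus gc3_percent over 3'UTR sequences.
#' @export
utr_stats <- function(utrs, bin = 25L) {
  per_kind <- lapply(split(utrs, utrs$kind), function(u) {
    breaks <- seq(0L, max(u$length) + bin, by = bin)
    list(n = nrow(u), mean_length = mean(u$length),
         n_introns = sum(u$introns),
         hist = table(cut(u$length, breaks = breaks, right = TRUE)))
  })
  u3 <- utrs[utrs$kind == "three_prime", ]
  gc3 <- if (nrow(u3)) {
    freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(u3$seq))
    100 * sum(freq[, c("G", "C")]) / sum(freq[, c("A", "C", "G", "T")])
  } else NA_real_
  c(per_kind, list(gc3_percent = gc3))
}
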