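#' Reciprocal best hits between two homology tables
#'
#' A pair (q, s) is reported iff s is q's best forward hit and q is s's
#' best reverse hit, with both hits at e-value <= \code{evalue_max}. "Best"
#' means lowest e-value, ties broken by higher bitscore, then by
#' lexicographic subject id. The result is symmetric in the two tables.
#'
#' @param fwd,rev 12-column hit tables (see \code{\link{read_hits}}).
#' @param evalue_max inclusive e-value ceiling.
#' @return data.frame: query, subject, evalue_fwd, evalue_rev.
#' @export
reciprocal_best_hits <- function(fwd, rev, evalue_max = 0.001) {
  fwd <- hit_table(fwd); rev <- hit_table(rev)
  best_of <- function(h) {
    if (!nrow(h)) return(h)
    h <- h[order(h$query, h$evalue, -h$bitscore, h$subject), ]
    h[!duplicated(h$query), ]
  }
  bf <- best_of(fwd)
  br <- best_of(rev)
  bf <- bf[bf$evalue <= evalue_max, ]
  br <- br[br$evalue <= evalue_max, ]
  if (!nrow(bf) || !nrow(br))
    return(data.frame(query = character(), subject = character(),
                      evalue_fwd = numeric(), evalue_rev = numeric(),
                      stringsAsFactors = FALSE))
  key_f <- paste(bf$query, bf$subject, sep = "\r")
  key_r <- paste(br$subject, br$query, sep = "\r")
  hit <- key_f %in% key_r
  out <- data.frame(query = bf$query[hit], subject = bf$subject[hit],
                    evalue_fwd = bf$evalue[hit],
                    evalue_rev = br$evalue[match(key_f[hit], key_r)],
                    stringsAsFactors = FALSE)
  out[order(out$query), , drop = FALSE]
}

#' Dual targeting-signal consensus
#'
#' Proteins whose mitochondrial-localisation probability is strictly above
#' the threshold in both predictor tables. Missing scores count as 0.
#'
#' @param scores_a,scores_b data.frames with protein_id and probability.
#' @param threshold strict lower bound for both probabilities.
#' @param proteome_ids ids of all analysed proteins (denominator of the
#'   rate); defaults to the union of the two tables.
#' @return list: ids, n_flagged, n_total, rate_percent (one decimal).
#' @export
targeting_consensus <- function(scores_a, scores_b, threshold = 0.5,
                                proteome_ids = NULL) {
  for (df in list(scores_a, scores_b)) {
    if (any(df$probability < 0 | df$probability > 1))
      stop("probabilities must lie in [0, 1]")
  }
  if (is.null(proteome_ids))
    proteome_ids <- union(scores_a$protein_id, scores_b$protein_id)
  pa <- stats::setNames(rep(0, length(proteome_ids)), proteome_ids)
  pb <- pa
  pa[scores_a$protein_id] <- scores_a$probability
  pb[scores_b$protein_id] <- scores_b$probability
  ids <- proteome_ids[pa[proteome_ids] > threshold &
                      pb[proteome_ids] > threshold]
  list(ids = ids, n_flagged = length(ids), n_total = length(proteome_ids),
       rate_percent = round(100 * length(ids) / length(proteome_ids), 1L))
}

#' Tail-anchor filter
#'
#' Keeps proteins having a transmembrane segment whose last residue lies
#' within \code{window} residues of the C-terminus (inclusive).
#'
#' @param protein_lengths named integer vector (or \code{seq_records}).
#' @param tmds data.frame protein_id, start, end.
#' @param window maximum distance in residues.
#' @return character vector of protein ids.
#' @export
tail_anchor_filter <- function(protein_lengths, tmds, window = 32L) {
  if (inherits(protein_lengths, "seq_records") ||
      is.data.frame(protein_lengths))
    protein_lengths <- stats::setNames(nchar(protein_lengths$seq),
                                       protein_lengths$id)
  unknown <- setdiff(unique(tmds$protein_id), names(protein_lengths))
  if (length(unknown))
    stop("TMD rows reference unknown protein(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  len <- protein_lengths[tmds$protein_id]
  if (any(tmds$end > len))
    stop("TMD out of protein bounds for ",
         tmds$protein_id[which(tmds$end > len)[1L]])
  sort(unique(tmds$protein_id[(len - tmds$end) <= window]))
}

# Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2, X = 0)

#' Hydropathy-based TMD fallback
#'
#' A sliding-window hydropathy scan used only when no external TMD
#' prediction table is available; it is not equivalent to a dedicated
#' predictor. Reports maximal runs of residue positions whose centred
#' Kyte-Doolittle window mean reaches the threshold, each run widened to
#' the window it covers.
#'
#' @param protein one amino-acid string.
#' @param window odd window size in residues.
#' @param threshold mean hydropathy cutoff.
#' @return data.frame start, end, source ("hydropathy_fallback").
#' @export
hydropathy_tmd_fallback <- function(protein, window = 19L, threshold = 1.6) {
  n <- nchar(protein)
  empty <- data.frame(start = integer(), end = integer(),
                      source = character(), stringsAsFactors = FALSE)
  if (n < window) return(empty)
  h <- .KD[strsplit(toupper(protein), "", fixed = TRUE)[[1L]]]
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  half <- (window - 1L) %/% 2L
  centres <- (half + 1L):(n - half)
  means <- (cs[centres + half + 1L] - cs[centres - half]) / window
  hot <- centres[means >= threshold]
  if (!length(hot)) return(empty)
  breaks <- which(diff(hot) > 1L)
  run_start <- hot[c(1L, breaks + 1L)]
  run_end <- hot[c(breaks, length(hot))]
  data.frame(start = pmax(1L, run_start - half),
             end = pmin(n, run_end + half),
             source = "hydropathy_fallback", stringsAsFactors = FALSE)
}

#' Default residue classes of the beta-signal pattern
#'
#' Polar (Po) and hydrophobic (Hy) alphabets for the
#' Po-x-G-Hy-x-Hy-x-Hy motif; exposed because published class tables vary.
#' @return list with polar_set and hydrophobic_set character vectors.
#' @export
beta_signal_classes <- function() {
  list(polar_set = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
       hydrophobic_set = c("A", "F", "I", "L", "M", "V", "W", "Y"))
}

#' Scan a protein for C-terminal beta-signals
#'
#' Reports every 8-mer matching the position classes
#' [Po, x, G, Hy, x, Hy, x, Hy] whose last residue lies within
#' \code{cterm_window} residues of the C-terminus; the rightmost hit is
#' marked primary.
#'
#' @param protein one amino-acid string (length >= 8).
#' @param classes residue classes, see \code{\link{beta_signal_classes}}.
#' @param cterm_window max distance of the motif's last residue from the
#'   C-terminus.
#' @return data.frame: start, residues, primary.
#' @export
beta_signal_scan <- function(protein, classes = beta_signal_classes(),
                             cterm_window = 15L) {
  protein <- toupper(protein)
  n <- nchar(protein)
  empty <- data.frame(start = integer(), residues = character(),
                      primary = logical(), stringsAsFactors = FALSE)
  if (n < 8L) return(empty)
  ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
  starts <- seq_len(n - 7L)
  starts <- starts[(n - (starts + 7L)) <= cterm_window]
  if (!length(starts)) return(empty)
  ok <- ch[starts] %in% classes$polar_set &
    ch[starts + 2L] == "G" &
    ch[starts + 3L] %in% classes$hydrophobic_set &
    ch[starts + 5L] %in% classes$hydrophobic_set &
    ch[starts + 7L] %in% classes$hydrophobic_set
  hits <- starts[ok]
  if (!length(hits)) return(empty)
  data.frame(start = hits,
             residues = substring(protein, hits, hits + 7L),
             primary = hits == max(hits), stringsAsFactors = FALSE)
}

#' Secondary-structure filters for beta-barrel (MBOMP) candidates
#'
#' Over the (up to) \code{context} residues immediately preceding the
#' beta-signal: strand (E) fraction must reach \code{min_strand}, helix (H)
#' fraction must not exceed \code{max_helix}; and at most
#' \code{max_signal_helix} of the 8 motif residues may be helical. All
#' bounds are inclusive.
#'
#' @param protein amino-acid string.
#' @param hit_start start position of the beta-signal 8-mer.
#' @param ss three-state secondary-structure string (H/E/C), same length as
#'   the protein.
#' @param context context window length in residues.
#' @param min_strand,max_helix,max_signal_helix filter thresholds.
#' @return list: pass, strand_frac, helix_frac, signal_helix_frac,
#'   context_len, short_context.
#' @export
mbomp_filter <- function(protein, hit_start, ss, context = 300L,
                         min_strand = 0.25, max_helix = 0.10,
                         max_signal_helix = 0.50) {
  if (nchar(ss) != nchar(protein))
    stop("secondary-structure string length differs from protein length")
  ctx_len <- min(context, hit_start - 1L)
  if (ctx_len < 1L)
    return(list(pass = FALSE, strand_frac = NA_real_,
                helix_frac = NA_real_, signal_helix_frac = NA_real_,
                context_len = 0L, short_context = TRUE))
  ctx <- strsplit(substr(ss, hit_start - ctx_len, hit_start - 1L), "",
                  fixed = TRUE)[[1L]]
  sig <- strsplit(substr(ss, hit_start, hit_start + 7L), "",
                  fixed = TRUE)[[1L]]
  strand_frac <- mean(ctx == "E")
  helix_frac <- mean(ctx == "H")
  signal_helix_frac <- mean(sig == "H")
  list(pass = strand_frac >= min_strand && helix_frac <= max_helix &&
         signal_helix_frac <= max_signal_helix,
       strand_frac = strand_frac, helix_frac = helix_frac,
       signal_helix_frac = signal_helix_frac,
       context_len = ctx_len, short_context = ctx_len < context)
}

#' MBOMP channel over a whole proteome
#'
#' Beta-signal scan followed by the secondary-structure filters, applied to
#' the primary (rightmost) signal of each protein.
#'
#' @param proteins \code{seq_records} (protein).
#' @param ss3 \code{seq_records} (ss3), ids matching the proteins.
#' @param cfg \code{\link{mx_config}}.
#' @return character vector of passing protein ids.
#' @export
mbomp_screen <- function(proteins, ss3, cfg = mx_config()) {
  ss_map <- stats::setNames(ss3$seq, ss3$id)
  pass <- character(0)
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$id[i]
    hits <- beta_signal_scan(proteins$seq[i],
                             cterm_window = cfg$beta_cterm_window)
    if (!nrow(hits)) next
    hs <- hits$start[hits$primary][1L]
    if (!id %in% names(ss_map))
      stop("no secondary-structure record for ", id)
    res <- mbomp_filter(proteins$seq[i], hs, ss_map[[id]],
                        context = cfg$mbomp_context,
                        min_strand = cfg$mbomp_min_strand,
                        max_helix = cfg$mbomp_max_helix,
                        max_signal_helix = cfg$mbomp_max_signal_helix)
    if (isTRUE(res$pass)) pass <- c(pass, id)
  }
  sort(pass)
}

#' Join HMM candidates with database homology hits
#'
#' @param hmm_hits data.frame protein_id, profile, evalue.
#' @param db_hits data.frame protein_id, subject, evalue.
#' @param evalue_max ceiling for a database hit to count as a homolog.
#' @return data.frame: protein_id, n_profiles, has_db_homolog.
#' @export
hmm_candidate_join <- function(hmm_hits, db_hits, evalue_max = 0.001) {
  if (!nrow(hmm_hits))
    return(data.frame(protein_id = character(), n_profiles = integer(),
                      has_db_homolog = logical(), stringsAsFactors = FALSE))
  hmm_hits <- hmm_hits[!duplicated(hmm_hits[c("protein_id", "profile")]), ]
  ids <- sort(unique(hmm_hits$protein_id))
  db_ok <- unique(db_hits$protein_id[db_hits$evalue <= evalue_max])
  data.frame(protein_id = ids,
             n_profiles = as.integer(table(hmm_hits$protein_id)[ids]),
             has_db_homolog = ids %in% db_ok, stringsAsFactors = FALSE)
}

#' Aggregate the evidence channels into a candidate report
#'
#' One row per protein with a flag per channel. Any flag sends the protein
#' to manual review; the screen never auto-declares a mitochondrial
#' protein, mirroring the manual final step of such surveys.
#'
#' @param proteome_ids all analysed protein ids.
#' @param rbh,hmm,targeting,tail_anchor,mbomp character vectors of flagged
#'   protein ids per channel.
#' @return list: \code{table} (per-protein flags and verdict) and
#'   \code{summary} (per-channel counts and percentages, one decimal, plus
#'   the union).
#' @export
aggregate_report <- function(proteome_ids, rbh = character(0),
                             hmm = character(0), targeting = character(0),
                             tail_anchor = character(0),
                             mbomp = character(0)) {
  channels <- list(rbh = rbh, hmm = hmm, targeting = targeting,
                   tail_anchor = tail_anchor, mbomp = mbomp)
  for (nm in names(channels)) {
    unknown <- setdiff(channels[[nm]], proteome_ids)
    if (length(unknown))
      stop("channel '", nm, "' references unknown protein(s): ",
           paste(utils::head(unknown, 3L), collapse = ", "))
  }
  tab <- data.frame(protein_id = proteome_ids, stringsAsFactors = FALSE)
  for (nm in names(channels)) tab[[nm]] <- proteome_ids %in% channels[[nm]]
  any_flag <- Reduce(`|`, tab[names(channels)])
  tab$verdict <- ifelse(any_flag, "manual_review", "rejected")
  n <- length(proteome_ids)
  summary <- data.frame(
    channel = c(names(channels), "union"),
    n_flagged = c(vapply(channels, function(x)
      length(intersect(x, proteome_ids)), integer(1)), sum(any_flag)),
    stringsAsFactors = FALSE)
  summary$percent <- round(100 * summary$n_flagged / n, 1L)
  list(table = tab, summary = summary)
}
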