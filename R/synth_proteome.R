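.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")
.HYDRO <- c("A", "F", "I", "L", "M", "V", "W")

.rand_strings <- function(n, lens, alphabet, prob = NULL) {
  total <- sum(lens)
  res <- sample(alphabet, total, replace = TRUE, prob = prob)
  pieces <- split(res, rep(seq_len(n), lens))
  vapply(pieces, paste, character(1), collapse = "", USE.NAMES = FALSE)
}

# secondary-structure stretch with exact state counts, order shuffled
.ss_block <- function(len, e_frac, h_frac) {
  ne <- round(e_frac * len)
  nh <- round(h_frac * len)
  paste(sample(c(rep("E", ne), rep("H", nh), rep("C", len - ne - nh))),
        collapse = "")
}

#' Generate a synthetic proteome with planted screen positives
#'
#' Plants, in disjoint protein sets: dual targeting-signal positives (both
#' predictor probabilities Uniform(0.55, 0.95); all other proteins get at
#' most one probability above 0.5 and at least one below 0.45), tail-anchor
#' positives (a 20-residue hydrophobic stretch ending within 32 residues of
#' the C-terminus, with a matching TMD-table row) and distant-TMD decoys,
#' beta-barrel (MBOMP) positives (C-terminal beta-signal plus a
#' strand-rich/helix-poor 300-residue context) and single-violation MBOMP
#' decoys, reciprocal-best-hit pairs against a synthetic database (planted
#' pair e-values well below 0.001; noise hits are log-uniform on
#' [1e-3, 10] and never mutual), and HMM-channel hits of which a subset
#' also has database homologs.
#'
#' @param spec \code{\link{synthesis_spec}} (its \code{proteome} element).
#' @return list: proteins, ss3 (\code{seq_records}), scores_a, scores_b,
#'   tmd, hits_fwd, hits_rev, hmm_hits (data.frames), manifest.
#' @export
make_proteome <- function(spec) {
  set.seed(spec$seed + 303L)
  ps <- spec$proteome
  n <- ps$n_total
  need <- ps$n_targeting + ps$n_ta + ps$n_ta_decoy + ps$n_mbomp_pos +
    ps$n_mbomp_decoy + ps$rbh_pairs + ps$n_hmm
  if (need > n)
    stop("planted channel counts (", need, ") exceed n_total (", n, ")")
  ids <- sprintf("PROT_%05d", seq_len(n))
  lens <- 150L + sample(450L, n, replace = TRUE)
  # channel index blocks (disjoint by construction)
  cursor <- 0L
  take <- function(k) {
    out <- if (k > 0L) cursor + seq_len(k) else integer(0)
    cursor <<- cursor + k
    out
  }
  i_targ <- take(ps$n_targeting)
  i_ta <- take(ps$n_ta)
  i_ta_dec <- take(ps$n_ta_decoy)
  i_mb <- take(ps$n_mbomp_pos)
  i_mb_dec <- take(ps$n_mbomp_decoy)
  i_rbh <- take(ps$rbh_pairs)
  i_hmm <- take(ps$n_hmm)
  lens[c(i_mb, i_mb_dec)] <- 360L + sample(80L, length(c(i_mb, i_mb_dec)),
                                           replace = TRUE)
  seqs <- .rand_strings(n, lens, .AA20)
  ss <- .rand_strings(n, lens, c("H", "E", "C"), prob = c(0.30, 0.15, 0.55))

  # ---- targeting scores ----
  pa <- stats::runif(n, 0, 0.45)
  pb <- stats::runif(n, 0, 0.95)
  pa[i_targ] <- stats::runif(length(i_targ), 0.55, 0.95)
  pb[i_targ] <- stats::runif(length(i_targ), 0.55, 0.95)
  scores_a <- data.frame(protein_id = ids, tool = "predA", probability = pa,
                         stringsAsFactors = FALSE)
  scores_b <- data.frame(protein_id = ids, tool = "predB", probability = pb,
                         stringsAsFactors = FALSE)

  # ---- tail anchors ----
  tmd_rows <- list()
  for (i in i_ta) {
    d <- sample(0:32, 1L)
    e <- lens[i] - d
    s <- e - 19L
    substr(seqs[i], s, e) <- paste(sample(.HYDRO, 20L, replace = TRUE),
                                   collapse = "")
    tmd_rows[[length(tmd_rows) + 1L]] <- data.frame(
      protein_id = ids[i], start = s, end = e, source = "external_table",
      stringsAsFactors = FALSE)
  }
  for (i in i_ta_dec) {
    e <- lens[i] - 33L - sample(40L, 1L)
    s <- e - 19L
    substr(seqs[i], s, e) <- paste(sample(.HYDRO, 20L, replace = TRUE),
                                   collapse = "")
    tmd_rows[[length(tmd_rows) + 1L]] <- data.frame(
      protein_id = ids[i], start = s, end = e, source = "external_table",
      stringsAsFactors = FALSE)
  }
  tmd <- if (length(tmd_rows)) do.call(rbind, tmd_rows) else
    data.frame(protein_id = character(), start = integer(),
               end = integer(), source = character(),
               stringsAsFactors = FALSE)

  # ---- beta-signal / MBOMP ----
  plant_signal <- function(i, dist) {
    L <- lens[i]
    # scrub the scan neighbourhood so the planted motif is the only G
    scrub_from <- max(1L, L - max(30L, dist + 10L) + 1L)
    seqs[i] <<- `substr<-`(seqs[i], scrub_from, L,
                           paste(sample(c("D", "E", "K", "N", "S"),
                                        L - scrub_from + 1L,
                                        replace = TRUE), collapse = ""))
    cls <- beta_signal_classes()
    motif <- c(sample(cls$polar_set, 1L), sample(setdiff(.AA20, "G"), 1L),
               "G", sample(cls$hydrophobic_set, 1L),
               sample(setdiff(.AA20, "G"), 1L),
               sample(cls$hydrophobic_set, 1L),
               sample(setdiff(.AA20, "G"), 1L),
               sample(cls$hydrophobic_set, 1L))
    start <- L - dist - 7L
    seqs[i] <<- `substr<-`(seqs[i], start, start + 7L,
                           paste(motif, collapse = ""))
    start
  }
  set_ss <- function(i, start, e_frac, h_frac, sig_ss) {
    ctx_start <- start - 300L
    stopifnot(ctx_start >= 1L)
    substr(ss[i], ctx_start, start - 1L) <<- .ss_block(300L, e_frac, h_frac)
    substr(ss[i], start, start + 7L) <<- sig_ss
    if (start + 8L <= lens[i])
      substr(ss[i], start + 8L, lens[i]) <<-
        strrep("C", lens[i] - start - 7L)
  }
  for (i in i_mb) {
    st <- plant_signal(i, sample(0:5, 1L))
    set_ss(i, st, 0.35, 0.06, "CCEEEECC")
  }
  decoy_types <- rep(c("low_strand", "high_helix", "helical_signal",
                       "signal_far", "no_signal"),
                     length.out = length(i_mb_dec))
  for (j in seq_along(i_mb_dec)) {
    i <- i_mb_dec[j]
    L <- lens[i]
    type <- decoy_types[j]
    if (type == "low_strand") {
      st <- plant_signal(i, sample(0:5, 1L)); set_ss(i, st, 0.15, 0.06,
                                                     "CCEEEECC")
    } else if (type == "high_helix") {
      st <- plant_signal(i, sample(0:5, 1L)); set_ss(i, st, 0.35, 0.15,
                                                     "CCEEEECC")
    } else if (type == "helical_signal") {
      st <- plant_signal(i, sample(0:5, 1L)); set_ss(i, st, 0.35, 0.06,
                                                     "HHHHHCCC")
    } else if (type == "signal_far") {
      st <- plant_signal(i, 40L); set_ss(i, st, 0.35, 0.06, "CCEEEECC")
    } else { # no_signal: scrubbed C-terminus, no motif planted
      substr(seqs[i], L - 29L, L) <-
        paste(sample(c("D", "E", "K", "N", "S"), 30L, replace = TRUE),
              collapse = "")
      substr(ss[i], max(1L, L - 330L), L) <-
        .ss_block(min(331L, L), 0.35, 0.06)
    }
  }

  # ---- homology tables ----
  mk_hit <- function(q, s, e) {
    k <- length(q)
    if (!k) return(NULL)
    data.frame(query = q, subject = s,
               pct_identity = round(stats::runif(k, 30, 95), 1),
               aln_len = sample(80:400, k, replace = TRUE),
               mismatches = sample(0:50, k, replace = TRUE),
               gapopen = sample(0:5, k, replace = TRUE),
               qstart = rep(1L, k), qend = sample(80:400, k, replace = TRUE),
               sstart = rep(1L, k), send = sample(80:400, k, replace = TRUE),
               evalue = e, bitscore = round(stats::runif(k, 50, 500), 1),
               stringsAsFactors = FALSE)
  }
  db_ids <- sprintf("MM_%05d", seq_len(max(200L, ps$rbh_pairs) + 200L))
  rbh_db <- db_ids[seq_along(i_rbh)]
  fwd <- mk_hit(ids[i_rbh], rbh_db, 10^stats::runif(length(i_rbh), -12, -6))
  rev <- mk_hit(rbh_db, ids[i_rbh], 10^stats::runif(length(i_rbh), -12, -6))
  n_noise <- max(50L, n %/% 2L)
  noise_q <- sample(ids, n_noise, replace = TRUE)
  noise_s <- sample(db_ids, n_noise, replace = TRUE)
  fwd <- rbind(fwd, mk_hit(noise_q, noise_s,
                           10^stats::runif(n_noise, -3, 1)))
  rev <- rbind(rev, mk_hit(sample(db_ids, n_noise, replace = TRUE),
                           sample(ids, n_noise, replace = TRUE),
                           10^stats::runif(n_noise, -3, 1)))

  # ---- HMM channel ----
  hmm_ids <- ids[i_hmm]
  hmm_db_ids <- hmm_ids[seq_len(min(ps$n_hmm_with_db, length(hmm_ids)))]
  hmm_hits <- if (length(hmm_ids)) data.frame(
    protein_id = hmm_ids,
    profile = sprintf("PF%05d", sample(1000L, length(hmm_ids))),
    evalue = 10^stats::runif(length(hmm_ids), -10, -4),
    stringsAsFactors = FALSE) else
    data.frame(protein_id = character(), profile = character(),
               evalue = numeric(), stringsAsFactors = FALSE)
  if (length(hmm_db_ids))
    fwd <- rbind(fwd, mk_hit(hmm_db_ids,
                             sample(db_ids, length(hmm_db_ids)),
                             10^stats::runif(length(hmm_db_ids), -8, -4)))

  manifest <- list(
    targeting = ids[i_targ],
    tail_anchor = ids[i_ta],
    tail_anchor_decoys = ids[i_ta_dec],
    mbomp = ids[i_mb],
    mbomp_decoys = data.frame(protein_id = ids[i_mb_dec],
                              type = decoy_types,
                              stringsAsFactors = FALSE),
    rbh = data.frame(query = ids[i_rbh], subject = rbh_db,
                     stringsAsFactors = FALSE),
    hmm = hmm_ids, hmm_with_db = hmm_db_ids
  )
  list(proteins = seq_records(ids, seqs, alphabet = "protein"),
       ss3 = seq_records(ids, ss, alphabet = "ss3"),
       scores_a = scores_a, scores_b = scores_b, tmd = tmd,
       hits_fwd = hit_table(fwd), hits_rev = hit_table(rev),
       hmm_hits = hmm_hits, manifest = manifest)
}
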