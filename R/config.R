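#' Pipeline configuration
#'
#' Central container for every tunable threshold used across the pipeline.
#' Defaults follow the study's stated cutoffs: reciprocal-BLAST e-value
#' 0.001, dual targeting-probability consensus strictly > 0.5, tail-anchor
#' TMD within 32 aa of the C-terminus, 300 aa of secondary-structure context
#' before the beta-signal with >= 25% strand / <= 10% helix and <= 50%
#' helical motif residues, exact (1.00) and near (0.95) clustering identity
#' with the equal-length rule, last-100-bp 3'UTR tail window, 10 bp Kozak
#' flanks, and 5 kb coding-density windows.
#'
#' @param evalue_max maximum e-value for homology hits (reciprocal best hits,
#'   database joins).
#' @param targeting_prob_min both targeting predictors must exceed this
#'   probability (strict \code{>}) for the consensus channel.
#' @param ta_cterm_window maximum distance (aa, inclusive) from the last TMD
#'   residue to the C-terminus for a tail-anchor call.
#' @param mbomp_context length (aa) of the secondary-structure window
#'   preceding the beta-signal.
#' @param mbomp_min_strand minimum strand (E) fraction in the context window.
#' @param mbomp_max_helix maximum helix (H) fraction in the context window.
#' @param mbomp_max_signal_helix maximum fraction of the 8 beta-signal
#'   residues predicted helical.
#' @param beta_signal_len length of the beta-signal motif (residues).
#' @param beta_cterm_window the motif's last residue must lie within this
#'   many residues of the C-terminus.
#' @param utr3_tail_window length (bp) of the terminal 3'UTR window scanned
#'   for polyadenylation signals.
#' @param kozak_flank bases extracted up- and downstream of the start codon.
#' @param cluster_exact_identity identity for the exact clustering stage.
#' @param cluster_near_identity identity for the near clustering stage.
#' @param coding_window window size (bp) for coding-density profiles.
#' @param motif_k k-mer size for the enrichment scan.
#' @param telomere_unit telomeric repeat unit searched at contig ends.
#' @param telomere_min_units minimum tandem copies for a telomere call.
#' @param telomere_max_mismatch total mismatches tolerated across a tandem run.
#' @param telomere_search_window bases searched at each contig end.
#' @param full_length_tolerance maximum distance (bp) between a read's polyA
#'   boundary and the annotated 3'UTR end for a full-length call.
#'
#' @return a list of class \code{mx_config}.
#' @export
mx_config <- function(evalue_max = 0.001,
                      targeting_prob_min = 0.5,
                      ta_cterm_window = 32L,
                      mbomp_context = 300L,
                      mbomp_min_strand = 0.25,
                      mbomp_max_helix = 0.10,
                      mbomp_max_signal_helix = 0.50,
                      beta_signal_len = 8L,
                      beta_cterm_window = 15L,
                      utr3_tail_window = 100L,
                      kozak_flank = 10L,
                      cluster_exact_identity = 1.00,
                      cluster_near_identity = 0.95,
                      coding_window = 5000L,
                      motif_k = 6L,
                      telomere_unit = "TTAGGG",
                      telomere_min_units = 5L,
                      telomere_max_mismatch = 2L,
                      telomere_search_window = 500L,
                      full_length_tolerance = 0L) {
  cfg <- list(
    evalue_max = evalue_max,
    targeting_prob_min = targeting_prob_min,
    ta_cterm_window = as.integer(ta_cterm_window),
    mbomp_context = as.integer(mbomp_context),
    mbomp_min_strand = mbomp_min_strand,
    mbomp_max_helix = mbomp_max_helix,
    mbomp_max_signal_helix = mbomp_max_signal_helix,
    beta_signal_len = as.integer(beta_signal_len),
    beta_cterm_window = as.integer(beta_cterm_window),
    utr3_tail_window = as.integer(utr3_tail_window),
    kozak_flank = as.integer(kozak_flank),
    cluster_exact_identity = cluster_exact_identity,
    cluster_near_identity = cluster_near_identity,
    coding_window = as.integer(coding_window),
    motif_k = as.integer(motif_k),
    telomere_unit = toupper(telomere_unit),
    telomere_min_units = as.integer(telomere_min_units),
    telomere_max_mismatch = as.integer(telomere_max_mismatch),
    telomere_search_window = as.integer(telomere_search_window),
    full_length_tolerance = as.integer(full_length_tolerance)
  )
  probs <- c("targeting_prob_min", "mbomp_min_strand", "mbomp_max_helix",
             "mbomp_max_signal_helix", "cluster_exact_identity",
             "cluster_near_identity")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("config '%s' must lie in [0, 1]", p))
  }
  wins <- c("ta_cterm_window", "mbomp_context", "utr3_tail_window",
            "kozak_flank", "coding_window", "motif_k", "beta_signal_len",
            "telomere_min_units", "telomere_search_window")
  for (w in wins) {
    if (cfg[[w]] <= 0L) stop(sprintf("config '%s' must be > 0", w))
  }
  if (cfg$evalue_max < 0) stop("config 'evalue_max' must be >= 0")
  structure(cfg, class = c("mx_config", "list"))
}
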