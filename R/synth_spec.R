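#' Specification for the synthetic-data generator
#'
#' Parameters default to the structural features of the real study system
#' where the study states them: background GC 37.2%, mean 3'UTR 312 bp and
#' 5'UTR 62 bp, ~1.95 introns per gene of mean length 119 bp with AT-rich
#' (27.6% GC) composition, hexamer polyadenylation signal AATAAA planted
#' 20-30 bp upstream of the cleavage site with U(T)-rich flanks
#' (probability 0.6 vs background 0.25), telomeric caps of 12 tandem repeat
#' units, and a proteome with 24 planted dual-targeting positives, 7
#' tail-anchor and 2 beta-barrel (MBOMP) positives among 4665 proteins.
#' Genome-scale counts (contigs, genes) are desk-scale, not genome-scale.
#'
#' @param seed integer master seed; sub-generators use fixed offsets.
#' @param n_contigs number of contigs.
#' @param n_both_telomeres contigs capped at both ends.
#' @param n_one_telomere contigs capped at exactly one end.
#' @param telomere_unit repeat unit (written forward at 5' ends, reverse
#'   complement at 3' ends).
#' @param telomere_units_per_end tandem copies per capped end.
#' @param gc background GC fraction.
#' @param intron_gc intron GC fraction.
#' @param n_genes number of genes.
#' @param intron_rate mean introns per gene (Poisson).
#' @param utr5_mean_len,utr3_mean_len mean UTR lengths (bp).
#' @param utr5_fraction,utr3_fraction fraction of genes given each UTR.
#' @param intergenic_mean_len mean intergenic gap (bp, minimum 300).
#' @param polya_motif planted hexamer (DNA alphabet).
#' @param polya_offset_range inclusive range of the motif-start offset,
#'   counted upstream from the cleavage site.
#' @param polya_plant_fraction fraction of 3'UTR-bearing genes that receive
#'   the motif.
#' @param u_rich_flank plant T-rich 10 bp flanks around the motif.
#' @param full_length_fraction fraction of 3'UTR genes covered by a
#'   full-length transcript read.
#' @param n_fusion_events adjacent new-gene pairs merged into one old model
#'   (these old tags split on transfer).
#' @param n_split_events new genes broken into two old models (these old
#'   tag pairs fuse on transfer).
#' @param n_frameshift_events old gene copies with a single-base indel.
#' @param contig_pieces number of pieces each contig is cut into for the
#'   old assembly.
#' @param proteome list: n_total, n_targeting, n_ta, n_ta_decoy,
#'   n_mbomp_pos, n_mbomp_decoy, rbh_pairs, n_hmm, n_hmm_with_db.
#' @return validated list of class \code{synthesis_spec}.
#' @export
synthesis_spec <- function(seed = 1L,
                           n_contigs = 10L,
                           n_both_telomeres = 2L,
                           n_one_telomere = 3L,
                           telomere_unit = "TTAGGG",
                           telomere_units_per_end = 12L,
                           gc = 0.372,
                           intron_gc = 0.276,
                           n_genes = 200L,
                           intron_rate = 1.95,
                           utr5_mean_len = 62,
                           utr3_mean_len = 312,
                           utr5_fraction = 0.4,
                           utr3_fraction = 0.6,
                           intergenic_mean_len = 1855,
                           polya_motif = "AATAAA",
                           polya_offset_range = c(20L, 30L),
                           polya_plant_fraction = 0.8,
                           u_rich_flank = TRUE,
                           full_length_fraction = 0.7,
                           n_fusion_events = 5L,
                           n_split_events = 3L,
                           n_frameshift_events = 2L,
                           contig_pieces = 2L,
                           proteome = list()) {
  pdef <- list(n_total = 4665L, n_targeting = 24L, n_ta = 7L,
               n_ta_decoy = 7L, n_mbomp_pos = 2L, n_mbomp_decoy = 6L,
               rbh_pairs = 326L, n_hmm = 28L, n_hmm_with_db = 6L)
  pdef[names(proteome)] <- proteome
  spec <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    n_both_telomeres = as.integer(n_both_telomeres),
    n_one_telomere = as.integer(n_one_telomere),
    telomere_unit = toupper(telomere_unit),
    telomere_units_per_end = as.integer(telomere_units_per_end),
    gc = gc, intron_gc = intron_gc,
    n_genes = as.integer(n_genes), intron_rate = intron_rate,
    utr5_mean_len = utr5_mean_len, utr3_mean_len = utr3_mean_len,
    utr5_fraction = utr5_fraction, utr3_fraction = utr3_fraction,
    intergenic_mean_len = intergenic_mean_len,
    polya_motif = toupper(polya_motif),
    polya_offset_range = as.integer(polya_offset_range),
    polya_plant_fraction = polya_plant_fraction,
    u_rich_flank = isTRUE(u_rich_flank),
    full_length_fraction = full_length_fraction,
    n_fusion_events = as.integer(n_fusion_events),
    n_split_events = as.integer(n_split_events),
    n_frameshift_events = as.integer(n_frameshift_events),
    contig_pieces = as.integer(contig_pieces),
    proteome = pdef
  )
  counts <- c(spec$n_contigs, spec$n_both_telomeres, spec$n_one_telomere,
              spec$n_genes, spec$n_fusion_events, spec$n_split_events,
              spec$n_frameshift_events, unlist(pdef))
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (spec$n_both_telomeres + spec$n_one_telomere > spec$n_contigs)
    stop("more telomere-bearing contigs requested than contigs")
  fr <- c(spec$polya_plant_fraction, spec$utr5_fraction, spec$utr3_fraction,
          spec$full_length_fraction, spec$gc, spec$intron_gc)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (spec$intergenic_mean_len < 301)
    stop("intergenic_mean_len must exceed 300")
  r <- spec$polya_offset_range
  if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > 100L)
    stop("polya_offset_range must be within [1, 100] and ordered")
  if (r[1] < nchar(spec$polya_motif))
    stop("polya offset must leave the motif upstream of the cleavage site")
  structure(spec, class = c("synthesis_spec", "list"))
}

# random DNA with given GC fraction
.rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

.STOPS <- c("TAA", "TAG", "TGA")
.codon_pool <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, .STOPS)
}
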