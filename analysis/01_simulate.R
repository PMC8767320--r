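#!/usr/bin/env Rscript
# Step 1: generate the synthetic study system.
#
# Builds a seeded genome (telomere-capped contigs, intron-bearing genes,
# planted polyadenylation signals), derives a fragmented "old" assembly
# with known fusion/split/frameshift events, emits oligo-dT transcript
# evidence, and generates a proteome with planted mitochondrial-hallmark
# positives. All downstream steps read these files; truth.json records
# every planted feature.

suppressPackageStartupMessages(library(mxpipe))

seed <- 7L
out <- "results/synth"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthesis_spec(seed = seed, n_genes = 500, n_contigs = 10)
message("generating genome: ", spec$n_genes, " genes on ", spec$n_contigs,
        " contigs (seed ", seed, ")")
g <- make_genome(spec)
write_fasta(g$contigs, file.path(out, "genome.fasta"))
write_gff3(g$models, file.path(out, "annotation.gff3"))

old <- derive_old_assembly(g, spec)
message("derived old assembly: ", nrow(old$contigs), " pieces; planted ",
        spec$n_fusion_events, " fusion, ", spec$n_split_events, " split, ",
        spec$n_frameshift_events, " frameshift events")
write_fasta(old$contigs, file.path(out, "old_assembly.fasta"))
write_gff3(old$models, file.path(out, "old_annotation.gff3"))
write_gff3(old$mapped_models, file.path(out, "old_mapped_on_new.gff3"))
write_tsvc(old$correspondence, file.path(out, "correspondence.tsv"))

te <- make_transcript_evidence(g, spec)
message("transcript evidence: ", nrow(te$reads), " reads, ",
        length(te$full_length_tags), " genes with a full-length read")
reads_out <- te$reads
reads_out$full_length <- as.integer(reads_out$full_length)
write_tsvc(reads_out, file.path(out, "reads.tsv"))

p <- make_proteome(spec)
message("proteome: ", nrow(p$proteins), " proteins (",
        length(p$manifest$targeting), " targeting / ",
        length(p$manifest$tail_anchor), " TA / ",
        length(p$manifest$mbomp), " MBOMP positives, ",
        nrow(p$manifest$rbh), " RBH pairs planted)")
write_fasta(p$proteins, file.path(out, "proteome.faa"))
write_fasta(p$ss3, file.path(out, "ss3.faa"))
write_tsvc(rbind(p$scores_a, p$scores_b),
           file.path(out, "targeting_scores.tsv"))
write_tsvc(p$tmd, file.path(out, "tmd.tsv"))
write_hits(p$hits_fwd, file.path(out, "hits_fwd.tsv"))
write_hits(p$hits_rev, file.path(out, "hits_rev.tsv"))
write_tsvc(p$hmm_hits, file.path(out, "hmm_hits.tsv"))

truth <- list(
  seed = seed,
  contigs = g$manifest$contigs,
  genes = g$manifest$genes,
  full_length_tags = te$full_length_tags,
  proteome = p$manifest
)
jsonlite::write_json(truth, file.path(out, "truth.json"), digits = NA)
message("wrote ", out, "/truth.json")
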