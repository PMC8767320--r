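#!/usr/bin/env Rscript
# Step 2: assembly and annotation statistics.
#
# N50/GC/size, telomeric-end classification and the chromosome-number
# estimate, 5 kb coding-density windows, and the gene/intron/UTR metrics.
# Also prints the estimate obtained from the published telomere tallies
# (10 both-ended + 65 one-ended contigs), the study's headline worked
# example.

suppressPackageStartupMessages(library(mxpipe))

synth <- "results/synth"
out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

contigs <- read_fasta(file.path(synth, "genome.fasta"))
models <- read_gff3(file.path(synth, "annotation.gff3"))

st <- assembly_stats(contigs)
message(sprintf("assembly: %d contigs, %d bp, N50 %d, GC %.1f%%",
                st$n_contigs, st$total_len, st$n50, st$gc_percent))
write_tsvc(as.data.frame(st), file.path(out, "stats.tsv"))

tel <- telomere_calls(contigs, unit = "TTAGGG", min_units = 5)
write_tsvc(tel, file.path(out, "telomeres.tsv"))
n_both <- sum(tel$five_prime & tel$three_prime)
n_one <- sum(xor(tel$five_prime, tel$three_prime))
est <- estimate_chromosomes(n_both, n_one)
message(sprintf("telomeres: %d both-ended, %d one-ended -> %.1f chromosomes (range %d-%d)",
                n_both, n_one, est$point, est$low, est$high))

pub <- estimate_chromosomes(10, 65)
message(sprintf("published tallies (10 both, 65 one) -> %.1f chromosomes (range %d-%d)",
                pub$point, pub$low, pub$high))

lens <- stats::setNames(nchar(contigs$seq), contigs$id)
cd <- coding_density(models, lens, window = 5000)
write_tsvc(cd$windows, file.path(out, "density.tsv"))
message(sprintf("coding density: %.1f%% of contig length covered by CDS",
                100 * sum(cd$per_contig$cds_bases) / sum(lens)))

gm <- gene_metrics(models, contigs)
write_tsvc(data.frame(metric = names(gm),
                      value = unlist(lapply(gm, format))),
           file.path(out, "gene_metrics.tsv"))
message(sprintf("genes: %d, mean length %.0f bp, %.2f introns/gene (mean %.0f bp, GC %.1f%%)",
                gm$n_genes, gm$mean_gene_length, gm$introns_per_gene,
                gm$mean_intron_length, gm$intron_gc_percent))
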