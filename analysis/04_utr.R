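#!/usr/bin/env Rscript
# Step 4: UTR landscape.
#
# Select full-length 3'UTRs by the oligo-dT boundary criterion, scan their
# last 100 bp for enriched hexamers against a dinucleotide-shuffle null,
# profile the top motifs and the U content upstream of the cleavage site,
# and build the Kozak position-frequency matrix.

suppressPackageStartupMessages(library(mxpipe))

synth <- "results/synth"
out <- "results/utr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 7L

contigs <- read_fasta(file.path(synth, "genome.fasta"))
models <- read_gff3(file.path(synth, "annotation.gff3"))
reads <- read_reads(file.path(synth, "reads.tsv"))

u3 <- extract_utrs(contigs, models, "three_prime")
u5 <- extract_utrs(contigs, models, "five_prime")
st <- utr_stats(rbind(u3, u5))
message(sprintf("UTRs: %d 3' (mean %.0f bp, GC %.1f%%), %d 5' (mean %.0f bp)",
                st$three_prime$n, st$three_prime$mean_length,
                st$gc3_percent, st$five_prime$n,
                st$five_prime$mean_length))
write_tsvc(data.frame(
  kind = c("three_prime", "five_prime"),
  n = c(st$three_prime$n, st$five_prime$n),
  mean_length = c(st$three_prime$mean_length, st$five_prime$mean_length),
  n_introns = c(st$three_prime$n_introns, st$five_prime$n_introns)),
  file.path(out, "utr_stats.tsv"))

fl <- flag_full_length_3utr(u3, reads, models, tolerance = 0)
message(sprintf("full-length 3'UTRs: %d of %d", sum(fl$full_length),
                nrow(fl)))
tails <- terminal_window(fl[fl$full_length, ], 100)

enr <- kmer_enrichment(tails$seq, k = 6, n_shuffles = 100, seed = seed)
write_tsvc(enr[1:50, ], file.path(out, "motifs.tsv"))
top <- enr$kmer_rna[1:2]
message("top enriched hexamers: ",
        paste(sprintf("%s (z=%.1f)", top, enr$z[1:2]), collapse = ", "))

pp1 <- positional_profile(tails$seq, enr$kmer[1])
pp2 <- positional_profile(tails$seq, enr$kmer[2])
up <- u_profile(tails$seq)
message(sprintf("%s peaks at %d; half of its occurrences fall in [%d, %d]",
                top[1], pp1$peak_position, pp1$window[1], pp1$window[2]))
write_tsvc(data.frame(position = pp1$positions,
                      motif_prob_1 = pp1$values,
                      motif_prob_2 = pp2$values,
                      u_content = up$values),
           file.path(out, "profiles.tsv"))

kz <- kozak_matrix(contigs, models, flank = 10)
message(sprintf("Kozak context from %d genes (%d excluded): upstream AT %.2f, consensus %s",
                kz$n_used, kz$n_excluded, kz$upstream_at_fraction,
                kz$consensus))
write_tsvc(data.frame(base = rownames(kz$matrix),
                      as.data.frame(kz$matrix, check.names = FALSE)),
           file.path(out, "kozak.tsv"))
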