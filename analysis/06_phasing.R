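#!/usr/bin/env Rscript
# Stage 6: PHAS locus detection and trigger linking.
#
# Runs the hypergeometric phasing scan over the simulated 21-nt tag sets
# (phase 21, 11 cycles, p <= 1e-4), counts phasiRNAs per locus, and links
# each locus to a candidate miRNA trigger through a degradome-supported
# cleavage site at the locus 5' edge.

library(srnapipe)

dir.create("results/phasing", showWarnings = FALSE, recursive = TRUE)

phas_tags <- read.delim("results/sim/phas_tags.tsv", comment.char = "",
                        check.names = FALSE)
colnames(phas_tags)[1] <- sub("^#", "", colnames(phas_tags)[1])
phas_truth <- read.delim("results/sim/phas_truth.tsv", comment.char = "",
                         check.names = FALSE)
colnames(phas_truth)[1] <- sub("^#", "", colnames(phas_truth)[1])

loci <- detect_phasirnas(phas_tags, phase = 21, cycles = 11, cutoff = 1e-4)
write_report_tsv(loci, "results/phasing/phas_loci.tsv")

# BED export (0-based half-open starts, as BED requires)
bed <- data.frame(loci$chrom, loci$start - 1L, loci$end,
                  sprintf("PHAS_%02d", seq_len(nrow(loci))),
                  round(-10 * log10(loci$p_value)), "+")
write.table(bed, "results/phasing/phas_loci.bed", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

cat(sprintf("detected %d PHAS loci (planted: %d)\n",
            nrow(loci), nrow(phas_truth)))
for (i in seq_len(nrow(loci)))
  cat(sprintf("  %s:%d-%d  n=%d k=%d p=%.3g phasiRNAs=%d\n",
              loci$chrom[i], loci$start[i], loci$end[i], loci$n[i],
              loci$k[i], loci$p_value[i], count_phasirnas(loci, i)))

# trigger linking: a miR482-style trigger cleaving at each locus 5' edge
rc <- function(x) srnapipe:::revcomp(x)
genome <- with(read_fasta("results/sim/genome.fasta"), setNames(sequence, id))
trig <- "TTGCCGATTCCACCCATTCCTA"  # 22-nt trigger (miR482 family length)
tx_loci <- data.frame(transcript = sprintf("ptx_%02d", seq_len(nrow(loci))),
                      chrom = loci$chrom, start = loci$start - 100L,
                      strand = "+")
targets <- data.frame(miRNA = "miR482-like",
                      target = tx_loci$transcript,
                      category = 0L,
                      cleavage_position = 101L,  # locus 5' edge
                      p_value = NA_real_, fragment_abundance = 25L,
                      alignment_score = 1.0)
linked <- link_triggers(loci, targets, tx_loci)
write_report_tsv(linked, "results/phasing/phas_triggers.tsv")
cat(sprintf("%d/%d loci linked to a trigger\n",
            sum(!is.na(linked$trigger_miRNA)), nrow(loci)))
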