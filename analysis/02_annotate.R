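#!/usr/bin/env Rscript
# Stage 2: length-filter and annotate the simulated sRNA tags.
#
# Applies the 18-28 nt length filter, matches tags to the genome on both
# strands, and classifies each tag by the priority rule
# rRNAetc (GenBank > Rfam) > known miRNA > repeat > exon > intron > unann.
# The known-miRNA database here is the first half of the planted matures
# (standing in for a curated set); the rest must surface later as novel.

library(srnapipe)

dir.create("results/annotation", showWarnings = FALSE, recursive = TRUE)

study_tags <- read_tag_table("results/sim/tags.tsv")
genome <- with(read_fasta("results/sim/genome.fasta"),
               setNames(sequence, id))
truth <- read.delim("results/sim/mirna_truth.tsv", comment.char = "",
                    check.names = FALSE)
colnames(truth)[1] <- sub("^#", "", colnames(truth)[1])

filtered <- length_filter(study_tags, 18, 28)
rm_mass <- attr(filtered, "removed")
cat(sprintf("length filter removed %d unique / %d total reads\n",
            rm_mass["unique"], rm_mass["total"]))

half <- seq_len(ceiling(nrow(truth) / 2))
known_db <- data.frame(id = truth$locus_id[half],
                       sequence = truth$mature[half])
ann <- annotate(filtered, genome, known_mirna_db = known_db)

write_report_tsv(ann$summary, "results/annotation/summary.tsv")
write_report_tsv(ann$annotated[, c("sequence", "category", "matched_source",
                                   "n_genome_hits")],
                 "results/annotation/annotated.tsv")
write_report_tsv(length_distribution(filtered), "results/annotation/length_all.tsv")
write_report_tsv(length_distribution(ann$annotated, by = "miRNA"),
                 "results/annotation/length_mirna.tsv")

tab <- table(ann$annotated$category)
cat("tags per category:\n")
print(tab)
clean <- ann$summary[ann$summary$category == "clean", ]
mg <- ann$summary[ann$summary$category == "match_genome", ]
cat(sprintf("genome-match rate (total reads): %s%%\n",
            paste(mg$total_pct, collapse = ", ")))
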