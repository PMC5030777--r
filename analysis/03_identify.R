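#!/usr/bin/env Rscript
# Stage 3: identify known miRNAs and predict novel ones.
#
# Known side: tags are aligned to the known-miRNA set (2 mismatches /
# 3 gaps), one representative per family is chosen by expression, and
# expression is re-quantified against the representatives (ungapped,
# <= 2 mismatches). Novel side: unannotated genome-matched tags are folded
# in flanking windows and kept only when the hairpin, 2-nt-overhang star
# (observed in the data), bulge, MFE and count criteria all hold; loci are
# then required in both replicates of a genotype.

library(srnapipe)

dir.create("results/identification", showWarnings = FALSE, recursive = TRUE)

tags <- read_tag_table("results/sim/tags.tsv")
genome <- with(read_fasta("results/sim/genome.fasta"), setNames(sequence, id))
truth <- read.delim("results/sim/mirna_truth.tsv", comment.char = "",
                    check.names = FALSE)
colnames(truth)[1] <- sub("^#", "", colnames(truth)[1])
ann_tab <- read.delim("results/annotation/annotated.tsv", comment.char = "",
                      check.names = FALSE)
colnames(ann_tab)[1] <- sub("^#", "", colnames(ann_tab)[1])

half <- seq_len(ceiling(nrow(truth) / 2))
known_db <- data.frame(id = truth$locus_id[half],
                       family = paste0("fam_", truth$locus_id[half]),
                       sequence = truth$mature[half])

# family assignment for every tag that aligns within budget
assignments <- do.call(rbind, lapply(tags$sequence, function(s) {
  hit <- align_to_mirbase(s, known_db)
  if (nrow(hit)) data.frame(sequence = s, family = hit$family[1]) else NULL
}))
cat(sprintf("%d tags assigned to %d known families\n",
            nrow(assignments), length(unique(assignments$family))))

temp_db <- build_family_representatives(assignments, tags)
known_counts <- quantify_known(tags, temp_db)
write_report_tsv(data.frame(family = rownames(known_counts), known_counts,
                            check.names = FALSE),
                 "results/identification/known.tsv")

# novel prediction from tags not in the known set
annotated <- merge(as.data.frame(tags), ann_tab, by = "sequence")
novel <- predict_novel(tags, genome, annotated = annotated)
write_report_tsv(novel[, setdiff(colnames(novel), "precursor")],
                 "results/identification/novel.tsv")
write_fasta(setNames(novel$precursor, novel$name),
            "results/identification/novel_precursors.fasta")

# replicate-consistency: a miRNA is kept for a genotype iff present (count
# >= 1) in both of its replicate libraries
libs <- tag_libraries(tags)
groups <- list(MT = grep("^MT", libs, value = TRUE),
               WT = grep("^WT", libs, value = TRUE))
flags <- as.data.frame(novel[, libs] >= 1)
flags$miRNA <- novel$name
merged <- merge_replicates(flags, groups)
write_report_tsv(merged[, c("miRNA", "MT", "WT", "both_genotypes")],
                 "results/identification/novel_replicated.tsv")

planted_unknown <- truth$mature[-half]
cat(sprintf("novel loci accepted: %d; planted non-database loci recovered: %d/%d\n",
            nrow(novel),
            sum(planted_unknown %in% novel$mature |
                  truth$star[-half] %in% novel$mature),
            length(planted_unknown)))
cat(sprintf("replicate-consistent in both genotypes: %d\n",
            sum(merged$both_genotypes)))
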