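#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study.
#
# Builds a toy genome with planted miRNA hairpin loci and 21-nt phased
# (PHAS) windows, then draws four small-RNA libraries (two genotypes, MT and
# WT, two biological replicates each) with heavy-tailed locus abundances,
# Poisson replicate noise, low-abundance star tags, random background tags,
# and an 8x fold change injected into two loci in the MT group.

library(srnapipe)

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1, n_mirna_loci = 8, n_phas_loci = 3,
                  genome_length = 50000,
                  fold_changes = c(mir_02 = 8, mir_05 = 8))
study <- simulate_study(cfg)

write_fasta(study$genome, "results/sim/genome.fasta")
write_fasta(setNames(study$mirna_truth$precursor, study$mirna_truth$locus_id),
            "results/sim/precursors.fasta")
write_tag_table(study$tags, "results/sim/tags.tsv")
write_report_tsv(study$mirna_truth, "results/sim/mirna_truth.tsv")
write_report_tsv(study$phas_truth, "results/sim/phas_truth.tsv")
write_report_tsv(study$phas_tags, "results/sim/phas_tags.tsv")
jsonlite::write_json(unclass(cfg), "results/sim/sim_config.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("simulated %d tags across %d libraries (%d miRNA loci, %d PHAS loci)\n",
            nrow(study$tags), length(tag_libraries(study$tags)),
            nrow(study$mirna_truth), nrow(study$phas_truth)))
cat(sprintf("total reads per library: %s\n",
            paste(colSums(tag_counts(study$tags)), collapse = ", ")))
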