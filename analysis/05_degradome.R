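#!/usr/bin/env Rscript
# Stage 5: degradome target calling.
#
# Builds synthetic transcripts carrying a perfectly complementary site for
# each planted mature miRNA, generates degradome profiles with the dominant
# peak at the predicted slicing position (opposite miRNA nt 10), then runs
# pre-processing (Rfam > GenBank > polyN), target calling at score <= 4.5,
# category classification, and T-plot data export.

library(srnapipe)

dir.create("results/degradome", showWarnings = FALSE, recursive = TRUE)
dir.create("results/degradome/tplots", showWarnings = FALSE)

truth <- read.delim("results/sim/mirna_truth.tsv", comment.char = "",
                    check.names = FALSE)
colnames(truth)[1] <- sub("^#", "", colnames(truth)[1])
rc <- function(x) srnapipe:::revcomp(x)

mirnas <- data.frame(name = truth$locus_id, sequence = truth$mature)
set.seed(51)
transcripts <- list(); profiles <- list()
for (i in seq_len(nrow(mirnas))) {
  tx <- sprintf("tx_%02d", i)
  flank5 <- srnapipe:::random_dna(150)
  flank3 <- srnapipe:::random_dna(150)
  transcripts[[tx]] <- paste0(flank5, rc(mirnas$sequence[i]), flank3)
  site <- 150L + nchar(mirnas$sequence[i]) - 9L
  # vary the requested category across transcripts to exercise the classifier
  cat_i <- c(0L, 0L, 1L, 2L, 0L, 3L, 0L, 4L)[(i - 1L) %% 8L + 1L]
  profiles[[tx]] <- gen_degradome_profile(tx, nchar(transcripts[[tx]]), site,
                                          signal = 40L, background = 10L,
                                          category = cat_i, seed = 500L + i)
}

# degradome tag table (the peak tags) for pre-processing demonstration
deg_tags <- tag_table(
  c(vapply(seq_along(profiles), function(i) {
      tx <- names(profiles)[i]
      substr(transcripts[[tx]], 150L + 12L, 150L + 12L + 19L)
    }, character(1)),
    strrep("A", 20),                      # polyN
    paste0(strrep("A", 14), "CGTGCC")),   # 70% exactly: kept
  data.frame(lib1 = rep(1L, length(profiles) + 2L)))
pre <- preprocess_degradome(deg_tags)
cat(sprintf("degradome pre-processing removed %d tag(s): %s\n",
            nrow(pre$ledger), paste(pre$ledger$removed_as, collapse = ", ")))

targets <- call_targets(mirnas, transcripts, profiles, max_score = 4.5)
write_report_tsv(targets, "results/degradome/targets.tsv")
for (j in seq_len(nrow(targets))) {
  tx <- targets$target[j]
  write_tplot_data(profiles[[tx]], targets$cleavage_position[j],
                   sprintf("results/degradome/tplots/%s_%s.tsv",
                           targets$miRNA[j], tx))
}

cat(sprintf("%d miRNA-target pairs called (score <= 4.5)\n", nrow(targets)))
cat("category counts:\n")
print(table(targets$category))
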