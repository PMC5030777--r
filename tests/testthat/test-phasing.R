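test_that("the detector p-value equals the enumerated hypergeometric tail", {
  for (n in 3:12) {
    for (k in 3:n) {
      expect_equal(phasing_pvalue(n, k), brute_hyper_tail(n, k),
                   tolerance = 1e-12, label = sprintf("n=%d k=%d", n, k))
    }
  }
  expect_error(phasing_pvalue(5, 3, cycles = 1), "cycles")
  expect_error(phasing_pvalue(1000, 3), "exceeds")
})

test_that("a fully phased planted locus is detected below the 1e-4 cutoff", {
  cfg <- sim_config(seed = 23)
  g <- gen_genome(cfg)
  w <- g$phas_truth$start[1]
  tags <- gen_phas_locus(cfg, g$genome, w, n_cycles = 11, n_phased = 11,
                         n_offphase = 0)
  res <- detect_phasirnas(tags)
  expect_equal(nrow(res), 1)
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$k, 11)
  expect_equal(res$start, w)
  expect_equal(count_phasirnas(res, 1), 11)
})

test_that("off-phase-only and short-length tag sets yield no loci", {
  cfg <- sim_config(seed = 24)
  g <- gen_genome(cfg)
  w <- g$phas_truth$start[1]
  offs <- gen_phas_locus(cfg, g$genome, w, n_cycles = 11, n_phased = 0,
                         n_offphase = 50)
  expect_equal(nrow(detect_phasirnas(offs)), 0)

  # 22-nt tags are excluded by the length rule even if perfectly phased
  tags <- gen_phas_locus(cfg, g$genome, w, n_cycles = 11, n_phased = 11,
                         n_offphase = 0)
  tags$sequence <- paste0(tags$sequence, "A")  # now 22 nt
  expect_equal(nrow(detect_phasirnas(tags)), 0)
})

test_that("antisense tags are shifted onto the sense register", {
  cfg <- sim_config(seed = 26)
  g <- gen_genome(cfg)
  w <- g$phas_truth$start[1]
  tags <- gen_phas_locus(cfg, g$genome, w, n_cycles = 11, n_phased = 11,
                         n_offphase = 0, seed = 4)
  expect_true(any(tags$strand == "-"))
  res <- detect_phasirnas(tags)
  expect_equal(res$k, 11)  # both strands contribute to the register
})

test_that("the statistic is invariant under translation by one phase", {
  cfg <- sim_config(seed = 25)
  g <- gen_genome(cfg)
  w <- g$phas_truth$start[1]
  tags <- gen_phas_locus(cfg, g$genome, w, n_cycles = 11, n_phased = 8,
                         n_offphase = 4)
  res <- detect_phasirnas(tags)
  shifted <- tags
  shifted$start <- shifted$start + 21L
  res2 <- detect_phasirnas(shifted)
  expect_equal(res2$n, res$n)
  expect_equal(res2$k, res$k)
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res2$start, res$start + 21L)
})

test_that("random unphased windows are almost never significant", {
  set.seed(61)
  pop <- 2L * 21L * 11L
  ps <- replicate(2000, {
    n <- sample(5:30, 1)
    draw <- sample(pop, n)
    phasing_pvalue(n, sum(draw <= 22L))
  })
  expect_lte(mean(ps <= 1e-4), 1e-3)
})

test_that("triggers are linked through degradome cleavage positions", {
  cfg <- sim_config(seed = 27)
  g <- gen_genome(cfg)
  w <- g$phas_truth$start[1]
  tags <- gen_phas_locus(cfg, g$genome, w, n_cycles = 11, n_phased = 11)
  loci <- detect_phasirnas(tags)

  # a transcript spanning the locus, cleaved at the window 5' edge
  tx_start <- w - 200L
  targets <- data.frame(miRNA = c("miR482", "miRfar"), target = c("tx1", "tx2"),
                        category = c(0L, 0L),
                        cleavage_position = c(201L, 50L),
                        p_value = NA_real_, fragment_abundance = c(30L, 10L),
                        alignment_score = c(1.5, 0.5))
  tx_loci <- data.frame(transcript = c("tx1", "tx2"), chrom = "chr1",
                        start = c(tx_start, w - 5000L), strand = "+")
  linked <- link_triggers(loci, targets, tx_loci)
  expect_equal(linked$trigger_miRNA, "miR482")  # tx2 cleaves 100s of nt away
  expect_equal(linked$trigger_position, w)

  # two in-window triggers: both recorded, sorted by alignment score
  targets2 <- rbind(targets[1, ],
                    within(targets[1, ], {
                      miRNA <- "miR393"; alignment_score <- 0.5
                    }))
  linked2 <- link_triggers(loci, targets2, tx_loci)
  expect_equal(nrow(linked2), 2)
  expect_equal(linked2$trigger_miRNA, c("miR393", "miR482"))
})
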