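test_that("generated hairpin loci satisfy the structural criteria by construction", {
  cfg <- sim_config(seed = 1)
  loc <- gen_mirna_locus(cfg, arm = "5p")
  ev <- evaluate_hairpin(loc$precursor, loc$mature_interval)
  expect_true(ev$ok)
  expect_lte(ev$hairpin$mfe, -18)
  expect_equal(ev$star_interval, loc$star_interval)
  # the planted star substring matches the geometry-implied star
  expect_equal(substr(loc$precursor, ev$star_interval[1], ev$star_interval[2]),
               loc$star)
})

test_that("the mature maps to the requested arm", {
  cfg <- sim_config(seed = 5)
  for (arm in c("5p", "3p")) {
    loc <- gen_mirna_locus(cfg, arm = arm)
    hp <- fold_hairpin(loc$precursor)
    mid <- mean(loc$mature_interval)
    if (arm == "5p") expect_lt(mid, hp$loop[1]) else expect_gt(mid, hp$loop[2])
    expect_identical(substr(loc$precursor, loc$mature_interval[1],
                            loc$mature_interval[2]), loc$mature)
  }
})

test_that("generators are deterministic in the seed", {
  cfg <- sim_config(seed = 42)
  expect_identical(gen_mirna_locus(cfg, "5p"), gen_mirna_locus(cfg, "5p"))
  g1 <- gen_genome(cfg); g2 <- gen_genome(cfg)
  expect_identical(g1, g2)
  t1 <- gen_srna_libraries(cfg, g1$mirna_truth)
  t2 <- gen_srna_libraries(cfg, g2$mirna_truth)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  p1 <- gen_phas_locus(cfg, g1$genome, g1$phas_truth$start[1])
  p2 <- gen_phas_locus(cfg, g2$genome, g2$phas_truth$start[1])
  expect_identical(p1, p2)
})

test_that("loci with planted bulges still pass hairpin evaluation", {
  cfg <- sim_config(seed = 9, planted_bulges = 1L)
  loc <- gen_mirna_locus(cfg, arm = "5p")
  ev <- evaluate_hairpin(loc$precursor, loc$mature_interval)
  expect_true(ev$criteria[["hairpin"]])
  expect_true(ev$criteria[["star"]])
})

test_that("injected fold changes are recovered empirically at high depth", {
  # locus with mean lambda=400, factor 8 on MT: the empirical MT/WT ratio of
  # Poisson sums over many replicate draws lands within 10% of 8
  lam <- 400
  set.seed(31)
  mt <- rpois(10000, 8 * lam)
  wt <- rpois(10000, lam)
  expect_lt(abs(mean(mt) / mean(wt) - 8) / 8, 0.1)
  # and the generator wires the factor through to the MT group only
  sim <- gen_de_experiment(n_mirnas = 50, seed = 2, n_inject = 5, fold = 8)
  inj <- sim$injected
  mt_avg <- rowMeans(sim$counts[, sim$groups$MT])
  wt_avg <- rowMeans(sim$counts[, sim$groups$WT])
  expect_gt(min((mt_avg / pmax(wt_avg, 1))[inj]), 3)
})

test_that("null construction: no injections means equal group means", {
  sim <- gen_de_experiment(n_mirnas = 100, seed = 3, n_inject = 0)
  expect_false(any(sim$injected))
  mt <- mean(sim$counts[, sim$groups$MT])
  wt <- mean(sim$counts[, sim$groups$WT])
  expect_lt(abs(mt - wt) / wt, 0.15)
})

test_that("zero noise rate leaves only truth-locus tags in the table", {
  cfg <- sim_config(seed = 4, noise_tag_rate = 0)
  g <- gen_genome(cfg)
  tt <- gen_srna_libraries(cfg, g$mirna_truth)
  expect_true(all(tt$sequence %in% c(g$mirna_truth$mature, g$mirna_truth$star)))
})

test_that("degradome generator realizes every requested category", {
  for (cat in 0:4) {
    prof <- gen_degradome_profile("tx", 500L, 250L, signal = 50L,
                                  background = 10L, category = cat, seed = 7)
    expect_equal(classify_category(prof, 250L), cat)
  }
  expect_error(gen_degradome_profile("tx", 100L, 200L, category = 0),
               "outside")
  expect_error(gen_degradome_profile("tx", 100L, 50L, signal = 1, category = 0),
               "signal")
})

test_that("phased-locus generator puts tags on the register", {
  cfg <- sim_config(seed = 6)
  g <- gen_genome(cfg)
  w <- g$phas_truth$start[1]
  tags <- gen_phas_locus(cfg, g$genome, w, n_cycles = 11, n_phased = 11,
                         n_offphase = 5)
  expect_true(all(nchar(tags$sequence) == 21))
  eff <- ifelse(tags$strand == "+", tags$start, tags$start + 2L)
  expect_true(all((eff[tags$phased] - w) %% 21 == 0))
  expect_true(all((eff[!tags$phased] - w) %% 21 != 0))
  expect_error(gen_phas_locus(cfg, g$genome, w, n_cycles = 5, n_phased = 11),
               "n_phased")
})
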