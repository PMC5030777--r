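test_that("family alignment honors the 2-mismatch / 3-gap budget", {
  mature <- "TGACAGAAGAGAGTGAGCACA"
  db <- data.frame(id = "mir1", family = "fam1",
                   sequence = paste0("GGAG", mature, "CTTG"))  # precursor-style
  hit <- align_to_mirbase(mature, db)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$gaps, 0)

  # interior substitutions (gaps cannot absorb them more cheaply)
  flip_at <- function(s, at) {
    for (p in at) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }
  two_mm <- flip_at(mature, c(6, 12))
  expect_equal(nrow(align_to_mirbase(two_mm, db)), 1)

  three_mm <- flip_at(mature, c(6, 12, 17))
  expect_equal(nrow(align_to_mirbase(three_mm, db)), 0)
})

test_that("family representatives are the highest-count tag, ties lexicographic", {
  tt <- make_tags(c("AACCGGTTAACCGGTTAACCG", "CCAACCGGTTAACCGGTTAAC",
                    "GGTTAACCGGTTAACCGGTTA"),
                  data.frame(lib1 = c(10L, 3L, 10L)))
  asg <- data.frame(sequence = tt$sequence,
                    family = c("famA", "famA", "famB"))
  rep <- build_family_representatives(asg, tt)
  expect_equal(rep$sequence[rep$family == "famA"], "AACCGGTTAACCGGTTAACCG")
  # tie at 10 within one family: lexicographically smaller wins
  asg2 <- data.frame(sequence = tt$sequence[c(1, 3)], family = "famC")
  rep2 <- build_family_representatives(asg2, tt)
  expect_equal(rep2$sequence, "AACCGGTTAACCGGTTAACCG")
  # single-tag family
  asg3 <- data.frame(sequence = tt$sequence[2], family = "famD")
  expect_equal(build_family_representatives(asg3, tt)$sequence, tt$sequence[2])
})

test_that("known-miRNA quantification sums within 2 ungapped mismatches, no double counting", {
  rep_seq <- "TGACAGAAGAGAGTGAGCACA"
  var1 <- paste0("A", substr(rep_seq, 2, 21))                 # 1 mismatch
  var3 <- paste0("CCC", substr(rep_seq, 4, 21))               # 3 mismatches
  tt <- make_tags(c(rep_seq, var1, var3),
                  data.frame(lib1 = c(7L, 3L, 99L)))
  db <- data.frame(family = "famX", sequence = rep_seq, total_count = 10L)
  q <- quantify_known(tt, db)
  expect_equal(unname(q["famX", "lib1"]), 10L)  # 7 + 3, 3-mm variant excluded

  # a tag equidistant from two representatives is counted once, toward the
  # higher-expressed representative
  repA <- strrep("ACGT", 5)
  repB <- paste0("TT", substr(repA, 3, 20))
  mid <- paste0("AT", substr(repA, 3, 20))  # 2 mm from repB? construct 2/2 case
  db2 <- data.frame(family = c("fA", "fB"),
                    sequence = c(repA, repB), total_count = c(50L, 10L))
  tt2 <- make_tags(mid, data.frame(lib1 = 5L))
  q2 <- quantify_known(tt2, db2)
  expect_equal(sum(q2), 5L)  # counted exactly once (mass conservation)

  # length mismatch never matches (ungapped contract)
  tt3 <- make_tags(substr(rep_seq, 1, 20), data.frame(lib1 = 4L))
  expect_equal(sum(quantify_known(tt3, db)), 0L)
})

test_that("folding is deterministic and detects hairpins vs unstructured input", {
  hp <- make_stem_hairpin(30)
  s1 <- fold_hairpin(hp)
  s2 <- fold_hairpin(hp)
  expect_identical(s1$structure, s2$structure)
  expect_true(s1$is_hairpin)
  expect_lt(s1$mfe, 0)
  expect_equal(nchar(s1$structure), nchar(hp))

  flat <- fold_hairpin(strrep("A", 100))
  expect_false(flat$is_hairpin)
  expect_error(fold_hairpin("ACGTX"), "non-IUPAC|length")
  expect_error(fold_hairpin("ACGU"), "length")
})

test_that("star intervals follow 2-nt 3' overhang geometry; blunt and loop-spanning fail", {
  cfg <- sim_config(seed = 13)
  loc <- gen_mirna_locus(cfg, arm = "5p")
  hp <- fold_hairpin(loc$precursor)
  res <- check_star_overhang(hp, loc$mature_interval)
  expect_true(res$ok)
  expect_equal(res$star_interval, loc$star_interval)

  # supplying a blunt-ended candidate star (no overhang) must fail
  pt <- hp$pair_table
  a <- loc$mature_interval[1]; b <- loc$mature_interval[2]
  blunt <- sort(c(pt[b], pt[a]))
  res_blunt <- check_star_overhang(hp, loc$mature_interval, star_interval = blunt)
  expect_false(res_blunt$ok)
  expect_match(res_blunt$reason, "overhang")

  # mature overlapping the terminal loop fails (a failure, not an error)
  loop_mature <- c(hp$loop[1] - 10L, hp$loop[1] + 3L)
  res_loop <- check_star_overhang(hp, loop_mature)
  expect_false(res_loop$ok)
  expect_match(res_loop$reason, "loop")
})

test_that("MFE decreases as complementary stem length grows", {
  mfes <- vapply(c(25, 35, 45, 55), function(k) fold_hairpin(make_stem_hairpin(k))$mfe,
                 numeric(1))
  expect_true(all(diff(mfes) < 0))
})

test_that("novel prediction accepts a compliant planted locus", {
  fx <- make_novel_fixture(seed = 11, mature_counts = c(3L, 2L, 0L, 0L))
  nov <- predict_novel(fx$tags, fx$genome)
  expect_equal(nrow(nov), 1)
  expect_equal(nov$mature, fx$locus$mature)
  expect_equal(nov$star, fx$locus$star)
  expect_true(nov$star_observed)
  expect_equal(nov$mature_count, 5L)
  expect_lte(nov$mfe, -18)
})

test_that("replicate merging keeps only miRNAs seen in both replicates", {
  groups <- list(MT = c("MT_bio1", "MT_bio2"), WT = c("WT_bio1", "WT_bio2"))
  rec <- data.frame(miRNA = c("a", "b", "c"),
                    MT_bio1 = c(TRUE, TRUE, TRUE),
                    MT_bio2 = c(FALSE, TRUE, TRUE),
                    WT_bio1 = c(TRUE, FALSE, TRUE),
                    WT_bio2 = c(TRUE, FALSE, TRUE))
  out <- merge_replicates(rec, groups)
  expect_equal(out$MT, c(FALSE, TRUE, TRUE))   # a seen in MT_bio1 only: dropped
  expect_equal(out$WT, c(TRUE, FALSE, TRUE))
  expect_equal(out$both_genotypes, c(FALSE, FALSE, TRUE))
})
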