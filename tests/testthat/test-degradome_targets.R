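test_that("degradome pre-processing removes Rfam > GenBank > polyN with strict 70%", {
  polyn_75 <- paste0(strrep("A", 15), "CGTGC")          # 15/20 = 75% -> removed
  polyn_70 <- paste0(strrep("A", 14), "CGTGCC")         # 14/20 = 70% -> kept
  rrna_tag <- "ACGTGACGTGACGTGACGTG"
  gb_tag <- "TTGCATTGCATTGCATTGCA"
  both <- strrep("A", 16)                                # polyN AND rRNA match
  tt <- make_tags(c(polyn_75, polyn_70, rrna_tag, gb_tag, both),
                  data.frame(lib1 = rep(1L, 5)))
  db <- data.frame(id = c("r", "g"),
                   sequence = c(paste0(rrna_tag, strrep("A", 20)), gb_tag),
                   source = c("Rfam", "GenBank"))
  out <- preprocess_degradome(tt, db)
  expect_setequal(out$tags$sequence, polyn_70)
  led <- stats::setNames(out$ledger$removed_as, out$ledger$sequence)
  expect_equal(unname(led[polyn_75]), "polyN")
  expect_equal(unname(led[rrna_tag]), "Rfam")
  expect_equal(unname(led[gb_tag]), "GenBank")
  expect_equal(unname(led[both]), "Rfam")  # structural priority over polyN
})

test_that("alignment scoring: perfect complement, wobble, and core doubling", {
  mir <- "TGACAGAAGAGAGTGAGCACA"
  perfect <- rc(mir)
  expect_equal(score_alignment(mir, perfect)$score, 0)

  # single G:U at miRNA position 17 (outside the doubled 2-13 core): 0.5
  # miRNA pos 17 is A? ensure a G:U by placing miRNA G against target T
  mir_g17 <- paste0(substr(mir, 1, 16), "G", substr(mir, 18, 21))
  win <- rc(mir_g17)
  # target base pairing position 17 is win[21 - 17 + 1 = 5]; make it T
  substr(win, 5, 5) <- "T"
  expect_equal(score_alignment(mir_g17, win)$score, 0.5)

  # single mismatch at miRNA position 5 (inside the core): 2.0
  win5 <- rc(mir)
  pos <- 21 - 5 + 1
  old <- substr(win5, pos, pos)
  # replace with a base that is neither complement nor wobble partner
  newb <- setdiff(c("A", "C", "G", "T"),
                  c(old, switch(substr(mir, 5, 5), A = "T", T = c("A", "G"),
                                G = c("C", "T"), C = "G")))[1]
  substr(win5, pos, pos) <- newb
  expect_equal(score_alignment(mir, win5)$score, 2.0)
})

test_that("the doubling region matches a brute-force position-wise scorer", {
  mir <- "TGACAGAAGAGAGTGAGCACA"
  for (i in 1:21) {
    win <- rc(mir)
    pos <- 21 - i + 1
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(win, pos, pos)) next
      w2 <- win
      substr(w2, pos, pos) <- b
      expect_equal(score_alignment(mir, w2)$score,
                   brute_ungapped_score(mir, w2),
                   label = sprintf("pos %d base %s", i, b))
    }
  }
})

test_that("adding a mismatch never decreases the score", {
  comp <- function(b) c(A = "T", T = "A", G = "C", C = "G")[b]
  set.seed(5)
  for (rep in 1:10) {
    mir <- srnapipe:::random_dna(21)
    win <- rc(mir)
    prev <- score_alignment(mir, win)$score
    mir_v <- strsplit(mir, "")[[1]]
    # degrade distinct Watson-Crick pairs into true mismatches (not wobbles)
    for (pos in sample(21, 4)) {
      wpos <- 21 - pos + 1
      wob <- if (mir_v[pos] == "G") "T" else if (mir_v[pos] == "T") "G" else "ZZ"
      b <- setdiff(c("A", "C", "G", "T"),
                   c(substr(win, wpos, wpos), comp(mir_v[pos]), wob))[1]
      substr(win, wpos, wpos) <- b
      cur <- score_alignment(mir, win)$score
      expect_gte(cur, prev - 1e-9)
      prev <- cur
    }
  }
})

test_that("cleavage position pairs miRNA position 10 and is shift-equivariant", {
  mir <- "TGACAGAAGAGAGTGAGCACA"
  tx <- paste0(srnapipe:::with_seed(3, srnapipe:::random_dna(924)), rc(mir),
               srnapipe:::with_seed(4, srnapipe:::random_dna(100)))
  win_start <- 925L
  aln <- score_alignment(mir, substr(tx, win_start, win_start + 20))
  site <- predict_cleavage(aln, win_start, 21L, nchar(tx))
  expect_equal(site, win_start + 21L - 10L)  # position pairing miRNA nt 10
  site2 <- predict_cleavage(aln, win_start + 1L, 21L, nchar(tx))
  expect_equal(site2, site + 1L)
  expect_error(predict_cleavage(aln, nchar(tx) - 5L, 21L, nchar(tx)),
               "outside")
})

test_that("category classification matches the spec wording on canonical cases", {
  p <- function(ab) degradome_profile("t", 1000L, ab)
  expect_equal(classify_category(p(c(`100` = 10L, `200` = 3L, `300` = 2L)), 100), 0L)
  expect_equal(classify_category(p(c(`100` = 10L, `200` = 10L, `300` = 2L)), 100), 1L)
  expect_equal(classify_category(p(c(`100` = 1L)), 100), 4L)
  expect_error(classify_category(p(c(`100` = 5L)), 200), "no raw reads")
})

test_that("category classification agrees with brute force on random profiles", {
  set.seed(41)
  for (i in 1:1000) {
    npos <- sample(1:30, 1)
    pos <- sample(500, npos)
    ab <- stats::setNames(sample(1:50, npos, replace = TRUE), pos)
    prof <- degradome_profile("t", 500L, ab)
    site <- pos[sample(length(pos), 1)]
    expect_identical(classify_category(prof, site), brute_category(ab, site))
  }
})

test_that("target calling honors the 4.5 boundary inclusively", {
  mir <- "TGACAGAAGAGAGTGAGCACA"
  tx_perfect <- paste0(strrep("CA", 30), rc(mir), strrep("GT", 30))
  site <- 60L + 21L - 9L
  prof <- gen_degradome_profile("tx", nchar(tx_perfect), site, signal = 40,
                                background = 8, category = 0, seed = 2)
  tt <- call_targets(data.frame(name = "miR", sequence = mir),
                     c(tx = tx_perfect), list(tx = prof))
  expect_equal(nrow(tt), 1)
  expect_equal(tt$category, 0L)
  expect_equal(tt$cleavage_position, site)
  expect_equal(tt$alignment_score, 0)
  expect_equal(tt$fragment_abundance, 40L)
  expect_true(is.na(tt$p_value))

  # degrade the site sequence to push the score to exactly 4.5 and beyond:
  # 2 core mismatches (4.0) + one non-core G:U (0.5)
  win <- rc(mir)
  flip <- function(w, mir_pos, to) {
    pos <- 21 - mir_pos + 1
    substr(w, pos, pos) <- to
    w
  }
  mk_tx <- function(w) paste0(strrep("CA", 30), w, strrep("GT", 30))
  w45 <- win
  for (mp in c(3, 6)) {  # core mismatches: 2 x 2.0
    pos <- 21 - mp + 1
    mb <- substr(mir, mp, mp)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(substr(w45, pos, pos),
                     switch(mb, A = "T", T = c("A", "G"),
                            G = c("C", "T"), C = "G")))[1]
    substr(w45, pos, pos) <- bad
  }
  mir_g <- mir  # ensure non-core wobble at pos 18: set miRNA base T, target G
  substr(mir_g, 18, 18) <- "T"
  w45b <- flip(w45, 18, "G")
  sc <- score_alignment(mir_g, w45b)$score
  expect_equal(sc, 4.5)
  tt45 <- call_targets(data.frame(name = "miR", sequence = mir_g),
                       c(tx = mk_tx(w45b)), list(tx = prof))
  expect_equal(nrow(tt45), 1)  # boundary inclusive

  # one more non-core wobble: 5.0 > 4.5 -> rejected... use a mismatch: 4.5+1
  mir_g2 <- mir_g
  substr(mir_g2, 20, 20) <- "C"
  w46 <- flip(w45b, 20, "A")  # C:A mismatch outside core: 4.5 + 1.0
  expect_gt(score_alignment(mir_g2, w46)$score, 4.5)
  tt46 <- call_targets(data.frame(name = "miR", sequence = mir_g2),
                       c(tx = mk_tx(w46)), list(tx = prof))
  expect_equal(nrow(tt46), 0)
})
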