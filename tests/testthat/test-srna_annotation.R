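test_that("length filter keeps the 18-28 nt boundary inclusive", {
  seqs <- c(strrep("A", 17), strrep("C", 18), strrep("G", 28), strrep("T", 29))
  tt <- make_tags(seqs, data.frame(lib1 = c(1L, 2L, 3L, 4L)))
  out <- length_filter(tt)
  expect_equal(nchar(out$sequence), c(18, 28))
  expect_equal(unname(attr(out, "removed")), c(2, 5))
  expect_equal(nrow(length_filter(out)), 2)  # idempotent on all-21nt style input
  expect_error(length_filter(tt, min = 24, max = 20), "min > max")
  empty <- tt[0, , drop = FALSE]
  expect_equal(nrow(length_filter(empty)), 0)
})

test_that("genome matching finds exact hits on both strands", {
  genome <- c(chr1 = paste0(strrep("A", 99), "ACGTACGTACGTACGTACGTA",
                            strrep("C", 80)))
  fwd <- substr(genome[[1]], 100, 120)
  rev <- rc(substr(genome[[1]], 50, 70))
  absent <- strrep("GT", 11)
  tt <- make_tags(c(fwd, rev, absent), data.frame(lib1 = c(1L, 1L, 1L)))
  hits <- match_genome(tt, genome)
  h_f <- hits[hits$sequence == fwd & hits$strand == "+", ]
  expect_true(100 %in% h_f$start)
  h_r <- hits[hits$sequence == rev, ]
  expect_true(any(h_r$strand == "-" & h_r$start == 50))
  expect_false(absent %in% hits$sequence)
})

test_that("the priority rule decides every multi-class tag", {
  genome <- c(chr1 = srnapipe:::with_seed(21, srnapipe:::random_dna(400)))
  tag_rrna_exon <- substr(genome[[1]], 101, 121)  # in an rRNA db AND an exon
  tag_mirna_rep <- substr(genome[[1]], 201, 221)  # known miRNA AND repeat
  tag_unann <- strrep("AG", 11)                   # matches nothing
  tt <- make_tags(c(tag_rrna_exon, tag_mirna_rep, tag_unann),
                  data.frame(lib1 = c(2L, 3L, 4L)))
  tracks <- list(
    annotation_track(data.frame(chrom = "chr1", start = 90, end = 130),
                     class = "exon"),
    annotation_track(data.frame(chrom = "chr1", start = 195, end = 230),
                     class = "repeat"))
  struct <- data.frame(id = "rrna1", sequence = paste0("GG", tag_rrna_exon, "CC"),
                       source = "GenBank")
  known <- data.frame(id = "mir1", sequence = tag_mirna_rep)
  ann <- annotate(tt, genome, tracks = tracks, known_mirna_db = known,
                  structural_db = struct)$annotated
  got <- stats::setNames(as.character(ann$category), ann$sequence)
  expect_equal(unname(got[tag_rrna_exon]), "rRNAetc")
  expect_equal(unname(got[tag_mirna_rep]), "miRNA")
  expect_equal(unname(got[tag_unann]), "unann")
  # database matches do not require genome hits
  off_genome <- strrep("TG", 11)
  tt2 <- make_tags(off_genome, data.frame(lib1 = 1L))
  struct2 <- data.frame(id = "r", sequence = off_genome, source = "Rfam")
  ann2 <- annotate(tt2, genome, structural_db = struct2)$annotated
  expect_equal(as.character(ann2$category), "rRNAetc")
  expect_equal(ann2$n_genome_hits, 0L)
})

test_that("unknown track classes are rejected", {
  tt <- make_tags(strrep("A", 21), data.frame(lib1 = 1L))
  bad <- annotation_track(data.frame(chrom = "chr1", start = 1, end = 10),
                          class = "exon")
  S4Vectors::mcols(bad)$class <- "enhancer"
  expect_error(annotate(tt, c(chr1 = strrep("A", 50)), tracks = list(bad)),
               "unknown class")
})

test_that("category totals partition the clean reads (Table-1 structure)", {
  st <- simulate_study(sim_config(seed = 8, n_mirna_loci = 3, n_phas_loci = 1,
                                  genome_length = 20000))
  known <- data.frame(id = "k", sequence = st$mirna_truth$mature[1])
  a <- annotate(st$tags, st$genome, known_mirna_db = known)
  s <- a$summary
  for (lib in tag_libraries(st$tags)) {
    sl <- s[s$library == lib, ]
    cats <- sl[sl$category %in% srnapipe:::ANNOTATION_CLASSES, ]
    expect_equal(sum(cats$total_reads), sl$total_reads[sl$category == "clean"])
    expect_equal(sum(cats$unique_reads), sl$unique_reads[sl$category == "clean"])
  }
  # priority idempotence: re-annotating yields identical categories
  a2 <- annotate(st$tags, st$genome, known_mirna_db = known)
  expect_identical(a$annotated$category, a2$annotated$category)
})

test_that("annotate agrees with a brute-force per-tag checker", {
  set.seed(77)
  genome <- c(chr1 = srnapipe:::random_dna(600), chr2 = srnapipe:::random_dna(400))
  n <- 40
  seqs <- unique(vapply(seq_len(n), function(i) {
    if (runif(1) < 0.7) {
      chrom <- sample(names(genome), 1)
      w <- sample(18:24, 1)
      s <- sample(nchar(genome[[chrom]]) - w, 1)
      tag <- substr(genome[[chrom]], s, s + w - 1)
      if (runif(1) < 0.3) tag <- rc(tag)
      tag
    } else srnapipe:::random_dna(sample(18:24, 1))
  }, character(1)))
  tt <- make_tags(seqs, data.frame(lib1 = rep(1L, length(seqs))))
  tracks <- list(
    annotation_track(data.frame(chrom = "chr1", start = c(40, 300),
                                end = c(140, 380)), class = "exon"),
    annotation_track(data.frame(chrom = "chr1", start = 150, end = 250),
                     class = "repeat"),
    annotation_track(data.frame(chrom = "chr2", start = 50, end = 200),
                     class = "intron"))
  struct <- data.frame(id = c("g", "r"),
                       sequence = c(substr(genome[[1]], 60, 110),
                                    substr(genome[[2]], 80, 130)),
                       source = c("GenBank", "Rfam"))
  known <- data.frame(id = "m", sequence = substr(genome[[1]], 320, 345))
  ann <- annotate(tt, genome, tracks = tracks, known_mirna_db = known,
                  structural_db = struct)$annotated

  # brute force: naive substring genome search + per-class membership tests,
  # then the priority order
  naive_hits <- function(tag) {
    out <- NULL
    for (chrom in names(genome)) {
      for (strand in c("+", "-")) {
        subj <- genome[[chrom]]
        query <- if (strand == "+") tag else rc(tag)
        p <- gregexpr(query, subj, fixed = TRUE)[[1]]
        if (p[1] != -1)
          out <- rbind(out, data.frame(chrom = chrom, start = as.integer(p),
                                       end = as.integer(p) + nchar(tag) - 1))
      }
    }
    out
  }
  overlaps <- function(hits, cls) {
    if (is.null(hits)) return(FALSE)
    for (tr in tracks) {
      if (S4Vectors::mcols(tr)$class[1] != cls) next
      for (k in seq_along(tr)) {
        same <- hits$chrom == as.character(GenomicRanges::seqnames(tr)[k])
        if (any(same & hits$start <= GenomicRanges::end(tr)[k] &
                  hits$end >= GenomicRanges::start(tr)[k])) return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_along(seqs)) {
    tag <- seqs[i]
    hits <- naive_hits(tag)
    expected <-
      if (any(grepl(tag, struct$sequence, fixed = TRUE))) "rRNAetc"
      else if (any(grepl(tag, known$sequence, fixed = TRUE))) "miRNA"
      else if (overlaps(hits, "repeat")) "repeat"
      else if (overlaps(hits, "exon")) "exon"
      else if (overlaps(hits, "intron")) "intron"
      else "unann"
    expect_equal(as.character(ann$category[ann$sequence == tag]), expected,
                 label = paste("tag", tag))
  }
})

test_that("length distributions conserve mass and honor the category filter", {
  seqs <- c(strrep("A", 21), strrep("C", 21), strrep("G", 21), strrep("T", 24))
  tt <- make_tags(seqs, data.frame(lib1 = c(2L, 3L, 5L, 7L)))
  ld <- length_distribution(tt)
  expect_equal(ld$unique_reads[ld$length == 21], 3L)
  expect_equal(ld$total_reads[ld$length == 21], 10L)
  expect_equal(sum(ld$total_reads), 17L)
  ann <- as.data.frame(tt)
  ann$category <- factor(c("miRNA", "unann", "miRNA", "unann"),
                         levels = srnapipe:::ANNOTATION_CLASSES)
  attr(ann, "libraries") <- "lib1"
  ld_mir <- length_distribution(ann, by = "miRNA")
  expect_equal(ld_mir$total_reads[ld_mir$length == 21], 7L)
  expect_equal(nrow(length_distribution(tt[0, ], by = "all")), 0)
})
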