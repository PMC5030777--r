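# Shared fixtures: all built in code at test time.

rc <- srnapipe:::revcomp

# A tag table with explicit per-library counts.
make_tags <- function(seqs, counts) {
  counts <- as.data.frame(counts)
  tag_table(seqs, counts)
}

# Perfect inverted-repeat hairpin: stem of `stem_len` bp around an 8-nt loop,
# from a fixed alternating pattern so MFE grows with stem length.
make_stem_hairpin <- function(stem_len, unit = "GCAT") {
  stem <- paste(rep(strsplit(unit, "")[[1]], length.out = stem_len),
                collapse = "")
  paste0(stem, "GAAACAAA", rc(stem))
}

# One planted miRNA locus embedded mid-genome, with a tag table whose mature
# counts are controlled. Returns everything predict_novel needs.
make_novel_fixture <- function(seed = 11, mature_counts = c(3L, 2L, 0L, 0L),
                               star_seq = NULL, genome_len = 3000L) {
  cfg <- sim_config(seed = seed)
  loc <- gen_mirna_locus(cfg, arm = "5p", seed = seed)
  genome <- srnapipe:::with_seed(seed + 1, srnapipe:::random_dna(genome_len))
  at <- 1200L
  genome <- paste0(substr(genome, 1, at - 1), loc$precursor,
                   substr(genome, at + nchar(loc$precursor), genome_len))
  if (is.null(star_seq)) star_seq <- loc$star
  seqs <- c(loc$mature, star_seq)
  cnt <- rbind(mature_counts, c(1L, 1L, 0L, 0L))
  tags <- make_tags(seqs, stats::setNames(as.data.frame(cnt),
                                          c("MT_bio1", "MT_bio2",
                                            "WT_bio1", "WT_bio2")))
  list(genome = c(chr1 = genome), locus = loc, tags = tags, at = at)
}

# Independent brute-force cleavage-site category classifier following the
# category wording directly (sorted-vector median, explicit max scan).
brute_category <- function(abundance, site) {
  a <- abundance[[as.character(site)]]
  if (a == 1) return(4L)
  v <- as.numeric(abundance)
  mx <- v[1]; for (x in v) if (x > mx) mx <- x
  if (a == mx) {
    ties <- 0L; for (x in v) if (x == mx) ties <- ties + 1L
    return(if (ties == 1L) 0L else 1L)
  }
  s <- sort(v)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  if (a > med) 2L else 3L
}

# Independent hypergeometric tail by direct enumeration of combinations.
brute_hyper_tail <- function(n, k, cycles = 11L, phase = 21L) {
  pop <- 2L * phase * cycles
  succ <- 2L * cycles
  xs <- k:min(n, succ)
  sum(vapply(xs, function(x) {
    choose(succ, x) * choose(pop - succ, n - x)
  }, numeric(1))) / choose(pop, n)
}

# Independent ungapped position-wise alignment scorer (no DP).
brute_ungapped_score <- function(mirna, window, core = 2:13) {
  m <- strsplit(srnapipe:::dna_norm(mirna), "")[[1]]
  w <- rev(strsplit(srnapipe:::dna_norm(window), "")[[1]])
  stopifnot(length(m) == length(w))
  total <- 0
  for (i in seq_along(m)) {
    pen <- if ((m[i] == "A" && w[i] == "T") || (m[i] == "T" && w[i] == "A") ||
               (m[i] == "G" && w[i] == "C") || (m[i] == "C" && w[i] == "G")) 0
           else if ((m[i] == "G" && w[i] == "T") ||
                    (m[i] == "T" && w[i] == "G")) 0.5
           else 1
    total <- total + pen * (if (i %in% core) 2 else 1)
  }
  total
}
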