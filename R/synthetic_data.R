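# Synthetic study generator: toy genomes, miRNA hairpin loci, multi-library
# sRNA tag tables, degradome profiles and 21-nt phased loci with the
# statistical structure every downstream stage assumes. Every generator is a
# pure function of (config, seed): the same config yields byte-identical
# output.

#' Simulation configuration
#'
#' Defaults describe the emulated study design: two genotypes (MT, WT) with
#' two replicate libraries each, heavy-tailed (log-normal) locus abundances
#' with Poisson replicate noise, 21-nt mature miRNAs, 21-nt phasing, and a
#' fraction of random background tags.
#'
#' @param seed integer master seed.
#' @param n_libraries number of sRNA libraries (4: MT_bio1/2, WT_bio1/2).
#' @param genome_length toy genome length in nt.
#' @param n_mirna_loci number of planted miRNA hairpin loci.
#' @param n_phas_loci number of planted PHAS loci.
#' @param mature_length mature miRNA length (18-24 nt).
#' @param phase_length phasing register length (fixed at 21 nt).
#' @param read_length_range length range of background tags.
#' @param expr_meanlog,expr_sdlog log-normal parameters for per-locus mean
#'   counts (many low, few high).
#' @param noise_tag_rate fraction of rows in the tag table that are random
#'   background tags.
#' @param noise_meanlog,noise_sdlog log-normal parameters for background tag
#'   counts; the defaults make background reads dominate the library, as in
#'   real sRNA libraries where annotated miRNAs are a few percent of clean
#'   reads, so RPM totals are not hostage to any single locus.
#' @param star_fraction expected star:mature abundance ratio.
#' @param fold_changes named numeric vector of multiplicative factors applied
#'   to the MT group mean of the named loci (locus ids `mir_01`, ...).
#' @param planted_bulges number of 1-nt bulges planted in hairpin arms (0-2).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_libraries = 4,
                       genome_length = 50000L,
                       n_mirna_loci = 8L,
                       n_phas_loci = 3L,
                       mature_length = 21L,
                       phase_length = 21L,
                       read_length_range = c(18L, 28L),
                       expr_meanlog = log(50),
                       expr_sdlog = 1.5,
                       noise_tag_rate = 0.6,
                       noise_meanlog = log(250),
                       noise_sdlog = 1,
                       star_fraction = 0.15,
                       fold_changes = numeric(),
                       planted_bulges = 0L) {
  stopifnot(mature_length >= 18, mature_length <= 24,
            phase_length == 21, planted_bulges <= 2,
            all(fold_changes > 0))
  cfg <- list(seed = as.integer(seed), n_libraries = as.integer(n_libraries),
              genome_length = as.integer(genome_length),
              n_mirna_loci = as.integer(n_mirna_loci),
              n_phas_loci = as.integer(n_phas_loci),
              mature_length = as.integer(mature_length),
              phase_length = as.integer(phase_length),
              read_length_range = as.integer(read_length_range),
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              noise_tag_rate = noise_tag_rate,
              noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog,
              star_fraction = star_fraction,
              fold_changes = fold_changes,
              planted_bulges = as.integer(planted_bulges))
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Library names and group layout implied by a config (2 genotypes, equal split).
sim_groups <- function(config) {
  n <- config$n_libraries
  half <- n %/% 2
  mt <- paste0("MT_bio", seq_len(half))
  wt <- paste0("WT_bio", seq_len(n - half))
  list(MT = mt, WT = wt)
}

#' Generate one miRNA hairpin locus
#'
#' Builds a precursor whose two arms are reverse-complementary apart from at
#' most two planted 1-nt bulges, with the mature on the requested arm and a
#' star positioned so both duplex ends carry exactly 2-nt 3' overhangs. The
#' construction is a perfect inverted repeat (flank + mature-bearing stem +
#' loop + reverse complement), so minimum-free-energy folding recovers the
#' intended hairpin.
#'
#' @param config a [sim_config()].
#' @param arm `"5p"` or `"3p"`: which arm carries the mature.
#' @param mature_seq optional mature sequence to plant (length must equal
#'   `config$mature_length`).
#' @param seed optional seed override (defaults to `config$seed`).
#' @return list with `precursor`, `mature`, `star`, `arm`,
#'   `mature_interval`, `star_interval` (1-based precursor coordinates).
#' @export
gen_mirna_locus <- function(config, arm = c("5p", "3p"), mature_seq = NULL,
                            seed = config$seed) {
  arm <- match.arg(arm)
  L <- config$mature_length
  with_seed(seed, {
    if (is.null(mature_seq)) {
      mature_seq <- random_dna(L)
    } else {
      mature_seq <- dna_norm(mature_seq)
      if (nchar(mature_seq) != L)
        stopf("gen_mirna_locus: mature_seq length %d != configured %d",
              nchar(mature_seq), L)
    }
    f <- 4L   # basal flank below the duplex; must be >= 2 for the overhang
    u <- 10L  # upper stem between duplex and loop
    if (f < 2)
      stopf("gen_mirna_locus: cannot satisfy a 2-nt overhang with flank < 2")
    loop <- paste0("GAA", random_dna(5))
    stem5 <- if (arm == "5p") {
      paste0(random_dna(f), mature_seq, random_dna(u))
    } else {
      # mature goes on the 3' arm: plant its reverse complement in the 5' arm
      paste0(random_dna(f), revcomp(mature_seq), random_dna(u))
    }
    stem3 <- revcomp(stem5)
    # optional 1-nt bulges, planted in the upper-stem portion of the 3' copy
    # so the mature/star duplex pairing is untouched
    bulge_shift <- 0L
    if (config$planted_bulges > 0) {
      for (b in seq_len(config$planted_bulges)) {
        at <- sample(seq_len(u - 2L), 1)  # within revcomp(upper stem)
        stem3 <- paste0(substr(stem3, 1, at), random_dna(1),
                        substr(stem3, at + 1, nchar(stem3)))
        bulge_shift <- bulge_shift + 1L
      }
    }
    precursor <- paste0(stem5, loop, stem3)
    T_perfect <- 2L * nchar(stem5) + nchar(loop)  # length before bulges
    if (arm == "5p") {
      mi <- c(f + 1L, f + L)
      # star on the 3' arm: shifted by planted bulges upstream of it
      si <- (T_perfect + 3L) - rev(mi) + bulge_shift
    } else {
      # mature on the 3' arm occupies the partner of the planted revcomp,
      # shifted by any bulges planted 5' of it
      mi <- c(T_perfect + 1L - (f + L), T_perfect + 1L - (f + 1L)) + bulge_shift
      si <- c(f + 1L, f + L) + 2L
    }
    mature_out <- substr(precursor, mi[1], mi[2])
    star_out <- substr(precursor, si[1], si[2])
    if (arm == "5p" && !identical(mature_out, mature_seq))
      stopf("gen_mirna_locus: internal coordinate error")
    list(precursor = precursor, mature = mature_out, star = star_out,
         arm = arm, mature_interval = mi, star_interval = si)
  })
}

#' Generate a genome with planted miRNA and PHAS loci
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of chromosomes),
#'   `mirna_truth` and `phas_truth` data.frames carrying genomic coordinates
#'   and sequences sufficient to score every downstream caller.
#' @export
gen_genome <- function(config) {
  with_seed(config$seed, {
    glen <- config$genome_length
    genome <- random_dna(glen)
    # spaced slots for planted features
    n_feat <- config$n_mirna_loci + config$n_phas_loci
    slot <- floor(glen / (n_feat + 1))
    mirna_truth <- NULL
    for (i in seq_len(config$n_mirna_loci)) {
      arm <- if (i %% 2 == 1) "5p" else "3p"
      loc <- gen_mirna_locus(config, arm = arm,
                             seed = config$seed * 1000L + i)
      at <- slot * i
      genome <- paste0(substr(genome, 1, at - 1), loc$precursor,
                       substr(genome, at + nchar(loc$precursor), glen))
      genome <- substr(genome, 1, glen)
      mirna_truth <- rbind(mirna_truth, data.frame(
        locus_id = sprintf("mir_%02d", i), chrom = "chr1",
        start = at, end = at + nchar(loc$precursor) - 1L, strand = "+",
        arm = arm, mature = loc$mature, star = loc$star,
        precursor = loc$precursor,
        mature_start = at + loc$mature_interval[1] - 1L,
        mature_end = at + loc$mature_interval[2] - 1L,
        star_start = at + loc$star_interval[1] - 1L,
        star_end = at + loc$star_interval[2] - 1L,
        stringsAsFactors = FALSE))
    }
    phas_truth <- NULL
    for (j in seq_len(config$n_phas_loci)) {
      at <- slot * (config$n_mirna_loci + j)
      win <- 11L * config$phase_length
      phas_truth <- rbind(phas_truth, data.frame(
        locus_id = sprintf("phas_%02d", j), chrom = "chr1",
        start = at, end = at + win - 1L, strand = "+",
        stringsAsFactors = FALSE))
    }
    list(genome = c(chr1 = genome), mirna_truth = mirna_truth,
         phas_truth = phas_truth)
  })
}

#' Generate multi-library sRNA tag tables from planted loci
#'
#' Per-locus mean counts are drawn log-normally; the MT group mean is
#' multiplied by any injected fold change; replicate counts are Poisson
#' around the group mean. Star tags are added at `star_fraction` of the
#' mature mean, and random background tags at `noise_tag_rate`.
#'
#' @param config a [sim_config()].
#' @param truth `mirna_truth` from [gen_genome()].
#' @return a [tag_table()] with a `groups` attribute and a `locus_means`
#'   attribute (the per-locus WT means used).
#' @export
gen_srna_libraries <- function(config, truth) {
  groups <- sim_groups(config)
  libs <- unlist(groups, use.names = FALSE)
  with_seed(config$seed + 7L, {
    n <- nrow(truth)
    base_mean <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
    fc <- rep(1, n)
    names(fc) <- truth$locus_id
    if (length(config$fold_changes)) {
      hit <- intersect(names(config$fold_changes), truth$locus_id)
      fc[hit] <- config$fold_changes[hit]
    }
    seqs <- character(); cnt <- NULL
    add_row <- function(s, means_by_lib) {
      row <- stats::rpois(length(libs), means_by_lib)
      seqs[length(seqs) + 1] <<- s
      cnt <<- rbind(cnt, row)
    }
    for (i in seq_len(n)) {
      means <- ifelse(libs %in% groups$MT, base_mean[i] * fc[i], base_mean[i])
      add_row(truth$mature[i], means)
      add_row(truth$star[i], pmax(means * config$star_fraction, 0.5))
    }
    # background tags of random sequence and length
    n_truth <- length(seqs)
    n_noise <- round(config$noise_tag_rate / (1 - config$noise_tag_rate) * n_truth)
    rl <- config$read_length_range
    k <- 0
    while (k < n_noise) {
      s <- random_dna(sample(seq(rl[1], rl[2]), 1))
      if (s %in% seqs) next
      add_row(s, rep(stats::rlnorm(1, config$noise_meanlog,
                                   config$noise_sdlog), length(libs)))
      k <- k + 1
    }
    keep <- !duplicated(seqs)
    seqs <- seqs[keep]; cnt <- cnt[keep, , drop = FALSE]
    cnt <- as.data.frame(cnt)
    colnames(cnt) <- libs
    tt <- tag_table(seqs, cnt, libs)
    attr(tt, "groups") <- groups
    attr(tt, "locus_means") <- stats::setNames(base_mean, truth$locus_id)
    tt
  })
}

#' Generate a degradome profile realizing a requested category
#'
#' Places `signal` reads at the true cleavage site and background reads at
#' other positions, parameterized so each of categories 0-4 is realizable:
#' \describe{
#'   \item{0}{site abundance is the unique transcript-wide maximum;}
#'   \item{1}{site ties the maximum with at least one other position;}
#'   \item{2}{site is above the median but below the maximum;}
#'   \item{3}{site is at or below the median;}
#'   \item{4}{the site carries a single raw read.}
#' }
#'
#' @param transcript transcript id.
#' @param length transcript length (nt).
#' @param true_site 1-based cleavage position.
#' @param signal reads at the site (ignored and forced to 1 for category 4).
#' @param background number of background positions.
#' @param category requested category (0-4).
#' @param seed RNG seed.
#' @return a [degradome_profile()].
#' @export
gen_degradome_profile <- function(transcript, length, true_site, signal = 50L,
                                  background = 10L, category = 0L, seed = 1L) {
  if (true_site < 1 || true_site > length)
    stopf("gen_degradome_profile: true_site outside transcript")
  with_seed(seed, {
    other <- setdiff(seq_len(length), true_site)
    pick <- function(k) sample(other, k)
    ab <- integer()
    if (category == 0) {
      if (signal < 2) stopf("category 0 needs signal >= 2")
      pos <- pick(background)
      ab <- stats::setNames(pmax(1L, stats::rpois(background, signal / 8)), pos)
      ab[ab >= signal] <- signal - 1L
      site_ab <- as.integer(signal)
    } else if (category == 1) {
      if (signal < 2) stopf("category 1 needs signal >= 2")
      pos <- pick(background + 1)
      ab <- stats::setNames(pmax(1L, stats::rpois(background, signal / 8)), pos[-1])
      ab[ab >= signal] <- signal - 1L
      ab[as.character(pos[1])] <- as.integer(signal)  # the tied maximum
      site_ab <- as.integer(signal)
    } else if (category == 2) {
      # need median < site < max
      if (signal < 3) stopf("category 2 needs signal >= 3")
      low <- pick(background + 1)
      ab <- stats::setNames(rep(1L, background), low[-1])
      ab[as.character(low[1])] <- as.integer(signal) * 3L  # dominant peak elsewhere
      site_ab <- as.integer(signal)
    } else if (category == 3) {
      if (signal < 2) stopf("category 3 needs signal >= 2")
      hi <- pick(background)
      ab <- stats::setNames(rep(as.integer(signal) * 2L, background), hi)
      site_ab <- as.integer(signal)  # at or below the median
    } else if (category == 4) {
      ab <- integer()
      site_ab <- 1L
    } else stopf("unknown category %s", category)
    ab[as.character(true_site)] <- site_ab
    degradome_profile(transcript, length, ab)
  })
}

#' Generate a 21-nt phased locus and its tag set
#'
#' Sense phased tags start exactly at the 21-nt registers of the window;
#' antisense phased tags start at register - 2 (the duplex overhang offset),
#' so that shifting antisense starts by +2 puts them on the sense register.
#' Off-phase tags start at uniformly random off-register positions.
#'
#' @param config a [sim_config()].
#' @param genome named character vector of chromosomes.
#' @param window_start 1-based genomic start of the phased window.
#' @param n_cycles number of 21-nt cycles in the window.
#' @param n_phased number of phased tags (must be <= 2 * n_cycles).
#' @param n_offphase number of off-register tags.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return data.frame of tags: `sequence`, `chrom`, `start` (1-based
#'   leftmost plus-strand coordinate), `strand`, `phased` flag.
#' @export
gen_phas_locus <- function(config, genome, window_start, n_cycles = 11L,
                           n_phased = 11L, n_offphase = 0L, chrom = "chr1",
                           seed = config$seed) {
  phase <- config$phase_length
  if (n_phased > 2 * n_cycles)
    stopf("gen_phas_locus: n_phased > 2 * n_cycles")
  gseq <- genome[[chrom]]
  win_len <- phase * n_cycles
  if (window_start + win_len + phase > nchar(gseq))
    stopf("gen_phas_locus: window outside genome")
  with_seed(seed, {
    registers <- window_start + phase * (seq_len(n_cycles) - 1L)
    # slots: (register, strand); antisense leftmost start = register - 2
    slots <- rbind(data.frame(reg = registers, strand = "+"),
                   data.frame(reg = registers, strand = "-"))
    picked <- slots[sample(nrow(slots), n_phased), , drop = FALSE]
    mk <- function(reg, strand) {
      start <- if (strand == "+") reg else reg - 2L
      s <- substr(gseq, start, start + phase - 1L)
      if (strand == "-") s <- revcomp(s)
      data.frame(sequence = s, chrom = chrom, start = start,
                 strand = strand, phased = TRUE, stringsAsFactors = FALSE)
    }
    tags <- NULL
    if (n_phased > 0)
      tags <- do.call(rbind, Map(mk, picked$reg, picked$strand))
    if (n_offphase > 0) {
      offsets <- setdiff(seq_len(win_len - phase), phase * seq_len(n_cycles))
      offs <- sample(offsets, n_offphase, replace = n_offphase > length(offsets))
      off_tags <- do.call(rbind, lapply(offs, function(o) {
        start <- window_start + o  # o not a multiple of phase offset 0 register
        s <- substr(gseq, start, start + phase - 1L)
        data.frame(sequence = s, chrom = chrom, start = start,
                   strand = "+", phased = FALSE, stringsAsFactors = FALSE)
      }))
      tags <- rbind(tags, off_tags)
    }
    if (is.null(tags))
      tags <- data.frame(sequence = character(), chrom = character(),
                         start = integer(), strand = character(),
                         phased = logical(), stringsAsFactors = FALSE)
    tags[!duplicated(tags[c("start", "strand")]), , drop = FALSE]
  })
}

#' Simulate a count matrix for differential-expression experiments
#'
#' Per-locus means are drawn log-normally (many low, few high); replicate
#' counts are Poisson around the group mean; selected high-abundance loci
#' (mean >= `high_threshold`) receive a multiplicative fold change in the MT
#' group. With `n_inject = 0` this is a null experiment.
#'
#' @param n_mirnas number of loci (rows).
#' @param seed RNG seed.
#' @param n_inject number of loci receiving the injected fold change.
#' @param fold injected MT/WT fold change (default 8).
#' @param high_threshold minimum base mean for injectable loci.
#' @param meanlog,sdlog log-normal parameters of the base means.
#' @return list `counts` (matrix, 2 MT + 2 WT columns), `groups`,
#'   `injected` (logical truth vector).
#' @export
gen_de_experiment <- function(n_mirnas = 200L, seed = 1L, n_inject = 0L,
                              fold = 8, high_threshold = 50,
                              meanlog = log(50), sdlog = 1.5) {
  with_seed(seed, {
    base <- stats::rlnorm(n_mirnas, meanlog, sdlog)
    injected <- rep(FALSE, n_mirnas)
    fc <- rep(1, n_mirnas)
    if (n_inject > 0) {
      hi <- which(base >= high_threshold)
      pick <- sample(hi, min(n_inject, length(hi)))
      fc[pick] <- fold
      injected[pick] <- TRUE
    }
    counts <- cbind(MT_bio1 = stats::rpois(n_mirnas, base * fc),
                    MT_bio2 = stats::rpois(n_mirnas, base * fc),
                    WT_bio1 = stats::rpois(n_mirnas, base),
                    WT_bio2 = stats::rpois(n_mirnas, base))
    rownames(counts) <- sprintf("m%03d", seq_len(n_mirnas))
    list(counts = counts,
         groups = list(MT = c("MT_bio1", "MT_bio2"),
                       WT = c("WT_bio1", "WT_bio2")),
         injected = injected)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper tying the generators together: genome with planted
#' miRNA and PHAS loci, four sRNA libraries, and tags for each PHAS locus
#' appended to the table.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `mirna_truth`, `phas_truth`, `tags`,
#'   `groups`, `phas_tags`.
#' @export
simulate_study <- function(config = sim_config()) {
  g <- gen_genome(config)
  tags <- gen_srna_libraries(config, g$mirna_truth)
  groups <- attr(tags, "groups")
  libs <- unlist(groups, use.names = FALSE)
  phas_tags <- NULL
  if (!is.null(g$phas_truth)) {
    for (j in seq_len(nrow(g$phas_truth))) {
      pt <- gen_phas_locus(config, g$genome,
                           window_start = g$phas_truth$start[j],
                           n_cycles = 11L, n_phased = 11L, n_offphase = 2L,
                           seed = config$seed * 100L + j)
      pt$locus_id <- g$phas_truth$locus_id[j]
      phas_tags <- rbind(phas_tags, pt)
    }
    # append phasiRNA tags to the table with modest uniform counts
    new_seq <- setdiff(phas_tags$sequence, tags$sequence)
    if (length(new_seq)) {
      cnts <- with_seed(config$seed + 13L, {
        matrix(stats::rpois(length(new_seq) * length(libs), 8),
               nrow = length(new_seq))
      })
      cnts <- as.data.frame(cnts); colnames(cnts) <- libs
      add <- tag_table(new_seq, cnts, libs)
      merged <- rbind(as.data.frame(tags), as.data.frame(add))
      tags <- tag_table(merged$sequence, merged[libs], libs)
      attr(tags, "groups") <- groups
    }
  }
  list(genome = g$genome, mirna_truth = g$mirna_truth,
       phas_truth = g$phas_truth, tags = tags, groups = groups,
       phas_tags = phas_tags)
}
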