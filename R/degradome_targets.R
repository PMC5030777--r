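# Degradome (PARE) target calling: tag pre-processing (Rfam > GenBank >
# polyN removal), rule-based miRNA:target complementarity scoring with a
# doubled-penalty core region, cleavage-site prediction opposite miRNA
# position 10, and category 0-4 classification of cleavage sites.

#' Degradome profile container
#'
#' Per-transcript map of 1-based positions (the 5' ends of degradome tags)
#' to raw abundances.
#'
#' @param transcript transcript id.
#' @param length transcript length, nt.
#' @param abundance named integer vector: names are 1-based positions,
#'   values are raw read counts (>= 1).
#' @return a `degradome_profile` list.
#' @export
degradome_profile <- function(transcript, length, abundance) {
  pos <- as.integer(names(abundance))
  if (length(abundance)) {
    if (any(is.na(pos)) || any(pos < 1) || any(pos > length))
      stopf("degradome_profile: positions outside [1, %d]", length)
    if (any(abundance < 1))
      stopf("degradome_profile: stored abundances must be >= 1")
  }
  ab <- as.integer(abundance)
  names(ab) <- as.character(pos)
  structure(list(transcript = transcript, length = as.integer(length),
                 abundance = ab),
            class = "degradome_profile")
}

#' Pre-process degradome tags
#'
#' Removes structural-RNA and low-complexity tags before target prediction,
#' with the removal priority Rfam > GenBank > polyN. A tag is polyN when any
#' single base makes up strictly more than 70% of its length.
#'
#' @param tags a [tag_table()] of degradome tags.
#' @param structural_db data.frame `id`, `sequence`, `source`
#'   (`"Rfam"`/`"GenBank"`) of structural RNAs.
#' @param polyn_fraction the strict polyN threshold (default 0.7).
#' @return list `tags` (survivors) and `ledger` (data.frame `sequence`,
#'   `removed_as` for every removed tag).
#' @export
preprocess_degradome <- function(tags, structural_db = NULL,
                                 polyn_fraction = 0.7) {
  norm <- dna_norm(tags$sequence)
  reason <- rep(NA_character_, nrow(tags))
  if (!is.null(structural_db) && nrow(structural_db)) {
    rf <- matches_seq_db(norm, structural_db$sequence[structural_db$source == "Rfam"])
    gb <- matches_seq_db(norm, structural_db$sequence[structural_db$source == "GenBank"])
    reason[gb] <- "GenBank"
    reason[rf] <- "Rfam"  # Rfam outranks GenBank in the removal ledger
  }
  is_polyn <- vapply(norm, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    max(table(ch)) / length(ch) > polyn_fraction
  }, logical(1), USE.NAMES = FALSE)
  reason[is_polyn & is.na(reason)] <- "polyN"
  keep <- is.na(reason)
  out <- tags[keep, , drop = FALSE]
  attr(out, "libraries") <- tag_libraries(tags)
  class(out) <- class(tags)
  list(tags = out,
       ledger = data.frame(sequence = tags$sequence[!keep],
                           removed_as = reason[!keep],
                           stringsAsFactors = FALSE))
}

# Penalty for pairing miRNA base m against target base t (both sense
# characters, DNA alphabet): 0 Watson-Crick, 0.5 G:U wobble, 1 mismatch.
pair_penalty <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
        (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, 0, ifelse(gu, 0.5, 1))
}

#' Score miRNA:target complementarity
#'
#' Rule-based scoring of a miRNA (5'->3') against a target site window
#' (transcript sense sequence, 5'->3', paired antiparallel): each mismatch
#' costs 1.0, each G:U wobble 0.5 and each gapped position 1.0, with
#' penalties at miRNA positions 2-13 doubled. Perfect Watson-Crick
#' complementarity scores 0. Gaps are handled by a minimal-cost alignment;
#' equal-length inputs reduce to the ungapped column-wise score.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site_sequence target window on the transcript, sense orientation.
#' @param core doubled-penalty region in miRNA coordinates (default 2:13).
#' @param core_weight multiplier inside the core (default 2).
#' @return list `score`, `columns` (data.frame of aligned miRNA/target
#'   positions; target positions are 1-based within the window).
#' @export
score_alignment <- function(mirna, site_sequence, core = 2:13,
                            core_weight = 2) {
  if (!nzchar(mirna) || !nzchar(site_sequence))
    stopf("score_alignment: empty input")
  m <- strsplit(dna_norm(mirna), "", fixed = TRUE)[[1]]
  # reverse the window so column i of the DP pairs miRNA 5'->3' against the
  # target 3'->5' (antiparallel); wr[j] is window position n - j + 1
  w <- strsplit(dna_norm(site_sequence), "", fixed = TRUE)[[1]]
  n <- length(w)
  wr <- rev(w)
  lm <- length(m)
  wt <- function(i) if (i %in% core) core_weight else 1
  # DP over (i miRNA, j reversed-window) minimizing total penalty
  INF <- 1e9
  D <- matrix(INF, lm + 1, n + 1)
  D[1, 1] <- 0
  for (j in seq_len(n)) D[1, j + 1] <- D[1, j] + wt(1) * 1      # leading target gap
  for (i in seq_len(lm)) D[i + 1, 1] <- D[i, 1] + wt(i) * 1     # miRNA gap
  for (i in seq_len(lm)) {
    for (j in seq_len(n)) {
      sub <- D[i, j] + wt(i) * pair_penalty(m[i], wr[j])
      gap_m <- D[i, j + 1] + wt(i) * 1   # miRNA base unpaired (gap in target)
      gap_t <- D[i + 1, j] + wt(min(i + 1, lm)) * 1  # target base unpaired
      D[i + 1, j + 1] <- min(sub, gap_m, gap_t)
    }
  }
  # traceback for the aligned columns
  cols <- list()
  i <- lm; j <- n
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        isTRUE(all.equal(D[i + 1, j + 1],
                         D[i, j] + wt(i) * pair_penalty(m[i], wr[j])))) {
      cols[[length(cols) + 1]] <- data.frame(
        mirna_pos = i, window_pos = n - j + 1,
        penalty = wt(i) * pair_penalty(m[i], wr[j]))
      i <- i - 1; j <- j - 1
    } else if (i > 0 &&
               isTRUE(all.equal(D[i + 1, j + 1], D[i, j + 1] + wt(i) * 1))) {
      cols[[length(cols) + 1]] <- data.frame(
        mirna_pos = i, window_pos = NA_integer_, penalty = wt(i) * 1)
      i <- i - 1
    } else {
      cols[[length(cols) + 1]] <- data.frame(
        mirna_pos = NA_integer_, window_pos = n - j + 1,
        penalty = wt(min(i + 1, lm)) * 1)
      j <- j - 1
    }
  }
  columns <- do.call(rbind, rev(cols))
  list(score = D[lm + 1, n + 1], columns = columns)
}

#' Predict the cleavage position from an accepted alignment
#'
#' The cleavage site is the transcript coordinate pairing miRNA position 10
#' (the 5'-most nucleotide of the downstream cleavage fragment), 1-based.
#'
#' @param alignment result of [score_alignment()].
#' @param window_start 1-based transcript coordinate of the window's first
#'   position.
#' @param window_length window length on the transcript.
#' @param transcript_length transcript length (for bounds checking).
#' @return 1-based transcript cleavage position.
#' @export
predict_cleavage <- function(alignment, window_start, window_length,
                             transcript_length = Inf) {
  if (window_start < 1 ||
      window_start + window_length - 1 > transcript_length)
    stopf("predict_cleavage: window outside transcript")
  cols <- alignment$columns
  row <- cols[!is.na(cols$mirna_pos) & cols$mirna_pos == 10 &
                !is.na(cols$window_pos), , drop = FALSE]
  if (!nrow(row))
    stopf("predict_cleavage: miRNA position 10 is not paired in the alignment")
  window_start + row$window_pos[1] - 1L
}

#' Classify a cleavage site into category 0-4
#'
#' Categories (checked in this order): a site carrying a single raw read is
#' category 4; otherwise the unique transcript-wide maximum is 0; a shared
#' maximum is 1; above the median (over positions with >= 1 read) is 2; at
#' or below the median is 3.
#'
#' @param profile a [degradome_profile()].
#' @param site 1-based cleavage position (must carry >= 1 read).
#' @return integer category in 0:4.
#' @export
classify_category <- function(profile, site) {
  ab <- profile$abundance
  key <- as.character(site)
  if (!key %in% names(ab) || ab[key] < 1)
    stopf("classify_category: no raw reads at site %s", site)
  a <- ab[[key]]
  if (a == 1) return(4L)
  mx <- max(ab)
  if (a == mx) {
    if (sum(ab == mx) == 1) return(0L) else return(1L)
  }
  med <- stats::median(ab)
  if (a > med) 2L else 3L
}

#' Call miRNA targets from degradome profiles
#'
#' For every (miRNA, transcript) pair, each degradome-supported position is
#' treated as a candidate cleavage site; the window pairing the miRNA with
#' its position 10 opposite the site is scored ungapped, and sites with
#' alignment score <= `max_score` are reported with their category, cleavage
#' position and fragment abundance. The per-target p-value column is emitted
#' as NA (no statistic is defined for it here).
#'
#' @param mirnas data.frame `name`, `sequence`.
#' @param transcripts named character vector of transcript (cDNA) sequences.
#' @param profiles list of [degradome_profile()] keyed by transcript id.
#' @param max_score score acceptance ceiling (default 4.5, inclusive).
#' @return data.frame sorted by (miRNA, category, score): `miRNA`, `target`,
#'   `category`, `cleavage_position`, `p_value`, `fragment_abundance`,
#'   `alignment_score`.
#' @export
call_targets <- function(mirnas, transcripts, profiles, max_score = 4.5) {
  out <- list()
  for (k in seq_len(nrow(mirnas))) {
    mir <- dna_norm(mirnas$sequence[k])
    lm <- nchar(mir)
    for (tx in names(profiles)) {
      prof <- profiles[[tx]]
      seq_tx <- dna_norm(transcripts[[tx]])
      for (p in as.integer(names(prof$abundance))) {
        win_start <- p + 10L - lm
        win_end <- p + 9L
        if (win_start < 1 || win_end > nchar(seq_tx)) next
        win <- substr(seq_tx, win_start, win_end)
        aln <- score_alignment(mir, win)
        if (aln$score > max_score) next
        site <- predict_cleavage(aln, win_start, nchar(win), nchar(seq_tx))
        if (site != p) next  # the window was built so position 10 pairs p
        out[[length(out) + 1]] <- data.frame(
          miRNA = mirnas$name[k], target = tx,
          category = classify_category(prof, site),
          cleavage_position = site, p_value = NA_real_,
          fragment_abundance = unname(prof$abundance[as.character(site)]),
          alignment_score = aln$score, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(miRNA = character(), target = character(),
                      category = integer(), cleavage_position = integer(),
                      p_value = numeric(), fragment_abundance = integer(),
                      alignment_score = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$miRNA, res$category, res$alignment_score), , drop = FALSE]
}
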