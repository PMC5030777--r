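# PHAS locus detection: 21-nt genome-matched tags are scanned in sliding
# windows of phase x cycles nt; antisense starts are shifted by the 2-nt
# duplex offset onto the sense register; windows are scored with a
# hypergeometric tail probability and significant windows are merged keeping
# the minimum-p representative.

#' Hypergeometric phasing p-value
#'
#' Tail probability P(X >= k) of drawing `k` in-register start positions
#' among `n` observed distinct starts, from a population of all
#' `2 * phase * cycles` start positions in the window (both strands) of
#' which `2 * cycles` lie on the phased register.
#'
#' @param n distinct observed start positions in the window.
#' @param k of those, the number on the phased register.
#' @param cycles number of phase cycles in the window (default 11).
#' @param phase phase length in nt (default 21).
#' @return tail probability in (0, 1].
#' @export
phasing_pvalue <- function(n, k, cycles = 11L, phase = 21L) {
  if (phase <= 0 || cycles < 2) stopf("phasing_pvalue: phase <= 0 or cycles < 2")
  pop <- 2L * phase * cycles
  succ <- 2L * cycles
  if (n > pop) stopf("phasing_pvalue: n exceeds the number of start positions")
  stats::phyper(k - 1L, succ, pop - succ, n, lower.tail = FALSE)
}

# Effective (register-comparable) start of a tag: plus-strand leftmost
# coordinate for sense tags; leftmost + 2 for antisense tags (duplex offset).
effective_starts <- function(positions) {
  ifelse(positions$strand == "+", positions$start, positions$start + 2L)
}

#' Detect phased siRNA (PHAS) loci
#'
#' Only exactly 21-nt (= `phase`) genome-matched tags enter the analysis.
#' Windows of `phase * cycles` nt anchored at each observed start are scored
#' with [phasing_pvalue()]; windows need at least `min_k` in-register
#' positions, and overlapping significant windows are merged keeping the
#' minimum-p window's coordinates.
#'
#' @param tags either a data.frame `sequence`, `chrom`, `start`, `strand`
#'   (positions known) or a [tag_table()] plus `genome` to be matched.
#' @param genome named character vector (needed when `tags` lacks
#'   positions).
#' @param phase phase length, nt (default 21).
#' @param cycles window size in cycles (default 11).
#' @param cutoff reporting threshold on the p-value (default 1e-4).
#' @param min_k minimum in-register positions (default 3).
#' @return data.frame of loci: `chrom`, `start`, `end`, `n`, `k`,
#'   `p_value`, `n_phasirnas`, with member tags in the `members` attribute
#'   (list of data.frames).
#' @export
detect_phasirnas <- function(tags, genome = NULL, phase = 21L, cycles = 11L,
                             cutoff = 1e-4, min_k = 3L) {
  if (phase <= 0 || cycles < 2) stopf("detect_phasirnas: phase <= 0 or cycles < 2")
  if (!all(c("chrom", "start", "strand") %in% names(tags))) {
    if (is.null(genome))
      stopf("detect_phasirnas: genome required to position tags")
    hits <- match_genome(tags, genome)
    tags <- hits
  }
  tags <- tags[nchar(tags$sequence) == phase, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n = integer(), k = integer(),
                      p_value = numeric(), n_phasirnas = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(tags)) return(empty)
  win_len <- phase * cycles
  loci <- list(); members <- list()
  for (chrom in unique(tags$chrom)) {
    tc <- tags[tags$chrom == chrom, , drop = FALSE]
    tc$eff <- effective_starts(tc)
    tc <- tc[!duplicated(tc[c("eff", "strand")]), , drop = FALSE]
    for (w in sort(unique(tc$eff))) {
      sel <- tc$eff >= w & tc$eff <= w + win_len - phase
      n <- sum(sel)
      k <- sum((tc$eff[sel] - w) %% phase == 0)
      if (k < min_k) next
      p <- phasing_pvalue(n, k, cycles, phase)
      if (p > cutoff) next
      loci[[length(loci) + 1]] <- data.frame(
        chrom = chrom, start = w, end = w + win_len - 1L,
        n = n, k = k, p_value = p, stringsAsFactors = FALSE)
      mem <- tc[sel & (tc$eff - w) %% phase == 0, , drop = FALSE]
      members[[length(loci)]] <- mem
    }
  }
  if (!length(loci)) return(empty)
  df <- do.call(rbind, loci)
  # merge overlapping windows, keeping the minimum-p window per cluster
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  cl <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr),
                                    select = "first")
  keep <- vapply(split(seq_len(nrow(df)), cl), function(idx) {
    idx[which.min(df$p_value[idx])]
  }, integer(1))
  out <- df[keep, , drop = FALSE]
  mem_out <- members[keep]
  out$n_phasirnas <- vapply(mem_out, function(m) length(unique(m$sequence)),
                            integer(1))
  rownames(out) <- NULL
  attr(out, "members") <- mem_out
  out
}

#' Number of distinct phasiRNAs in a detected locus
#'
#' @param locus a single-row slice of the [detect_phasirnas()] result (with
#'   its `members` attribute), or the full result plus `which`.
#' @param which row index when `locus` is the full table.
#' @return number of distinct member tag sequences at phased registers.
#' @export
count_phasirnas <- function(locus, which = 1L) {
  mem <- attr(locus, "members")[[which]]
  length(unique(mem$sequence))
}

#' Link PHAS loci to miRNA triggers via degradome cleavage
#'
#' A locus gains a trigger annotation iff an accepted target alignment's
#' cleavage position (lifted to genome coordinates through the transcript
#' locus map) falls within the locus window extended by one phase on each
#' side. Multiple triggers are all recorded, sorted by alignment score.
#'
#' @param loci [detect_phasirnas()] result.
#' @param target_alignments [call_targets()] result.
#' @param transcript_loci data.frame `transcript`, `chrom`, `start` (1-based
#'   genomic start of the transcript), `strand`.
#' @param phase phase length used for the window extension (default 21).
#' @return data.frame: one row per (locus, trigger) with `trigger_miRNA`,
#'   `trigger_position` (genomic), plus untriggered loci with NA trigger.
#' @export
link_triggers <- function(loci, target_alignments, transcript_loci,
                          phase = 21L) {
  if (!nrow(loci)) return(cbind(loci, trigger_miRNA = character(0),
                                trigger_position = integer(0)))
  ta <- merge(target_alignments, transcript_loci,
              by.x = "target", by.y = "transcript")
  ta$genomic_site <- ifelse(ta$strand == "+",
                            ta$start + ta$cleavage_position - 1L,
                            ta$start - ta$cleavage_position + 1L)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    lo <- loci$start[i] - phase
    hi <- loci$end[i] + phase
    hit <- ta[ta$chrom == loci$chrom[i] &
                ta$genomic_site >= lo & ta$genomic_site <= hi, , drop = FALSE]
    if (nrow(hit)) {
      hit <- hit[order(hit$alignment_score), , drop = FALSE]
      for (j in seq_len(nrow(hit))) {
        rows[[length(rows) + 1]] <- cbind(
          loci[i, , drop = FALSE],
          data.frame(trigger_miRNA = hit$miRNA[j],
                     trigger_position = hit$genomic_site[j],
                     trigger_score = hit$alignment_score[j],
                     stringsAsFactors = FALSE))
      }
    } else {
      rows[[length(rows) + 1]] <- cbind(
        loci[i, , drop = FALSE],
        data.frame(trigger_miRNA = NA_character_,
                   trigger_position = NA_integer_,
                   trigger_score = NA_real_, stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
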