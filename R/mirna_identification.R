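# Known-miRNA identification (family alignment, family representatives,
# ungapped quantification) and novel-miRNA prediction (hairpin folding via
# minimum-free-energy structure, 2-nt 3' overhang star geometry, bulge and
# abundance criteria, observed-star requirement).

#' Align a tag to a miRNA database within a mismatch/gap budget
#'
#' Global alignment of the tag against a local region of each database entry
#' (mature or precursor), accepting assignments with at most
#' `max_mismatches` substitutions and at most `max_gaps` gapped positions,
#' budgeted separately. Assignments are returned best-first (fewest
#' mismatches + gaps).
#'
#' @param tag tag sequence.
#' @param db data.frame with columns `id`, `family`, `sequence`.
#' @param max_mismatches substitution budget (default 2).
#' @param max_gaps gap-position budget (default 3).
#' @return data.frame `id`, `family`, `mismatches`, `gaps`, best-first.
#' @export
align_to_mirbase <- function(tag, db, max_mismatches = 2L, max_gaps = 3L) {
  tg <- Biostrings::DNAString(dna_norm(tag))
  res <- lapply(seq_len(nrow(db)), function(k) {
    subj <- Biostrings::DNAString(dna_norm(db$sequence[k]))
    aln <- Biostrings::pairwiseAlignment(
      tg, subj, type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 0, gapExtension = 1)
    mm <- Biostrings::nmismatch(aln)
    ind <- Biostrings::nindel(aln)
    gaps <- sum(ind@insertion[, "WidthSum"], ind@deletion[, "WidthSum"])
    data.frame(id = db$id[k], family = db$family[k],
               mismatches = mm, gaps = gaps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[out$mismatches <= max_mismatches & out$gaps <= max_gaps, ,
             drop = FALSE]
  out[order(out$mismatches + out$gaps, out$mismatches, out$id), , drop = FALSE]
}

#' Choose the highest-expressed tag per family as representative
#'
#' For every miRNA family with at least one assigned tag, the tag with the
#' highest summed raw count across libraries becomes the family's temporary
#' representative; ties break to the lexicographically smaller sequence.
#'
#' @param assignments data.frame `sequence`, `family` (one row per tag/family
#'   assignment).
#' @param tags a [tag_table()] providing the counts.
#' @return data.frame `family`, `sequence`, `total_count` (the temporary
#'   miRNA database).
#' @export
build_family_representatives <- function(assignments, tags) {
  tot <- rowSums(tag_counts(tags))
  names(tot) <- tags$sequence
  fams <- split(assignments$sequence, assignments$family)
  out <- lapply(names(fams), function(fam) {
    seqs <- unique(fams[[fam]])
    cts <- tot[seqs]
    cts[is.na(cts)] <- 0
    best <- seqs[cts == max(cts)]
    best <- sort(best)[1]
    data.frame(family = fam, sequence = best,
               total_count = as.integer(max(cts)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Hamming distance between equal-length strings; Inf for unequal lengths.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Quantify known miRNAs against the temporary database
#'
#' Each representative's count per library is the sum over tags within two
#' ungapped mismatches (equal length, Hamming distance <= `max_mismatches`).
#' A tag contributes to at most one representative: its best match, ties
#' broken toward the higher-expressed representative.
#'
#' @param tags a [tag_table()].
#' @param temp_db output of [build_family_representatives()].
#' @param max_mismatches ungapped substitution budget (default 2).
#' @return matrix of counts, one row per representative family, one column
#'   per library.
#' @export
quantify_known <- function(tags, temp_db, max_mismatches = 2L) {
  libs <- tag_libraries(tags)
  cnt <- tag_counts(tags)
  norm <- dna_norm(tags$sequence)
  rep_norm <- dna_norm(temp_db$sequence)
  out <- matrix(0L, nrow = nrow(temp_db), ncol = length(libs),
                dimnames = list(temp_db$family, libs))
  for (i in seq_len(nrow(tags))) {
    d <- vapply(rep_norm, hamming, numeric(1), a = norm[i])
    ok <- which(d <= max_mismatches)
    if (!length(ok)) next
    best <- ok[d[ok] == min(d[ok])]
    if (length(best) > 1)  # tie: higher-expressed representative
      best <- best[order(-temp_db$total_count[best], temp_db$family[best])][1]
    out[best[1], ] <- out[best[1], ] + cnt[i, ]
  }
  out
}

# --- hairpin folding ---------------------------------------------------------

# Parse a dot-bracket string into a pair table (0 = unpaired).
pair_table <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stopf("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stopf("unbalanced dot-bracket string")
  pt
}

#' Fold a precursor candidate into its MFE secondary structure
#'
#' Deterministic minimum-free-energy folding (ViennaRNA's `RNAfold`). The
#' hairpin test requires a single terminal loop: every base pair nests into
#' one stem (no ")(" transition in the bracket string), so no multiloop can
#' separate a mature from its star.
#'
#' @param sequence precursor sequence (50-400 nt by default).
#' @param length_range permitted length window.
#' @return a `hairpin_structure` list: `sequence`, `structure` (dot-bracket),
#'   `mfe` (kcal/mol), `pair_table`, `is_hairpin`, and arm intervals
#'   `arm5`, `loop`, `arm3` (NULL when no pair exists).
#' @export
fold_hairpin <- function(sequence, length_range = c(50L, 400L)) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGUTN]", sequence))
    stopf("fold_hairpin: non-IUPAC nucleotide in input")
  n <- nchar(sequence)
  if (n < length_range[1] || n > length_range[2])
    stopf("fold_hairpin: sequence length %d outside [%d, %d]",
          n, length_range[1], length_range[2])
  out <- system2("RNAfold", args = c("--noPS"), input = sequence,
                 stdout = TRUE, stderr = FALSE)
  if (length(out) < 2)
    stopf("fold_hairpin: RNAfold produced no structure (is ViennaRNA installed?)")
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3)
    stopf("fold_hairpin: cannot parse RNAfold output: %s", line)
  structure <- m[2]
  mfe <- as.numeric(m[3])
  pt <- pair_table(structure)
  brackets <- gsub("\\.", "", structure)
  is_hairpin <- nzchar(brackets) && !grepl("\\)\\(", brackets)
  arm5 <- loop <- arm3 <- NULL
  if (is_hairpin) {
    opens <- which(strsplit(structure, "")[[1]] == "(")
    i_top <- max(opens)
    j_top <- pt[i_top]
    arm5 <- c(1L, i_top)
    loop <- c(i_top + 1L, j_top - 1L)
    arm3 <- c(j_top, n)
  }
  structure(list(sequence = sequence, structure = structure, mfe = mfe,
                 pair_table = pt, is_hairpin = is_hairpin,
                 arm5 = arm5, loop = loop, arm3 = arm3),
            class = "hairpin_structure")
}

#' Derive the miRNA* interval implied by 2-nt 3' overhang geometry
#'
#' In a canonical miRNA/miRNA* duplex both 3' ends protrude by exactly two
#' nucleotides, so the folded pairing determines the star from the mature:
#' star spans `[p(b-2), p(a)+2]` where `[a, b]` is the mature interval and
#' `p()` the base-pairing partner. Returns a failure (not an error) when the
#' mature overlaps the terminal loop, when its duplex ends are unpaired, or
#' when a supplied candidate star disagrees with the implied interval (e.g.
#' a blunt-ended duplex).
#'
#' @param hairpin a [fold_hairpin()] result.
#' @param mature_interval 1-based `(start, end)` of the mature on the
#'   precursor.
#' @param star_interval optional candidate star interval to validate.
#' @param tolerance allowed |implied length - mature length| (bulges shift
#'   the partner by up to this much; default 2).
#' @return list `ok` (logical), `star_interval`, `reason`.
#' @export
check_star_overhang <- function(hairpin, mature_interval,
                                star_interval = NULL, tolerance = 2L) {
  pt <- hairpin$pair_table
  a <- mature_interval[1]; b <- mature_interval[2]
  fail <- function(reason) list(ok = FALSE, star_interval = NULL, reason = reason)
  if (a < 1 || b > length(pt) || a >= b) return(fail("mature outside precursor"))
  if (!is.null(hairpin$loop)) {
    lo <- hairpin$loop
    if (a <= lo[2] && b >= lo[1]) {
      # mature positions inside the terminal loop
      inside <- sum(seq(a, b) >= lo[1] & seq(a, b) <= lo[2])
      if (inside > 0) return(fail("mature overlaps the terminal loop"))
    }
  }
  if (pt[a] == 0 || pt[b - 2L] == 0)
    return(fail("mature duplex ends unpaired in the fold"))
  star <- sort(c(pt[b - 2L], pt[a] + 2L))
  if (star[1] < 1 || star[2] > length(pt))
    return(fail("implied star extends outside the precursor"))
  L <- b - a + 1L
  if (abs((star[2] - star[1] + 1L) - L) > tolerance)
    return(fail("folded pairing implies a non-canonical duplex"))
  if (max(star[1], a) <= min(star[2], b))
    return(fail("implied star overlaps the mature"))
  if (!is.null(star_interval)) {
    if (!identical(as.integer(star_interval), as.integer(star)))
      return(fail(sprintf(
        "candidate star [%d,%d] does not carry 2-nt 3' overhangs (implied [%d,%d])",
        star_interval[1], star_interval[2], star[1], star[2])))
  }
  list(ok = TRUE, star_interval = star, reason = "ok")
}

# Is the region a single stem-loop? Considering only pairs lying wholly
# inside the region, the bracket sequence must contain no ")(" transition
# (no multiloop); pairs leaving the region disqualify it.
single_stem_region <- function(pt, region) {
  idx <- seq(region[1], region[2])
  sub <- pt[idx]
  # only pairs with both ends inside the region count; pairs reaching out
  # belong to the enclosing stem and are ignored
  paired <- which(sub != 0 & sub >= region[1] & sub <= region[2])
  if (!length(paired)) return(FALSE)
  br <- ifelse(sub[paired] > idx[paired], "(", ")")
  !grepl(")(", paste(br, collapse = ""), fixed = TRUE)
}

# Largest internal loop / bulge (unpaired run on either side, or asymmetry
# between consecutive pairs) within the mature/star duplex.
duplex_max_bulge <- function(hairpin, mature_interval) {
  pt <- hairpin$pair_table
  a <- mature_interval[1]; b <- mature_interval[2]
  paired <- which(pt[a:(b - 2L)] != 0) + a - 1L
  if (length(paired) < 2) return(Inf)
  mx <- 0L
  for (k in seq_len(length(paired) - 1L)) {
    i <- paired[k]; j <- paired[k + 1L]
    gap_m <- j - i - 1L                    # unpaired run on the mature side
    gap_s <- abs(pt[i] - pt[j]) - 1L       # skipped positions on the star side
    mx <- max(mx, gap_m, gap_s)
  }
  mx
}

#' Evaluate a precursor candidate as a miRNA hairpin
#'
#' Folds the candidate and applies the structural criteria: single-hairpin
#' fold, mature wholly within one arm, star interval with 2-nt 3' overhangs,
#' maximal duplex bulge, and an MFE ceiling.
#'
#' @param sequence precursor candidate.
#' @param mature_interval mature position on the candidate.
#' @param mfe_max MFE acceptance ceiling, kcal/mol (default -18; accept iff
#'   `mfe <= mfe_max`).
#' @param max_bulge largest tolerated internal loop/bulge in the duplex, nt
#'   (default 5).
#' @param length_range permitted precursor length window (passed to
#'   [fold_hairpin()]).
#' @return list with `ok`, per-criterion flags, `hairpin`, `star_interval`.
#' @export
evaluate_hairpin <- function(sequence, mature_interval, mfe_max = -18,
                             max_bulge = 5L, length_range = c(50L, 400L)) {
  hp <- fold_hairpin(sequence, length_range = length_range)
  # the star-geometry tolerance must accommodate duplex bulges up to the
  # point where the bulge criterion itself rejects the locus, so the two
  # criteria stay independent
  star <- check_star_overhang(hp, mature_interval,
                              tolerance = max(2L, max_bulge + 3L))
  bulge <- if (star$ok) duplex_max_bulge(hp, mature_interval) else Inf
  # the hairpin criterion is local: the mature/star span must fold as one
  # stem-loop (no multiloop separating mature from star); structure outside
  # the candidate duplex (random flank) is irrelevant
  hairpin_ok <- if (star$ok) {
    single_stem_region(hp$pair_table,
                       range(c(mature_interval, star$star_interval)))
  } else hp$is_hairpin
  crit <- c(hairpin = hairpin_ok,
            star = star$ok,
            bulge = is.finite(bulge) && bulge <= max_bulge,
            mfe = hp$mfe <= mfe_max)
  list(ok = all(crit), criteria = crit, hairpin = hp,
       star_interval = star$star_interval, max_bulge = bulge)
}

#' Predict novel miRNAs from unannotated genome-matched tags
#'
#' Candidate tags are those annotated `unann` or `intron`, plus tags hitting
#' an exon on its antisense strand. For each candidate tag cluster the most
#' abundant tag is treated as the mature; flanking genomic windows on the
#' tag's strand are folded and the locus is accepted iff (hairpin fold) the
#' window folds into a single hairpin with the mature in one arm; (star) a
#' star with 2-nt 3' overhangs is implied by the fold and the corresponding
#' tag is observed in the data (when `require_star`); (bulge) no duplex
#' internal loop/bulge exceeds `max_bulge`; (mfe) MFE <= `mfe_max`; (count)
#' the mature tag's summed count is >= `min_count`.
#'
#' @param tags a [tag_table()].
#' @param genome named character vector of chromosomes.
#' @param annotated the `annotated` data.frame from [annotate()] (supplies
#'   categories); if `NULL`, all genome-matching tags are candidates.
#' @param tracks annotation tracks (for the antisense-exon rule).
#' @param genome_hits optional precomputed [match_genome()] result.
#' @param min_count minimum summed mature count (default 5).
#' @param mfe_max MFE ceiling (default -18 kcal/mol).
#' @param max_bulge maximal duplex bulge (default 5 nt).
#' @param require_star require the star tag to be observed (default TRUE).
#' @param windows candidate window half-widths around the mature, nt.
#' @return data.frame of accepted records: name, mature/star sequences, arm,
#'   locus coordinates, precursor, mfe, mature count, per-library counts.
#' @export
predict_novel <- function(tags, genome, annotated = NULL, tracks = list(),
                          genome_hits = NULL, min_count = 5L, mfe_max = -18,
                          max_bulge = 5L, require_star = TRUE,
                          windows = c(90L, 130L)) {
  libs <- tag_libraries(tags)
  if (is.null(genome_hits)) genome_hits <- match_genome(tags, genome)
  cand_seqs <- candidate_novel_tags(tags, annotated, tracks, genome_hits)
  hits <- genome_hits[genome_hits$sequence %in% cand_seqs, , drop = FALSE]
  if (!nrow(hits)) return(empty_novel_records(libs))
  tot <- rowSums(tag_counts(tags)); names(tot) <- tags$sequence
  # cluster hits per chrom/strand within 50 nt
  hits <- hits[order(hits$chrom, hits$strand, hits$start), , drop = FALSE]
  gap <- c(Inf, diff(hits$start))
  newgrp <- gap > 50 | c(TRUE, hits$chrom[-1] != hits$chrom[-nrow(hits)] |
                           hits$strand[-1] != hits$strand[-nrow(hits)])
  grp <- cumsum(newgrp)
  records <- list()
  for (g in unique(grp)) {
    cl <- hits[grp == g, , drop = FALSE]
    mature_row <- cl[which.max(tot[cl$sequence]), , drop = FALSE]
    rec <- evaluate_novel_locus(mature_row, tags, genome, tot,
                                min_count, mfe_max, max_bulge,
                                require_star, windows, libs)
    if (!is.null(rec)) records[[length(records) + 1]] <- rec
  }
  if (!length(records)) return(empty_novel_records(libs))
  out <- do.call(rbind, records)
  # a hairpin is an inverted repeat: the same locus surfaces on both strands
  # (and via its star arm); collapse overlapping loci keeping the
  # highest-expressed mature
  out <- out[order(-out$mature_count), , drop = FALSE]
  gr <- GenomicRanges::GRanges(out$chrom,
                               IRanges::IRanges(out$locus_start, out$locus_end))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prior <- which(keep[seq_len(i - 1)])
    if (any(IRanges::overlapsAny(gr[i], gr[prior]))) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$name <- sprintf("novel_%02d", seq_len(nrow(out)))
  out[, c("name", setdiff(colnames(out), "name"))]
}

candidate_novel_tags <- function(tags, annotated, tracks, genome_hits) {
  matched <- unique(genome_hits$sequence)
  if (is.null(annotated)) return(matched)
  cand <- annotated$sequence[annotated$category %in% c("unann", "intron")]
  # antisense-exon tags: a hit overlapping an exon interval on its opposite strand
  exon_tracks <- tracks[vapply(tracks, function(tr)
    any(S4Vectors::mcols(tr)$class == "exon"), logical(1))]
  if (length(exon_tracks) && nrow(genome_hits)) {
    ex <- do.call(c, lapply(exon_tracks, function(tr)
      tr[S4Vectors::mcols(tr)$class == "exon"]))
    hg <- GenomicRanges::GRanges(
      genome_hits$chrom,
      IRanges::IRanges(genome_hits$start,
                       genome_hits$start + nchar(genome_hits$sequence) - 1L),
      strand = genome_hits$strand)
    ov <- GenomicRanges::findOverlaps(hg, ex, ignore.strand = TRUE)
    anti <- as.character(GenomicRanges::strand(hg))[S4Vectors::queryHits(ov)] !=
      as.character(GenomicRanges::strand(ex))[S4Vectors::subjectHits(ov)] &
      as.character(GenomicRanges::strand(ex))[S4Vectors::subjectHits(ov)] %in% c("+", "-")
    cand <- union(cand, unique(genome_hits$sequence[S4Vectors::queryHits(ov)[anti]]))
  }
  intersect(cand, matched)
}

evaluate_novel_locus <- function(mature_row, tags, genome, tot, min_count,
                                 mfe_max, max_bulge, require_star, windows,
                                 libs) {
  chrom_seq <- dna_norm(genome[[mature_row$chrom]])
  L <- nchar(mature_row$sequence)
  s <- mature_row$start
  mature_count <- tot[mature_row$sequence]
  if (is.na(mature_count) || mature_count < min_count) return(NULL)
  norm_tags <- dna_norm(tags$sequence)
  for (w in windows) {
    # two placements: mature near the window 5' end (5p arm) or 3' end (3p arm)
    for (placement in c("5p", "3p")) {
      if (placement == "5p") {
        win_start <- max(1L, s - 20L)
        win_end <- min(nchar(chrom_seq), win_start + w - 1L)
      } else {
        win_end <- min(nchar(chrom_seq), s + L - 1L + 20L)
        win_start <- max(1L, win_end - w + 1L)
      }
      win_seq <- substr(chrom_seq, win_start, win_end)
      if (mature_row$strand == "-") win_seq <- revcomp(win_seq)
      moff <- if (mature_row$strand == "+") s - win_start + 1L
              else win_end - (s + L - 1L) + 1L
      mi <- c(moff, moff + L - 1L)
      if (mi[1] < 1 || mi[2] > nchar(win_seq)) next
      ev <- tryCatch(
        evaluate_hairpin(win_seq, mi, mfe_max = mfe_max, max_bulge = max_bulge),
        error = function(e) NULL)
      if (is.null(ev) || !ev$criteria[["hairpin"]] || !ev$criteria[["star"]]) next
      if (!ev$criteria[["bulge"]] || !ev$criteria[["mfe"]]) next
      star_seq <- substr(win_seq, ev$star_interval[1], ev$star_interval[2])
      star_observed <- star_seq %in% norm_tags
      if (require_star && !star_observed) next
      cnt <- tag_counts(tags)[match(mature_row$sequence, tags$sequence), ,
                              drop = FALSE]
      rec <- data.frame(
        mature = mature_row$sequence, star = star_seq,
        arm = if (ev$star_interval[1] > mi[2]) "5p" else "3p",
        chrom = mature_row$chrom, strand = mature_row$strand,
        locus_start = win_start, locus_end = win_end,
        precursor = win_seq, mfe = ev$hairpin$mfe,
        mature_count = as.integer(mature_count),
        star_observed = star_observed, stringsAsFactors = FALSE)
      rec <- cbind(rec, as.data.frame(cnt))
      colnames(rec)[(ncol(rec) - length(libs) + 1):ncol(rec)] <- libs
      return(rec)
    }
  }
  NULL
}

empty_novel_records <- function(libs) {
  base <- data.frame(name = character(), mature = character(),
                     star = character(), arm = character(),
                     chrom = character(), strand = character(),
                     locus_start = integer(), locus_end = integer(),
                     precursor = character(), mfe = numeric(),
                     mature_count = integer(), star_observed = logical(),
                     stringsAsFactors = FALSE)
  for (lib in libs) base[[lib]] <- integer()
  base
}

#' Retain miRNAs identified in both biological replicates
#'
#' A miRNA is reported for a genotype iff it was identified in both of the
#' genotype's replicate libraries; miRNAs present in both genotypes are
#' flagged.
#'
#' @param records data.frame with one row per miRNA and logical
#'   identification flags named after the libraries.
#' @param groups named list of library names per genotype.
#' @return `records` with added logical columns per genotype and
#'   `both_genotypes`.
#' @export
merge_replicates <- function(records, groups) {
  for (gt in names(groups)) {
    flags <- as.matrix(records[, groups[[gt]], drop = FALSE])
    records[[gt]] <- rowSums(flags) == length(groups[[gt]])
  }
  records$both_genotypes <- Reduce(`&`, lapply(names(groups),
                                               function(gt) records[[gt]]))
  records
}
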