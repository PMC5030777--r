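# Annotation of small RNA tags: length filtering, exact genome matching on
# both strands, and classification of every tag into exactly one category by
# the priority rule
#   rRNAetc (GenBank > Rfam) > known miRNA > repeat > exon > intron
# with unmatched tags falling through to "unann". Sequence-database classes
# (rRNAetc, miRNA) are assigned by sequence match regardless of genome
# position; interval classes (repeat, exon, intron) require a genome hit
# overlapping the interval (any >= 1 nt overlap, either strand).

ANNOTATION_CLASSES <- c("rRNAetc", "miRNA", "repeat", "exon", "intron", "unann")

#' Filter tags by length
#'
#' @param tags a [tag_table()].
#' @param min,max inclusive length bounds (default 18-28 nt).
#' @return the filtered tag table; the removed unique/total mass is attached
#'   as the `removed` attribute.
#' @export
length_filter <- function(tags, min = 18L, max = 28L) {
  if (min > max) stopf("length_filter: min > max")
  len <- nchar(tags$sequence)
  keep <- len >= min & len <= max
  out <- tags[keep, , drop = FALSE]
  attr(out, "libraries") <- tag_libraries(tags)
  attr(out, "groups") <- attr(tags, "groups")
  class(out) <- class(tags)
  attr(out, "removed") <- c(unique = sum(!keep),
                            total = sum(tag_counts(tags)[!keep, , drop = FALSE]))
  out
}

#' Match tags to a genome exactly on both strands
#'
#' Exact matching (tags and genome compared after mapping U to T) via
#' Biostrings dictionaries, grouped by tag width. A tag "matches the genome"
#' iff it has at least one hit on either strand.
#'
#' @param tags a [tag_table()] or character vector of sequences.
#' @param genome named character vector of chromosome sequences.
#' @return data.frame of hits: `sequence`, `chrom`, `start` (1-based
#'   leftmost plus-strand coordinate), `strand`.
#' @export
match_genome <- function(tags, genome) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  seqs <- unique(seqs)
  hits <- list()
  if (!length(seqs) || !length(genome)) {
    return(data.frame(sequence = character(), chrom = character(),
                      start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  norm <- dna_norm(seqs)
  chrom_sets <- lapply(genome, function(s) Biostrings::DNAString(dna_norm(s)))
  for (w in unique(nchar(norm))) {
    idx <- which(nchar(norm) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(norm[idx]))
    for (chrom in names(genome)) {
      subj <- chrom_sets[[chrom]]
      clen <- length(subj)
      m <- Biostrings::matchPDict(pd, subj)
      for (k in seq_along(m)) {
        st <- BiocGenerics::start(m[[k]])
        if (length(st))
          hits[[length(hits) + 1]] <- data.frame(
            sequence = seqs[idx[k]], chrom = chrom, start = st,
            strand = "+", stringsAsFactors = FALSE)
      }
      mr <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj))
      for (k in seq_along(mr)) {
        st <- BiocGenerics::start(mr[[k]])
        if (length(st))
          hits[[length(hits) + 1]] <- data.frame(
            sequence = seqs[idx[k]], chrom = chrom,
            start = clen - (st + w - 1L) + 1L,
            strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(sequence = character(), chrom = character(),
                      start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$sequence, out$chrom, out$start, out$strand), , drop = FALSE]
}

# Does each tag match (as exact substring, U/T-insensitive) any sequence of a
# database? Returns logical vector over tags.
matches_seq_db <- function(tags_norm, db_seqs) {
  if (!length(db_seqs)) return(rep(FALSE, length(tags_norm)))
  db_norm <- dna_norm(db_seqs)
  vapply(tags_norm, function(tg) {
    any(vapply(db_norm, function(db) {
      grepl(tg, db, fixed = TRUE)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Annotate tags by the priority rule
#'
#' Each tag is assigned the highest-priority class it qualifies for:
#' rRNAetc (GenBank before Rfam) > known miRNA > repeat > exon > intron;
#' tags qualifying for nothing fall into `unann`. Multi-hit tags are
#' classified by the best class over all their genome hits.
#'
#' @param tags a [tag_table()].
#' @param genome named character vector of chromosomes (used for interval
#'   classes; may be `NULL` if no interval tracks are supplied).
#' @param tracks a list of annotation tracks ([annotation_track()]) carrying
#'   interval classes `rRNAetc`, `repeat`, `exon`, `intron`.
#' @param known_mirna_db data.frame of known miRNAs with columns `id`,
#'   `sequence` (mature and/or precursor sequences).
#' @param structural_db data.frame of structural RNAs (rRNA/tRNA/snRNA/
#'   snoRNA) with columns `id`, `sequence`, `source` (`"GenBank"` or
#'   `"Rfam"`).
#' @param genome_hits optional precomputed [match_genome()] result.
#' @return list with `annotated` (tag table + `category`, `matched_source`,
#'   `n_genome_hits` columns) and `summary` (per-library unique/total counts
#'   and percentages per category, Table-1 style).
#' @export
annotate <- function(tags, genome = NULL, tracks = list(),
                     known_mirna_db = NULL, structural_db = NULL,
                     genome_hits = NULL) {
  libs <- tag_libraries(tags)
  norm <- dna_norm(tags$sequence)
  n <- nrow(tags)

  for (tr in tracks) {
    cls <- unique(S4Vectors::mcols(tr)$class)
    if (!all(cls %in% setdiff(ANNOTATION_CLASSES, c("miRNA", "unann"))))
      stopf("annotate: unknown class in track: %s",
            paste(setdiff(cls, ANNOTATION_CLASSES), collapse = ", "))
  }

  # sequence-database classes
  src <- rep("none", n)
  is_struct_gb <- is_struct_rf <- rep(FALSE, n)
  if (!is.null(structural_db) && nrow(structural_db)) {
    gb <- structural_db$sequence[structural_db$source == "GenBank"]
    rf <- structural_db$sequence[structural_db$source == "Rfam"]
    is_struct_gb <- matches_seq_db(norm, gb)
    is_struct_rf <- matches_seq_db(norm, rf)
  }
  is_mirna <- rep(FALSE, n)
  if (!is.null(known_mirna_db) && nrow(known_mirna_db))
    is_mirna <- matches_seq_db(norm, known_mirna_db$sequence)

  # genome hits + interval classes
  if (is.null(genome_hits))
    genome_hits <- if (is.null(genome)) {
      data.frame(sequence = character(), chrom = character(),
                 start = integer(), strand = character())
    } else match_genome(tags, genome)
  hit_counts <- table(factor(genome_hits$sequence, levels = tags$sequence))
  interval_class <- function(cls) {
    grs <- tracks[vapply(tracks, function(tr)
      any(S4Vectors::mcols(tr)$class == cls), logical(1))]
    out <- rep(FALSE, n)
    if (!length(grs) || !nrow(genome_hits)) return(out)
    track <- do.call(c, lapply(grs, function(tr)
      tr[S4Vectors::mcols(tr)$class == cls]))
    hg <- GenomicRanges::GRanges(
      genome_hits$chrom,
      IRanges::IRanges(genome_hits$start,
                       genome_hits$start + nchar(genome_hits$sequence) - 1L),
      strand = genome_hits$strand)
    ov <- GenomicRanges::findOverlaps(hg, track, minoverlap = 1L,
                                      ignore.strand = TRUE)
    hit_seqs <- unique(genome_hits$sequence[S4Vectors::queryHits(ov)])
    out[tags$sequence %in% hit_seqs] <- TRUE
    out
  }
  is_repeat <- interval_class("repeat")
  is_exon <- interval_class("exon")
  is_intron <- interval_class("intron")
  is_rrna_iv <- interval_class("rRNAetc")

  category <- rep("unann", n)
  category[is_intron] <- "intron"
  category[is_exon] <- "exon"
  category[is_repeat] <- "repeat"
  category[is_mirna] <- "miRNA"
  category[is_struct_rf | is_rrna_iv] <- "rRNAetc"
  category[is_struct_gb] <- "rRNAetc"
  src[is_mirna & category == "miRNA"] <- "miRBase"
  src[category == "rRNAetc"] <- "Rfam"
  src[is_struct_gb] <- "GenBank"  # GenBank outranks Rfam within rRNAetc
  src[category %in% c("repeat", "exon", "intron")] <- "user"

  ann <- as.data.frame(tags)
  ann$category <- factor(category, levels = ANNOTATION_CLASSES)
  ann$matched_source <- src
  ann$n_genome_hits <- as.integer(hit_counts)

  list(annotated = ann,
       summary = annotation_summary(ann, libs),
       genome_hits = genome_hits)
}

# Table-1 style bookkeeping: per library, unique and total counts (and
# percentages of clean reads) for clean reads, genome-matching reads and each
# category.
annotation_summary <- function(ann, libs) {
  cnt <- as.matrix(ann[, libs, drop = FALSE])
  rows <- list()
  add <- function(label, sel) {
    uniq <- colSums((cnt[sel, , drop = FALSE] > 0))
    tot <- colSums(cnt[sel, , drop = FALSE])
    rows[[length(rows) + 1]] <<- data.frame(
      category = label, library = libs,
      unique_reads = as.integer(uniq), total_reads = as.integer(tot),
      stringsAsFactors = FALSE)
  }
  add("clean", rep(TRUE, nrow(ann)))
  add("match_genome", ann$n_genome_hits > 0)
  for (cls in ANNOTATION_CLASSES) add(cls, ann$category == cls)
  out <- do.call(rbind, rows)
  clean <- out[out$category == "clean", ]
  i <- match(out$library, clean$library)
  out$unique_pct <- round_half_away(
    100 * out$unique_reads / pmax(clean$unique_reads[i], 1), 2)
  out$total_pct <- round_half_away(
    100 * out$total_reads / pmax(clean$total_reads[i], 1), 2)
  out
}

#' Length distribution of tags
#'
#' @param tags annotated tag data.frame (output of [annotate()]) or a plain
#'   [tag_table()] when `by = "all"`.
#' @param by `"all"` for all tags, `"miRNA"` for the miRNA category only.
#' @return data.frame `length`, `unique_reads`, `total_reads` over the
#'   observed lengths; totals conserve the selected input mass.
#' @export
length_distribution <- function(tags, by = c("all", "miRNA")) {
  by <- match.arg(by)
  df <- as.data.frame(tags)
  if (by == "miRNA") {
    if (!"category" %in% names(df))
      stopf("length_distribution: by='miRNA' requires annotated tags")
    df <- df[df$category == "miRNA", , drop = FALSE]
  }
  libs <- tag_libraries(tags)
  if (!nrow(df)) {
    return(data.frame(length = integer(), unique_reads = integer(),
                      total_reads = integer()))
  }
  len <- nchar(df$sequence)
  tot <- rowSums(df[, libs, drop = FALSE])
  agg <- stats::aggregate(cbind(unique_reads = 1, total_reads = tot),
                          by = list(length = len), sum)
  agg$unique_reads <- as.integer(agg$unique_reads)
  agg$total_reads <- as.integer(agg$total_reads)
  agg
}
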