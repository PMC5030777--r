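# Readers and writers for the formats the pipeline touches: FASTA, FASTQ,
# collapsed tag-count TSVs, annotation tracks, and the pipeline's own tabular
# artifacts. All TSV artifacts carry a single commented header line ("#...").

#' Read a FASTA file
#'
#' Line-based reader that preserves the input alphabet (U and T are both
#' accepted and kept as given, but sequences are uppercased) and reports
#' format errors with the offending line number. Order of records is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path)
  empty <- data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  # leading/trailing blank lines are tolerated
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(empty)
  ids <- character()
  descs <- character()
  seqs <- character()
  cur_seq <- NULL
  cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur_seq)) return(invisible())
    if (!nzchar(cur_seq))
      stopf("FASTA format error: empty sequence for record starting at line %d",
            cur_line)
    seqs[length(seqs) + 1] <<- cur_seq
  }
  for (i in nonblank) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush()
      header <- sub("^>", "", ln)
      if (!nzchar(trimws(header)))
        stopf("FASTA format error: empty header at line %d", i)
      toks <- strsplit(trimws(header), "\\s+")[[1]]
      ids[length(ids) + 1] <- toks[1]
      descs[length(descs) + 1] <-
        if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
      cur_seq <- ""
      cur_line <- i
    } else {
      if (is.null(cur_seq))
        stopf("FASTA format error: sequence data before any header at line %d", i)
      frag <- gsub("\\s", "", ln)
      if (grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv.-]", frag))
        stopf("FASTA format error: invalid sequence character at line %d", i)
      cur_seq <- paste0(cur_seq, toupper(frag))
    }
  }
  flush()
  data.frame(id = ids, description = descs, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' Canonical wrapping at a fixed line width so that read/write round-trips
#' are byte-identical for canonical files. The alphabet is written exactly
#' as stored (no U/T conversion).
#'
#' @param records data.frame with `id`, `sequence` and optionally
#'   `description` columns, or a named character vector of sequences.
#' @param path output path.
#' @param width sequence line width (default 60).
#' @export
write_fasta <- function(records, path, width = 60) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records), stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records)) records$description[k] else ""
    header <- if (nzchar(desc)) paste(records$id[k], desc) else records$id[k]
    writeLines(paste0(">", header), con)
    s <- records$sequence[k]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a tag table
#'
#' The atom of all small-RNA computation: one row per unique tag sequence
#' with a non-negative integer count for every declared library.
#'
#' @param sequence character vector of unique tag sequences.
#' @param counts data.frame or matrix of integer counts, one column per
#'   library.
#' @param libraries library names; defaults to the column names of `counts`.
#' @return a `tag_table` data.frame (`sequence` + one integer column per
#'   library) with a `libraries` attribute.
#' @export
tag_table <- function(sequence, counts, libraries = colnames(counts)) {
  counts <- as.data.frame(counts)
  if (is.null(libraries) || !length(libraries))
    stopf("tag_table: library names are required")
  colnames(counts) <- libraries
  if (length(sequence) != nrow(counts))
    stopf("tag_table: %d sequences but %d count rows",
          length(sequence), nrow(counts))
  for (lib in libraries) {
    v <- counts[[lib]]
    if (any(is.na(v)) || any(v < 0) || any(v != trunc(v)))
      stopf("tag_table: counts for library '%s' must be non-negative integers", lib)
    counts[[lib]] <- as.integer(v)
  }
  sequence <- toupper(sequence)
  if (anyDuplicated(sequence))
    stopf("tag_table: duplicated sequences; collapse before construction")
  out <- cbind(data.frame(sequence = sequence, stringsAsFactors = FALSE), counts)
  attr(out, "libraries") <- libraries
  class(out) <- c("tag_table", "data.frame")
  out
}

#' Library names of a tag table
#' @param tags a [tag_table()].
#' @return character vector of library names.
#' @export
tag_libraries <- function(tags) {
  libs <- attr(tags, "libraries")
  if (is.null(libs)) libs <- setdiff(colnames(tags), "sequence")
  libs
}

#' Count matrix of a tag table
#' @param tags a [tag_table()].
#' @return integer matrix, one column per library.
#' @export
tag_counts <- function(tags) {
  as.matrix(tags[, tag_libraries(tags), drop = FALSE])
}

#' Read a collapsed tag-count TSV
#'
#' Expected layout: a header line `sequence<TAB>lib1<TAB>...<TAB>libN`
#' (a leading `#` on the header is tolerated), then one row per tag.
#' Duplicate sequences are summed with a warning; negative or non-integer
#' counts are format errors.
#'
#' @param path TSV path.
#' @param libraries optional expected library names; an error is raised if
#'   the file header does not match.
#' @return a [tag_table()].
#' @export
read_tag_table <- function(path, libraries = NULL) {
  if (!file.exists(path)) stopf("tag table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- sub("^#\\s*", "", colnames(df)[1])
  if (colnames(df)[1] != "sequence")
    stopf("tag table format error: first column must be 'sequence', got '%s'",
          colnames(df)[1])
  file_libs <- colnames(df)[-1]
  if (!is.null(libraries) && !identical(file_libs, as.character(libraries)))
    stopf("tag table header mismatch: file has [%s], expected [%s]",
          paste(file_libs, collapse = ", "), paste(libraries, collapse = ", "))
  for (lib in file_libs) {
    v <- suppressWarnings(as.numeric(df[[lib]]))
    if (any(is.na(v)) || any(v < 0) || any(v != trunc(v)))
      stopf("tag table format error: non-integer or negative count in library '%s'",
            lib)
    df[[lib]] <- as.integer(v)
  }
  df$sequence <- toupper(df$sequence)
  if (anyDuplicated(df$sequence)) {
    warning("duplicate sequences in tag table; counts summed", call. = FALSE)
    agg <- stats::aggregate(df[file_libs], by = list(sequence = df$sequence), sum)
    df <- agg[match(unique(df$sequence), agg$sequence), , drop = FALSE]
  }
  tag_table(df$sequence, df[file_libs], file_libs)
}

#' Write a tag table as TSV
#'
#' @param tags a [tag_table()].
#' @param path output path.
#' @export
write_tag_table <- function(tags, path) {
  libs <- tag_libraries(tags)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#sequence\t", paste(libs, collapse = "\t")), con)
  utils::write.table(tags[, c("sequence", libs)], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse a FASTQ file into a single-library tag table
#'
#' Reads are collapsed case-insensitively (uppercased); the total of the
#' counts equals the number of FASTQ records. Quality strings are ignored
#' (inputs are assumed adapter- and quality-trimmed upstream).
#'
#' @param path FASTQ path.
#' @param library name for the single count column (default `"lib1"`).
#' @return a [tag_table()] with one count column.
#' @export
collapse_fastq <- function(path, library = "lib1") {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0))]
  if (length(lines) == 0) {
    cnts <- data.frame(x = integer(0))
    colnames(cnts) <- library
    return(tag_table(character(), cnts, library))
  }
  if (length(lines) %% 4 != 0)
    stopf("FASTQ format error: truncated record (%d lines, not a multiple of 4)",
          length(lines))
  idx <- seq(1, length(lines), by = 4)
  bad_at <- idx[!startsWith(lines[idx], "@")]
  if (length(bad_at))
    stopf("FASTQ format error: record header missing '@' at line %d", bad_at[1])
  bad_plus <- idx[!startsWith(lines[idx + 2], "+")]
  if (length(bad_plus))
    stopf("FASTQ format error: separator missing '+' at line %d", bad_plus[1] + 2)
  seqs <- toupper(lines[idx + 1])
  bad_len <- which(nchar(seqs) != nchar(lines[idx + 3]))
  if (length(bad_len))
    stopf("FASTQ format error: sequence/quality length mismatch at line %d",
          idx[bad_len[1]] + 1)
  tab <- table(seqs)
  cnts <- data.frame(as.integer(tab))
  colnames(cnts) <- library
  tag_table(names(tab), cnts, library)
}

#' Export T-plot data for one transcript/cleavage-site pair
#'
#' Writes the per-position degradome abundance profile with the predicted
#' cleavage site flagged, as TSV (position, abundance, is_predicted_site);
#' positions are 1-based transcript coordinates. This is the data behind a
#' T-plot; rendering is left to the user.
#'
#' @param site_profile a [degradome_profile()].
#' @param predicted_site 1-based transcript position of the predicted
#'   cleavage site.
#' @param path output TSV path.
#' @export
write_tplot_data <- function(site_profile, predicted_site, path) {
  stopifnot(inherits(site_profile, "degradome_profile"))
  ab <- site_profile$abundance
  if (length(ab) == 0) stopf("write_tplot_data: empty degradome profile")
  if (predicted_site < 1 || predicted_site > site_profile$length)
    stopf("write_tplot_data: predicted site %d outside transcript (length %d)",
          predicted_site, site_profile$length)
  pos <- sort(unique(c(as.integer(names(ab)), as.integer(predicted_site))))
  val <- ifelse(is.na(ab[as.character(pos)]), 0L, ab[as.character(pos)])
  out <- data.frame(position = pos, abundance = as.integer(val),
                    is_predicted_site = as.integer(pos == predicted_site))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#position\tabundance\tis_predicted_site", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an annotation track (BED or GFF3) as a classed interval set
#'
#' @param path BED or GFF3 file (format chosen by extension).
#' @param class interval class, one of `"rRNAetc"`, `"repeat"`, `"exon"`,
#'   `"intron"`.
#' @param source provenance label (`"GenBank"`, `"Rfam"` or `"user"`).
#' @return a `GRanges` with metadata columns `class` and `source`.
#' @export
read_annotation_track <- function(path, class, source = "user") {
  gr <- rtracklayer::import(path)
  annotation_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ), class = class, source = source)
}

#' Build an annotation track from a coordinate data.frame
#'
#' @param df data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and optionally `strand` columns.
#' @param class interval class from the closed vocabulary.
#' @param source provenance label.
#' @return a `GRanges` with `class` and `source` metadata columns.
#' @export
annotation_track <- function(df, class, source = "user") {
  classes <- c("rRNAetc", "repeat", "exon", "intron")
  if (!class %in% classes)
    stopf("annotation_track: unknown class '%s' (must be one of %s)",
          class, paste(classes, collapse = ", "))
  if (any(df$start > df$end))
    stopf("annotation_track: start > end")
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strand
  )
  S4Vectors::mcols(gr)$class <- class
  S4Vectors::mcols(gr)$source <- source
  gr
}

#' Write a report table as a '#'-headed TSV
#'
#' All tabular pipeline artifacts share this layout: a single commented
#' header line followed by tab-separated rows.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_report_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
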