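# RPM normalization, zero imputation, log2 fold changes, and a
# noise-distribution differential-expression test: within-group library
# pairs define an empirical (M, D) noise cloud (log2 ratio, absolute
# difference); a miRNA's between-group (M_A, D_A) point earns a probability
# equal to the fraction of noise points it strictly dominates on both axes.
# Significance: |M_A| >= 1.0 AND prob > 0.8.

#' Normalize raw counts to reads per million
#'
#' RPM = raw count / library total * 1e6. Library totals should be the total
#' raw counts of the library (all counted tags), not just the rows present.
#'
#' @param raw_counts numeric matrix (rows = miRNAs, columns = libraries).
#' @param library_totals named numeric vector of per-library total raw
#'   counts; defaults to the column sums.
#' @return RPM matrix of the same shape.
#' @export
normalize_rpm <- function(raw_counts, library_totals = colSums(raw_counts)) {
  raw_counts <- as.matrix(raw_counts)
  if (any(library_totals <= 0))
    stopf("normalize_rpm: library total must be > 0")
  sweep(raw_counts, 2, library_totals, "/") * 1e6
}

#' Impute exact zeros
#'
#' Replaces values that are exactly zero by `floor` (default 0.01); all other
#' values, however small, are untouched.
#'
#' @param matrix RPM matrix.
#' @param floor replacement for exact zeros.
#' @return imputed matrix.
#' @export
impute_zero <- function(matrix, floor = 0.01) {
  matrix[matrix == 0] <- floor
  matrix
}

#' Log2 fold change between genotypes
#'
#' M = log2(MT / WT), computed at full precision; report tables round to two
#' decimals half away from zero.
#'
#' @param mt_value,wt_value post-imputation expression values (> 0).
#' @return log2 ratio (unrounded).
#' @export
log2_fold_change <- function(mt_value, wt_value) {
  if (any(mt_value <= 0) || any(wt_value <= 0))
    stopf("log2_fold_change: inputs must be positive (impute zeros first)")
  log2(mt_value / wt_value)
}

#' Build the within-group noise model
#'
#' For every unordered pair of libraries inside a group and every miRNA,
#' contributes one noise point (M_n = log2 ratio, D_n = absolute
#' difference). Both groups contribute. The matrix must be imputed (no
#' zeros) so every ratio is finite.
#'
#' @param matrix imputed RPM matrix with library columns.
#' @param groups named list of library-name vectors.
#' @return data.frame `M`, `D` of noise points.
#' @export
build_noise_model <- function(matrix, groups) {
  if (!any(vapply(groups, length, integer(1)) >= 2))
    stopf("build_noise_model: no group has two libraries")
  if (any(matrix <= 0))
    stopf("build_noise_model: matrix contains non-positive values; impute first")
  pts <- list()
  for (g in names(groups)) {
    libs <- groups[[g]]
    if (length(libs) < 2) next
    for (i in seq_len(length(libs) - 1)) {
      for (j in seq(i + 1, length(libs))) {
        a <- matrix[, libs[i]]; b <- matrix[, libs[j]]
        pts[[length(pts) + 1]] <- data.frame(M = log2(a / b), D = abs(a - b))
      }
    }
  }
  noise <- do.call(rbind, pts)
  rownames(noise) <- NULL
  noise
}

#' Noise-distribution probability for one miRNA
#'
#' prob = fraction of noise points with |M_n| < |M_A| AND D_n < D_A
#' (strictly less on both axes).
#'
#' @param m_a,d_a the miRNA's between-group log2 ratio and absolute
#'   difference.
#' @param noise_model data.frame from [build_noise_model()].
#' @return probability in \[0, 1\].
#' @export
noiseq_prob <- function(m_a, d_a, noise_model) {
  if (is.null(noise_model) || !nrow(noise_model))
    stopf("noiseq_prob: empty noise model")
  mean(abs(noise_model$M) < abs(m_a) & noise_model$D < d_a)
}

#' Differential-expression analysis between two groups
#'
#' Runs the full chain on a raw count matrix: RPM normalization, zero
#' imputation, group averages, M/D statistics, noise-model probabilities and
#' the significance call.
#'
#' @param raw_counts matrix (rows = miRNAs, columns = libraries).
#' @param groups named list; the first element is the treatment (MT), the
#'   second the control (WT).
#' @param library_totals per-library totals for RPM (defaults to column
#'   sums).
#' @param floor zero-imputation floor.
#' @param m_threshold minimum |M| (default 1.0, inclusive).
#' @param prob_threshold minimum prob (default 0.8, exclusive).
#' @return data.frame: `miRNA`, `Control_avg`, `Treat_avg`, `M`, `D`,
#'   `prob`, `M_rounded`, `significant`.
#' @export
de_analysis <- function(raw_counts, groups,
                        library_totals = colSums(raw_counts), floor = 0.01,
                        m_threshold = 1.0, prob_threshold = 0.8) {
  rpm <- impute_zero(normalize_rpm(raw_counts, library_totals), floor)
  treat <- names(groups)[1]; control <- names(groups)[2]
  treat_avg <- rowMeans(rpm[, groups[[treat]], drop = FALSE])
  control_avg <- rowMeans(rpm[, groups[[control]], drop = FALSE])
  m <- log2_fold_change(treat_avg, control_avg)
  d <- abs(control_avg - treat_avg)
  noise <- build_noise_model(rpm, groups)
  prob <- vapply(seq_along(m), function(i) noiseq_prob(m[i], d[i], noise),
                 numeric(1))
  res <- data.frame(
    miRNA = if (is.null(rownames(raw_counts))) as.character(seq_along(m))
            else rownames(raw_counts),
    Control_avg = control_avg, Treat_avg = treat_avg,
    M = m, D = d, prob = prob,
    M_rounded = round_half_away(m, 2),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res$significant <- call_de(res$M, res$prob, m_threshold, prob_threshold)
  res
}

#' Significance rule
#'
#' significant iff |M| >= m_threshold (inclusive) AND prob > prob_threshold
#' (strict).
#'
#' @param m log2 fold changes.
#' @param prob noise-model probabilities.
#' @param m_threshold inclusive |M| cutoff (default 1.0).
#' @param prob_threshold exclusive prob cutoff (default 0.8).
#' @return logical vector.
#' @export
call_de <- function(m, prob, m_threshold = 1.0, prob_threshold = 0.8) {
  abs(m) >= m_threshold & prob > prob_threshold
}
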