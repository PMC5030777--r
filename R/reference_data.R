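# Access to the bundled reference expression table.

#' Reference miRNA expression table (MT vs WT sweet orange)
#'
#' Published per-miRNA mean RPM values, NOISeq probabilities and reported
#' log2(MT/WT) fold changes for the late-ripening sweet orange mutant (MT)
#' versus wild-type (WT) comparison. Used as the worked example for the
#' fold-change pipeline (impute exact zeros to 0.01, M = log2(MT/WT), round
#' to two decimals). The `consistent` flag marks rows whose reported fold
#' change is arithmetically consistent with their own RPM pair under that
#' pipeline; the remaining rows differ by one unit in the last printed
#' decimal.
#'
#' @return data.frame: `miRNA`, `status` (known/novel), `WT_RPM`, `MT_RPM`,
#'   `prob`, `log2fc_printed`, `consistent`.
#' @export
reference_expression_table <- function() {
  path <- system.file("extdata", "mirna_expression_reference.tsv",
                      package = "srnapipe")
  df <- utils::read.delim(path, header = TRUE, comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- sub("^#", "", colnames(df)[1])
  df$consistent <- df$consistent == 1
  df
}

#' Recompute fold changes for the reference table
#'
#' Applies the expression pipeline to the printed RPM pairs: impute exact
#' zeros to `floor`, M = log2(MT/WT), round half away from zero to 2
#' decimals; then applies the significance rule to the printed
#' probabilities.
#'
#' @param floor zero-imputation floor (default 0.01).
#' @return the reference table with `log2fc_recomputed` and `significant`
#'   columns added.
#' @export
recompute_reference_fold_changes <- function(floor = 0.01) {
  ref <- reference_expression_table()
  wt <- impute_zero(matrix(ref$WT_RPM), floor)[, 1]
  mt <- impute_zero(matrix(ref$MT_RPM), floor)[, 1]
  ref$log2fc_recomputed <- round_half_away(log2_fold_change(mt, wt), 2)
  ref$significant <- call_de(ref$log2fc_recomputed, ref$prob)
  ref
}
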