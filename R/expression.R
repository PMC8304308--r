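# Small expression utilities: RPKM, differential-expression threshold
# flags, Benjamini-Hochberg adjustment of supplied p-values, and relative
# qPCR quantification by the 2^-ddCt method.

#' Reads per kilobase of coding sequence per million mapped reads
#'
#' `count / (cds_length_bp / 1000) / (mapped_reads / 1e6)`.
#'
#' @param count Non-negative read count (vectorised).
#' @param cds_length_bp Coding-sequence length in bp (> 0).
#' @param mapped_reads Library size in mapped reads (> 0).
#' @return RPKM values; 0 exactly where `count` is 0.
#' @examples
#' rpkm(10, 1000, 1e6)   # 10
#' rpkm(100, 2000, 2e6)  # 25
#' @export
rpkm <- function(count, cds_length_bp, mapped_reads) {
  if (any(cds_length_bp <= 0)) stop("'cds_length_bp' must be > 0", call. = FALSE)
  if (any(mapped_reads <= 0)) stop("'mapped_reads' must be > 0", call. = FALSE)
  if (any(count < 0)) stop("'count' must be non-negative", call. = FALSE)
  count / (cds_length_bp / 1000) / (mapped_reads / 1e6)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` so the
#' differential-expression filter is self-contained when the input carries
#' raw p-values only.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted values, monotone in the p-value ranks, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Flag differentially expressed genes by FDR and fold-change thresholds
#'
#' A gene is `up` when `log2fc >= lfc_min` and `fdr <= fdr_max`, `down` when
#' `log2fc <= -lfc_min` and `fdr <= fdr_max`, otherwise `not_significant`.
#' Boundary values are inclusive. When the table has no `fdr` column it is
#' derived from `pvalue` by [bh_adjust()].
#'
#' @param records Data frame with `gene_id`, `log2fc`, `pvalue` and
#'   optionally `fdr`.
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param fdr_max Maximum FDR (default 0.001).
#' @return The input with `fdr` (if derived) and `flag` columns.
#' @export
deg_filter <- function(records, lfc_min = 1, fdr_max = 0.001) {
  if (!"fdr" %in% names(records)) {
    records$fdr <- bh_adjust(records$pvalue)
  }
  sig <- !is.na(records$fdr) & records$fdr <= fdr_max
  records$flag <- "not_significant"
  records$flag[sig & records$log2fc >= lfc_min] <- "up"
  records$flag[sig & records$log2fc <= -lfc_min] <- "down"
  records
}

#' Relative expression by the 2^-ddCt method
#'
#' `2 ^ -((Ct_target,s - Ct_ref,s) - (Ct_target,c - Ct_ref,c))`, the
#' expression of a target gene relative to a reference gene, normalised to a
#' calibrator sample.
#'
#' @param target_ct,ref_ct Ct of the target and reference gene in the
#'   sample(s) of interest (vectorised).
#' @param calibrator_target_ct,calibrator_ref_ct Ct of target and reference
#'   gene in the calibrator sample.
#' @return Relative expression; 1 when the sample equals the calibrator.
#' @examples
#' ddct(12, 10, 14, 10)  # sample dCt 2, calibrator dCt 4 -> 4
#' @export
ddct <- function(target_ct, ref_ct, calibrator_target_ct, calibrator_ref_ct) {
  cts <- c(target_ct, ref_ct, calibrator_target_ct, calibrator_ref_ct)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("Ct values must be finite and positive (is the calibrator missing?)",
         call. = FALSE)
  }
  2^-((target_ct - ref_ct) - (calibrator_target_ct - calibrator_ref_ct))
}
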