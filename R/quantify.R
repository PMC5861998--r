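# Small quantification utilities: gene-level fold changes on count
# matrices, qPCR relative quantification, and the GC-vs-induction rank
# correlation.

#' Per-gene transcript fold changes between conditions
#'
#' Simple fold-change plumbing for synthetic count matrices: median-of-ratios
#' size factors, fold change of normalized condition means versus the
#' control, a Wald-style p-value from a two-sample t statistic on log2
#' normalized counts, and Benjamini-Hochberg FDR. Genes averaging at most
#' `min_control_count` raw fragments in the control condition are removed;
#' all-zero rows are dropped with a warning.
#'
#' @param counts numeric matrix (genes x samples) with row names.
#' @param conditions condition label per column; first factor level is the
#'   control.
#' @param fc_threshold fold-change magnitude for the `changed` flag
#'   (default 1.5).
#' @param fdr_threshold FDR for the `changed` flag (default 0.1).
#' @param decrease_threshold fraction of control defining the `decreased`
#'   flag (default 0.67).
#' @param min_control_count genes with mean control counts at or below this
#'   are removed (default 7).
#' @return data.frame with gene, base_mean, fold_change, log2_fold_change,
#'   p, fdr, changed, decreased.
#' @export
transcript_foldchange <- function(counts, conditions, fc_threshold = 1.5,
                                  fdr_threshold = 0.1,
                                  decrease_threshold = 0.67,
                                  min_control_count = 7) {
  counts <- as.matrix(counts)
  conditions <- as.factor(conditions)
  if (nlevels(conditions) < 2L) stop("need >= 2 conditions")
  if (any(table(conditions) < 2L)) stop("need >= 2 replicates per condition")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero gene rows", sum(zero)))
    counts <- counts[!zero, , drop = FALSE]
  }
  # median-of-ratios size factors over genes positive in all samples
  logmeans <- rowMeans(log(counts))
  usable <- is.finite(logmeans)
  if (!any(usable)) stop("no gene is positive in all samples; cannot size-normalize")
  sf <- apply(counts, 2L, function(col) {
    exp(stats::median(log(col[usable]) - logmeans[usable]))
  })
  norm <- sweep(counts, 2L, sf, "/")
  ctrl <- conditions == levels(conditions)[1L]
  keep <- rowMeans(counts[, ctrl, drop = FALSE]) > min_control_count
  norm <- norm[keep, , drop = FALSE]
  m_ctrl <- rowMeans(norm[, ctrl, drop = FALSE])
  m_trt <- rowMeans(norm[, !ctrl, drop = FALSE])
  fc <- (m_trt + 0.5) / (m_ctrl + 0.5)
  lx <- log2(norm + 0.5)
  p <- vapply(seq_len(nrow(lx)), function(i) {
    a <- lx[i, !ctrl]; b <- lx[i, ctrl]
    d <- mean(a) - mean(b)
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (se == 0) return(if (d == 0) 1 else 0)
    2 * stats::pnorm(-abs(d / se))
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(norm), base_mean = rowMeans(norm),
             fold_change = unname(fc), log2_fold_change = unname(log2(fc)),
             p = p, fdr = fdr,
             changed = (fc >= fc_threshold | fc <= 1 / fc_threshold) &
                       fdr <= fdr_threshold,
             decreased = fc < decrease_threshold,
             row.names = NULL)
}

#' Relative transcript quantification by the 2^-ddCt method
#'
#' Fold change of a target transcript in a treated sample relative to a
#' control, each normalized to a reference transcript:
#' `2^-((Ct_target_treated - Ct_ref_treated) - (Ct_target_control - Ct_ref_control))`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   threshold cycles (finite numerics, vectorized).
#' @return Fold change (1 = unchanged).
#' @examples
#' ddct_foldchange(20, 15, 22, 15)  # 4
#' @export
ddct_foldchange <- function(ct_target_treated, ct_ref_treated,
                            ct_target_control, ct_ref_control) {
  stopifnot(all(is.finite(c(ct_target_treated, ct_ref_treated,
                            ct_target_control, ct_ref_control))))
  2^-((ct_target_treated - ct_ref_treated) -
        (ct_target_control - ct_ref_control))
}

#' Rank correlation between MO GC content and immune-gene induction
#'
#' Spearman correlation between the GC contents of injected MOs and the
#' fold induction of an immune-response gene; the p-value is exact for small
#' n without ties.
#'
#' @param gc_percents numeric, GC content in percent.
#' @param induction_folds numeric, induction fold changes; same length.
#' @return List with `rho`, `p`, `n`, and `degenerate` (TRUE when an input
#'   is constant and rho is undefined).
#' @export
gc_induction_correlation <- function(gc_percents, induction_folds) {
  if (length(gc_percents) != length(induction_folds) || length(gc_percents) < 3L) {
    stop("need >= 3 paired observations")
  }
  if (stats::sd(gc_percents) == 0 || stats::sd(induction_folds) == 0) {
    warning("constant input: rank correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(gc_percents),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(gc_percents, induction_folds,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(gc_percents),
       degenerate = FALSE)
}
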