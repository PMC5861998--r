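# Library-size normalization for split-read count matrices: counts per
# million and trimmed-mean-of-M-values (TMM) scaling factors.

#' Counts per million
#' @param counts numeric matrix (features x samples).
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return CPM matrix of the same dimensions.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' CPM expression filter
#'
#' Flags features whose mean counts-per-million across samples exceeds
#' `min_cpm` (default: more than one count per million).
#'
#' @inheritParams cpm
#' @param min_cpm CPM threshold (default 1).
#' @return Logical vector, one entry per row of `counts`.
#' @export
cpm_filter <- function(counts, min_cpm = 1, lib_sizes = colSums(counts)) {
  rowMeans(cpm(counts, lib_sizes)) > min_cpm
}

# Upper-quartile of nonzero-scaled counts, used to pick the TMM reference.
.uq <- function(x, lib) stats::quantile(x / lib, p = 0.75, names = FALSE)

.tmm_pair <- function(obs, ref, nO, nR, logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref  # delta-method weight
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1;     hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Compositional normalization for count libraries: per-sample scaling
#' factors from the doubly trimmed (30% on M-values, 5% on A-values),
#' precision-weighted mean of log ratios against a reference sample. The
#' reference is the sample whose upper quartile of scaled counts is closest
#' to the mean upper quartile. Factors are normalized to geometric mean 1.
#'
#' @param counts numeric matrix (features x samples).
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @param logratio_trim,sum_trim trim fractions for M- and A-values.
#' @return Numeric vector of scaling factors, one per sample.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) stop("all-zero sample")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  f75 <- vapply(seq_len(ncol(counts)), function(j) .uq(counts[, j], lib_sizes[j]),
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) 1 else .tmm_pair(counts[, j], counts[, ref],
                                   lib_sizes[j], lib_sizes[ref],
                                   logratio_trim, sum_trim)
  }, numeric(1))
  f / exp(mean(log(f)))
}
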