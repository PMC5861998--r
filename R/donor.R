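# Donor splice-site consensus: position weight matrix over a 9-base window
# spanning the exon|intron boundary (positions -3..+6), built from junction
# flank sequences weighted by split-read support.

IUPAC_AMBIGUITY <- c(A = "A", C = "C", G = "G", T = "T",
                     AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                     ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Build a donor splice-site position weight matrix
#'
#' Columns are support-weighted base frequencies over the contributing donor
#' windows; windows with fewer supporting split reads than `min_support` are
#' excluded. The consensus is the per-column argmax base, with ties collapsed
#' to the IUPAC ambiguity letter.
#'
#' @param windows character vector of equal-width donor windows (default
#'   convention: 9-mers, exon positions -3..-1 then intron +1..+6).
#' @param support integer vector of split-read support per window (recycled
#'   to 1 if missing).
#' @param min_support minimum split-read support for a window to contribute
#'   (default 10).
#' @return Object of class `donor_pwm`: list with `width`,
#'   `column_probabilities` (4 x width matrix, rows A/C/G/T), `support`
#'   (total contributing junctions), `consensus`.
#' @examples
#' pwm <- build_donor_pwm(c("CAGGTAAGT", "AAGGTAAGT"), support = c(30, 10))
#' pwm$consensus
#' @export
build_donor_pwm <- function(windows, support = NULL, min_support = 10L) {
  if (is.null(support)) support <- rep(1L, length(windows))
  if (length(support) != length(windows)) stop("support length must match windows")
  if (any(support < 0)) stop("support counts must be >= 0")
  windows <- toupper(windows)
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop("all windows must have the same width")
  keep <- support >= min_support
  if (!any(keep)) stop("no junctions pass support threshold")
  windows <- windows[keep]; support <- support[keep]
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  mat[mat == "U"] <- "T"
  probs <- vapply(seq_len(w), function(j) {
    cnt <- vapply(c("A", "C", "G", "T"),
                  function(b) sum(support[mat[, j] == b]), numeric(1))
    cnt / sum(support)
  }, numeric(4))
  rownames(probs) <- c("A", "C", "G", "T")
  consensus <- paste(vapply(seq_len(w), function(j) {
    p <- probs[, j]
    top <- sort(names(p)[p == max(p)])
    unname(IUPAC_AMBIGUITY[paste(top, collapse = "")])
  }, ""), collapse = "")
  structure(list(width = w, column_probabilities = probs,
                 support = length(windows), consensus = consensus),
            class = "donor_pwm")
}

#' @export
print.donor_pwm <- function(x, ...) {
  cat(sprintf("<donor_pwm> width %d, %d contributing windows, consensus %s\n",
              x$width, x$support, x$consensus))
  print(round(x$column_probabilities, 3))
  invisible(x)
}

#' Canonical vertebrate donor splice-site consensus
#'
#' The most frequently encountered donor motif at exon|intron boundaries,
#' written on the sense strand in exon(-3..-1)|intron(+1..+6) orientation.
#'
#' @param as (`"DNA"` or `"RNA"`) alphabet of the returned string.
#' @return Character scalar, default `"CAGGTAAGT"`.
#' @export
donor_consensus <- function(as = c("DNA", "RNA")) {
  as <- match.arg(as)
  if (as == "RNA") "CAGGUAAGU" else "CAGGTAAGT"
}

#' Longest run of consecutive bases by which an MO pairs a donor consensus
#'
#' The MO "matches" the donor site by base-pairing the sense-strand motif
#' (treated as RNA, since the MO hybridizes pre-mRNA): this is the longest
#' Watson-Crick complementary run between the MO and the consensus.
#'
#' @param mo an [oligo] with role `"MO"`.
#' @param consensus sense-strand donor motif string (exon|intron orientation).
#' @return Integer run length.
#' @examples
#' mo_consensus_match(study_morpholinos()$cMO)  # 7
#' @export
mo_consensus_match <- function(mo, consensus = donor_consensus("RNA")) {
  rna <- chartr("T", "U", toupper(consensus))
  longest_complementary_run(mo, oligo(rna, role = "RNA"),
                            allow_wobble = FALSE)$length
}
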