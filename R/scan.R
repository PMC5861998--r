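# Ungapped antiparallel complementarity scanning between a morpholino and
# target RNA/DNA. A duplex "run" is a stretch of consecutive paired bases
# when the MO (5'->3') is laid antiparallel against the target (5'->3').
# Watson-Crick pairs: MO A : target U/T, T:A, G:C, C:G. Wobble pairing adds
# MO G : target U/T and MO T : target G (guanine pairing thymine or uracil
# in either orientation of the duplex).

.pair_table <- function(allow_wobble) {
  tb <- matrix(FALSE, nrow = 4, ncol = 5,
               dimnames = list(c("A", "C", "G", "T"),
                               c("A", "C", "G", "T", "U")))
  tb["A", c("T", "U")] <- TRUE
  tb["T", "A"] <- TRUE
  tb["G", "C"] <- TRUE
  tb["C", "G"] <- TRUE
  if (allow_wobble) {
    tb["G", c("T", "U")] <- TRUE
    tb["T", "G"] <- TRUE
  }
  tb
}

# All maximal complementary runs of length >= min_len between mo and target.
# Runs live on diagonals of the (reversed MO) x target pairing matrix; a run
# is maximal when bounded by a non-pairing position or a sequence end.
# Returns 0-based target_start and mo_offset (on the MO read 5'->3').
.maximal_runs <- function(mo, target, allow_wobble = FALSE, min_len = 1L) {
  tb <- .pair_table(allow_wobble)
  mor <- rev(mo$residues)
  tg <- target$residues
  m <- length(mor); n <- length(tg)
  ndiag <- n + m - 1L               # diagonals indexed by d = q - p
  run <- integer(ndiag)
  out_d <- integer(0); out_pend <- integer(0); out_len <- integer(0)
  d_all <- seq.int(1L - m, n - 1L)
  for (p in seq_len(m)) {
    q <- p + d_all
    ok <- q >= 1L & q <= n
    okp <- logical(ndiag)
    okp[ok] <- tb[cbind(mor[p], tg[q[ok]])]
    ended <- !okp & run >= min_len
    if (any(ended)) {
      out_d <- c(out_d, d_all[ended])
      out_pend <- c(out_pend, rep.int(p - 1L, sum(ended)))
      out_len <- c(out_len, run[ended])
    }
    run <- ifelse(okp, run + 1L, 0L)
  }
  open <- run >= min_len
  if (any(open)) {
    out_d <- c(out_d, d_all[open])
    out_pend <- c(out_pend, rep.int(m, sum(open)))
    out_len <- c(out_len, run[open])
  }
  data.frame(
    target_start = out_pend + out_d - out_len,   # 0-based
    length = out_len,
    mo_offset = m - out_pend,                    # 0-based on the MO 5'->3'
    diag = out_d,
    p_end = out_pend
  )
}

#' Longest consecutive complementary run between an MO and a target
#'
#' Maximal antiparallel ungapped duplex run length over all alignments of the
#' MO against the target. With `allow_wobble`, G:U (and G:T / T:G) wobble
#' pairs also count as paired. Ties are broken by the smallest target offset,
#' then the smallest MO offset.
#'
#' @param mo an [oligo] with role `"MO"` (character input is accepted).
#' @param target an [oligo] with role `"RNA"` or `"DNA"`.
#' @param allow_wobble logical; count wobble pairs in the run.
#' @return List with `length` (bases; 0 if no base pairs at all),
#'   `mo_offset`, and `target_offset` (both 0-based).
#' @examples
#' mos <- study_morpholinos(); rna <- study_rna_oligos()
#' longest_complementary_run(mos$t_splice, rna$t_target)$length       # 25
#' longest_complementary_run(mos$t_splice, rna$dtymk_offtarget)$length # 8
#' @export
longest_complementary_run <- function(mo, target, allow_wobble = FALSE) {
  mo <- as_oligo(mo, "MO")
  if (!inherits(target, "oligo")) {
    role <- if (grepl("U", toupper(paste(target, collapse = "")))) "RNA" else "DNA"
    target <- as_oligo(target, role)
  }
  if (mo$length == 0L || target$length == 0L) stop("empty sequence")
  runs <- .maximal_runs(mo, target, allow_wobble = allow_wobble, min_len = 1L)
  if (nrow(runs) == 0L) {
    return(list(length = 0L, mo_offset = NA_integer_, target_offset = NA_integer_))
  }
  runs <- runs[order(-runs$length, runs$target_start, runs$mo_offset), ]
  list(length = runs$length[1L], mo_offset = runs$mo_offset[1L],
       target_offset = runs$target_start[1L])
}

# Wobble extension of one Watson-Crick run: maximal wobble-allowed run on the
# same alignment diagonal containing the WC run.
.wobble_extend <- function(mo, target, diag, p_start, p_end) {
  tb <- .pair_table(allow_wobble = TRUE)
  mor <- rev(mo$residues); tg <- target$residues
  m <- length(mor); n <- length(tg)
  lo <- p_start
  while (lo > 1L) {
    q <- lo - 1L + diag
    if (q < 1L || q > n || !tb[mor[lo - 1L], tg[q]]) break
    lo <- lo - 1L
  }
  hi <- p_end
  while (hi < m) {
    q <- hi + 1L + diag
    if (q < 1L || q > n || !tb[mor[hi + 1L], tg[q]]) break
    hi <- hi + 1L
  }
  hi - lo + 1L
}

.scan_one_strand <- function(mo, target, min_run) {
  runs <- .maximal_runs(mo, target, allow_wobble = FALSE, min_len = min_run)
  if (nrow(runs) == 0L) return(runs[, c("target_start", "length", "mo_offset"), drop = FALSE])
  runs$wobble <- vapply(seq_len(nrow(runs)), function(i) {
    .wobble_extend(mo, target, runs$diag[i],
                   runs$p_end[i] - runs$length[i] + 1L, runs$p_end[i])
  }, integer(1))
  runs
}

# Merge hits whose target intervals overlap (same strand): keep the longest
# run per overlap family; ties by smallest start, then smallest mo_offset.
.merge_overlapping <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$target_start, -df$length, df$mo_offset), ]
  fam_end <- -1L
  fams <- integer(nrow(df)); fam_id <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$target_start[i] >= fam_end) fam_id <- fam_id + 1L
    fams[i] <- fam_id
    fam_end <- max(fam_end, df$target_start[i] + df$length[i])
  }
  picked <- vapply(split(seq_len(nrow(df)), fams), function(idx) {
    sub <- df[idx, ]
    idx[order(-sub$length, sub$target_start, sub$mo_offset)][1L]
  }, integer(1))
  df[sort(picked), ]
}

#' Scan a sequence collection for MO off-target complementarity
#'
#' Records every maximal run of at least `min_run` consecutive Watson-Crick
#' complementary bases between the MO and each target. In `transcriptome`
#' mode only the orientation in which the MO is antisense to the transcript
#' sense sequence is scanned; in `genome` mode both strands are scanned.
#' The wobble-extended run length (same alignment frame, G:U/T:G pairs
#' allowed) is reported alongside but never used for thresholding.
#' Overlapping runs on a target are merged, keeping the maximal one.
#'
#' @param mo an [oligo] with role `"MO"`.
#' @param targets named list of [oligo] objects (or character vector).
#' @param min_run minimum Watson-Crick run length to report (default 8).
#' @param mode `"transcriptome"` or `"genome"`.
#' @return A data.frame of hits with columns `mo_name`, `target_id`,
#'   `target_strand`, `run_start` (0-based on the sense sequence),
#'   `run_length`, `wobble_run_length`, `mo_offset`,
#'   `distance_to_splice_site` (NA until [annotate_hit_distances]),
#'   `within_window`; sorted by `target_id` then `run_start`.
#' @export
scan_for_offtargets <- function(mo, targets, min_run = 8L,
                                mode = c("transcriptome", "genome")) {
  mode <- match.arg(mode)
  mo <- as_oligo(mo, "MO")
  if (min_run < 4L) stop("min_run must be >= 4")
  if (length(targets) == 0L) stop("targets must be non-empty")
  if (is.character(targets)) {
    nm <- names(targets)
    if (is.null(nm)) nm <- paste0("target_", seq_along(targets))
    targets <- mapply(function(s, n) {
      role <- if (grepl("U", toupper(s))) "RNA" else "DNA"
      tryCatch(oligo(s, role = role, name = n),
               error = function(e) stop(sprintf("target '%s': %s", n, conditionMessage(e))))
    }, targets, nm, SIMPLIFY = FALSE)
  }
  ids <- unname(vapply(targets, function(t) t$name, ""))
  ids[!nzchar(ids)] <- names(targets)[!nzchar(ids)]

  res <- lapply(seq_along(targets), function(i) {
    tg <- targets[[i]]
    fwd <- .scan_one_strand(mo, tg, min_run)
    frames <- list()
    if (nrow(fwd) > 0L) {
      frames$fwd <- data.frame(target_id = ids[i], target_strand = "+",
                               run_start = fwd$target_start,
                               run_length = fwd$length,
                               wobble_run_length = fwd$wobble,
                               mo_offset = fwd$mo_offset)
    }
    if (mode == "genome") {
      rc <- reverse_complement(tg, output_role = "DNA")
      rev <- .scan_one_strand(mo, rc, min_run)
      if (nrow(rev) > 0L) {
        frames$rev <- data.frame(target_id = ids[i], target_strand = "-",
                                 run_start = tg$length - rev$target_start - rev$length,
                                 run_length = rev$length,
                                 wobble_run_length = rev$wobble,
                                 mo_offset = rev$mo_offset)
      }
    }
    if (length(frames) == 0L) return(NULL)
    do.call(rbind, lapply(frames, function(f) {
      f2 <- .merge_overlapping(data.frame(target_start = f$run_start,
                                          length = f$run_length,
                                          mo_offset = f$mo_offset,
                                          wobble = f$wobble_run_length))
      data.frame(target_id = f$target_id[1L], target_strand = f$target_strand[1L],
                 run_start = f2$target_start, run_length = f2$length,
                 wobble_run_length = f2$wobble, mo_offset = f2$mo_offset)
    }))
  })
  res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(target_id = character(0), target_strand = character(0),
                      run_start = integer(0), run_length = integer(0),
                      wobble_run_length = integer(0), mo_offset = integer(0))
  }
  res <- cbind(mo_name = rep(mo$name, nrow(res)), res)
  res$distance_to_splice_site <- rep(NA_integer_, nrow(res))
  res$within_window <- rep(NA, nrow(res))
  rownames(res) <- NULL
  res[order(res$target_id, res$run_start), , drop = FALSE]
}

#' Annotate hits with the distance to the nearest splice site
#'
#' For each hit, computes the gap (in bp) between the run interval
#' `[run_start, run_start + run_length)` and the nearest splice-site
#' position, 0 when the site falls inside the run. Hits farther than
#' `window` are flagged (`within_window = FALSE`) but never removed, so
#' callers decide how to filter.
#'
#' @param hits data.frame from [scan_for_offtargets].
#' @param splice_sites numeric vector of 0-based positions (applied to every
#'   target), or a named list of such vectors keyed by `target_id`.
#' @param window distance threshold in bp used for the flag (default 75).
#' @return `hits` with `distance_to_splice_site` and `within_window` filled.
#' @export
annotate_hit_distances <- function(hits, splice_sites, window = 75L) {
  if (nrow(hits) == 0L) return(hits)
  site_for <- function(id) {
    if (is.list(splice_sites)) splice_sites[[id]] else splice_sites
  }
  for (i in seq_len(nrow(hits))) {
    ss <- site_for(hits$target_id[i])
    if (is.null(ss) || length(ss) == 0L) {
      hits$distance_to_splice_site[i] <- NA_integer_
      hits$within_window[i] <- NA
      next
    }
    s0 <- hits$run_start[i]; s1 <- s0 + hits$run_length[i]
    d <- ifelse(ss < s0, s0 - ss, ifelse(ss >= s1, ss - s1, 0L))
    hits$distance_to_splice_site[i] <- min(d)
    hits$within_window[i] <- min(d) <= window
  }
  hits
}

#' Export hits as BED6 and companion TSV
#'
#' BED6 columns: target_id, run_start, run_end, mo_name, run_length, strand.
#' The TSV adds wobble run length and splice-site distance.
#'
#' @param hits annotated hits data.frame.
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @return Invisibly, a list of the paths written.
#' @export
export_hits <- function(hits, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(hits$target_id, hits$run_start,
                      hits$run_start + hits$run_length, hits$mo_name,
                      hits$run_length, hits$target_strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(hits, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}
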