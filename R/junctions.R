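# Split-read splice-junction tables and annotation-free intron clustering.
# Internally all intron coordinates are 0-based, half-open [start, end).
# A junction table is a data.frame with columns contig, start, end, strand
# followed by one non-negative integer count column per sample.

JUNCTION_META <- c("contig", "start", "end", "strand")

#' Extract the per-sample count matrix of a junction table
#' @param junctions junction data.frame.
#' @return Numeric matrix (junctions x samples).
#' @export
junction_counts <- function(junctions) {
  cols <- setdiff(colnames(junctions), c(JUNCTION_META, "cluster_id", "testable"))
  as.matrix(junctions[, cols, drop = FALSE])
}

#' Canonical junction identifiers (contig:start:end:strand)
#' @param junctions junction data.frame.
#' @return Character vector of ids.
#' @export
junction_id <- function(junctions) {
  paste(junctions$contig, junctions$start, junctions$end, junctions$strand,
        sep = ":")
}

#' Read a split-read junction count table
#'
#' Two dialects are supported. `star_sj` follows the STAR `SJ.out.tab`
#' convention: 1-based inclusive intron coordinates and a strand code
#' (0 = undefined, 1 = `+`, 2 = `-`); coordinates are converted to the
#' internal 0-based half-open convention. `bed_counts` carries 0-based
#' half-open coordinates and literal `+`/`-`/`?` strands. In both dialects
#' the first four columns are contig, start, end, strand and every remaining
#' column is a per-sample count. Duplicate records for the same junction are
#' merged by summing counts.
#'
#' @param path TSV file path (no header unless `header = TRUE`).
#' @param dialect `"star_sj"` or `"bed_counts"`.
#' @param sample_names optional names for the count columns.
#' @param header logical; does the file carry a header line.
#' @return Junction data.frame in internal convention, deterministically
#'   ordered by contig, start, end, strand.
#' @export
read_junction_table <- function(path, dialect = c("star_sj", "bed_counts"),
                                sample_names = NULL, header = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = header,
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(tab) || nrow(tab) == 0L) {
    warning("empty junction table: ", path)
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
    return(out)
  }
  if (ncol(tab) < 5L) stop("junction table needs >= 5 columns (4 meta + counts)")
  counts <- tab[, -(1:4), drop = FALSE]
  for (j in seq_len(ncol(counts))) {
    v <- suppressWarnings(as.numeric(counts[, j]))
    if (anyNA(v)) stop(sprintf("malformed count at line %d, column %d",
                               which(is.na(v))[1L], j + 4L))
    if (any(v < 0)) stop(sprintf("negative count at line %d", which(v < 0)[1L]))
    counts[, j] <- v
  }
  if (is.null(sample_names)) sample_names <- paste0("sample_", seq_len(ncol(counts)))
  colnames(counts) <- sample_names
  start <- suppressWarnings(as.integer(tab[, 2L]))
  end <- suppressWarnings(as.integer(tab[, 3L]))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed coordinate at line %d",
                 which(is.na(start) | is.na(end))[1L]))
  }
  if (dialect == "star_sj") {
    start <- start - 1L                       # 1-based inclusive -> 0-based half-open
    strand <- c("?", "+", "-")[as.integer(tab[, 4L]) + 1L]
  } else {
    strand <- as.character(tab[, 4L])
    strand[!(strand %in% c("+", "-"))] <- "?"
  }
  if (any(end <= start)) {
    stop(sprintf("intron end <= start at line %d", which(end <= start)[1L]))
  }
  out <- cbind(data.frame(contig = as.character(tab[, 1L]), start = start,
                          end = end, strand = strand), counts)
  key <- junction_id(out)
  if (anyDuplicated(key)) {
    cnt <- rowsum(junction_counts(out), key)
    meta <- out[!duplicated(key), JUNCTION_META]
    out <- cbind(meta, cnt[match(key[!duplicated(key)], rownames(cnt)), ,
                           drop = FALSE])
  }
  out <- out[order(out$contig, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Write a junction table in the bed_counts dialect
#' @param junctions junction data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(junctions, path) {
  cols <- c(JUNCTION_META,
            setdiff(colnames(junctions), c(JUNCTION_META, "cluster_id", "testable")))
  utils::write.table(junctions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Cluster introns by shared donor or acceptor coordinates
#'
#' Builds connected components of junctions that share a boundary coordinate
#' (either end) on the same contig and strand, after removing introns longer
#' than `max_intron_len`. Clusters whose total split reads (summed over all
#' samples and member junctions) fall below `min_cluster_reads` are dropped.
#' Cluster ids are assigned deterministically by (contig, leftmost
#' coordinate).
#'
#' @param junctions junction data.frame (see [read_junction_table]).
#' @param min_cluster_reads minimum total reads per cluster (default 7).
#' @param max_intron_len maximum intron length in bp (default 500000).
#' @return The junction data.frame restricted to clustered junctions, with a
#'   `cluster_id` column (`clu_1`, `clu_2`, ...).
#' @export
cluster_introns <- function(junctions, min_cluster_reads = 7L,
                            max_intron_len = 500000L) {
  if (nrow(junctions) == 0L) {
    junctions$cluster_id <- character(0)
    return(junctions)
  }
  junctions <- junctions[junctions$end - junctions$start <= max_intron_len, ,
                         drop = FALSE]
  if (nrow(junctions) == 0L) {
    junctions$cluster_id <- character(0)
    return(junctions)
  }
  # union-find over shared boundary coordinates within contig+strand
  n <- nrow(junctions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  keyL <- paste(junctions$contig, junctions$strand, junctions$start)
  keyR <- paste(junctions$contig, junctions$strand, junctions$end)
  for (grp in c(split(seq_len(n), keyL), split(seq_len(n), keyR))) {
    if (length(grp) > 1L) for (i in grp[-1L]) union2(grp[1L], i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  totals <- rowSums(junction_counts(junctions))
  comp_total <- tapply(totals, comp, sum)
  keep_comp <- names(comp_total)[comp_total >= min_cluster_reads]
  keep <- as.character(comp) %in% keep_comp
  junctions <- junctions[keep, , drop = FALSE]
  comp <- comp[keep]
  # deterministic ids ordered by (contig, leftmost coordinate), with strand
  # and leftmost end breaking ties between coincident clusters
  key <- do.call(rbind, lapply(split(seq_along(comp), comp), function(ix) {
    st <- min(junctions$start[ix])
    data.frame(contig = junctions$contig[ix[1L]], start = st,
               end = min(junctions$end[ix][junctions$start[ix] == st]),
               strand = junctions$strand[ix[1L]])
  }))
  ord <- order(key$contig, key$start, key$end, key$strand)
  id_map <- stats::setNames(paste0("clu_", seq_along(ord)), rownames(key)[ord])
  junctions$cluster_id <- unname(id_map[as.character(comp)])
  junctions <- junctions[order(junctions$cluster_id, junctions$start, junctions$end), ]
  rownames(junctions) <- NULL
  junctions
}

#' Flag junctions eligible for differential-splicing testing
#'
#' A junction is testable when every sample of every condition supports it
#' with at least `min_reads_per_sample` split reads. Non-testable junctions
#' are flagged rather than removed, so they still contribute to PSI
#' denominators.
#'
#' @param junctions clustered junction data.frame (see [cluster_introns]).
#' @param conditions character/factor of condition labels, one per count
#'   column.
#' @param min_reads_per_sample threshold (default 7).
#' @return `junctions` with a logical `testable` column.
#' @export
filter_for_testing <- function(junctions, conditions, min_reads_per_sample = 7L) {
  counts <- junction_counts(junctions)
  conditions <- as.factor(conditions)
  if (length(conditions) != ncol(counts)) {
    stop("conditions must have one label per count column")
  }
  if (nlevels(conditions) < 2L) stop("need >= 2 conditions")
  if (any(table(conditions) == 0L)) stop("condition with zero samples")
  junctions$testable <- rowSums(counts < min_reads_per_sample) == 0L
  if (nrow(junctions) > 0L && !any(junctions$testable)) {
    warning("no junction passes the per-sample read filter; testable set is empty")
  }
  junctions
}

#' Percent spliced in (PSI) per junction and sample
#'
#' PSI is a junction's count divided by its cluster's total count in that
#' sample. When a cluster has zero reads in a sample, PSI is `NA` (absent),
#' not 0.
#'
#' @param junctions clustered junction data.frame with `cluster_id`.
#' @return Numeric matrix (junctions x samples) of PSI values; row names are
#'   junction ids.
#' @export
compute_psi <- function(junctions) {
  counts <- junction_counts(junctions)
  if (nrow(counts) == 0L) return(counts)
  psi <- counts
  for (cl in split(seq_len(nrow(counts)), junctions$cluster_id)) {
    tot <- colSums(counts[cl, , drop = FALSE])
    denom <- rep(tot, each = length(cl))
    psi[cl, ] <- ifelse(denom > 0, counts[cl, , drop = FALSE] / denom, NA_real_)
  }
  rownames(psi) <- junction_id(junctions)
  psi
}

#' Read a sample-to-condition map
#'
#' Parses a small plain-text config of `sample=condition` (or
#' `sample: condition`) lines; blank lines and `#` comments are ignored.
#'
#' @param path config file path.
#' @return Named character vector mapping sample names to condition labels.
#' @export
read_condition_map <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^=:]+?)\\s*[=:]\\s*(.+)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop(sprintf("malformed config line: '%s'", lines[bad][1L]))
  stats::setNames(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 2L))
}
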