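# End-to-end orchestration: simulate -> scan -> cluster -> test -> enrich.
# Every stage is deterministic given the master seed, and the returned
# object carries the ground truth alongside each intermediate result.

#' Longest MO match near each junction's donor site
#'
#' For each junction, the maximal Watson-Crick run length among scan hits on
#' the same contig whose run interval lies within `window` bp of the
#' junction's donor coordinate (0 when there is none).
#'
#' @param junctions junction data.frame.
#' @param hits hit data.frame from [scan_for_offtargets].
#' @param window distance threshold in bp (default 75).
#' @return Named numeric vector keyed by junction id.
#' @export
junction_match_length <- function(junctions, hits, window = 75L) {
  out <- stats::setNames(numeric(nrow(junctions)), junction_id(junctions))
  if (nrow(hits) == 0L) return(out)
  for (i in seq_len(nrow(junctions))) {
    h <- hits[hits$target_id == junctions$contig[i], , drop = FALSE]
    if (nrow(h) == 0L) next
    donor <- junctions$start[i]
    d <- ifelse(donor < h$run_start, h$run_start - donor,
                ifelse(donor >= h$run_start + h$run_length,
                       donor - (h$run_start + h$run_length), 0L))
    near <- d <= window
    if (any(near)) out[i] <- max(h$run_length[near])
  }
  out
}

#' Run the full off-target mis-splicing pipeline on synthetic data
#'
#' Chains the stages end to end: generate a transcriptome, plant MO
#' off-target sites next to donor splice sites of the first `n_blocked`
#' genes, simulate split-read junction counts under the blocking model, scan
#' the transcriptome for MO complementarity, cluster introns, test
#' differential splicing, and quantify match enrichment at mis-spliced
#' junctions against a bootstrap background.
#'
#' @param mo the morpholino to scan (default: the standard control MO).
#' @param n_genes genes in the synthetic transcriptome (default 40).
#' @param n_blocked genes receiving a planted off-target site at their first
#'   donor (default 8; 0 gives a matched null dataset).
#' @param run_length planted Watson-Crick run length (default 10).
#' @param depth expected cluster read total per sample (default 150).
#' @param delta_psi optional fixed PSI drop at blocked junctions (otherwise
#'   the logistic blocking model applies).
#' @param min_run scanner threshold (default 8).
#' @param fdr_threshold differential-splicing FDR (default 0.1).
#' @param background_min_reads split-read total defining the enrichment
#'   background (default 20).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed master seed; all stages derive their seeds from it.
#' @return List with `transcriptome`, `sim`, `hits`, `clustered`,
#'   `diffsplice`, `match_length`, `enrichment`, `blocked_truth`, `seed`.
#' @export
run_pipeline <- function(mo = study_morpholinos()$cMO, n_genes = 40L,
                         n_blocked = 8L, run_length = 10L, depth = 150,
                         delta_psi = NULL, min_run = 8L,
                         fdr_threshold = 0.1, background_min_reads = 20L,
                         n_boot = 1000L, seed = 1L) {
  txome <- generate_transcriptome(n_genes, seed = seed)
  if (n_blocked > 0L) {
    genes <- names(txome$sequences)[seq_len(min(n_blocked, n_genes))]
    spec <- do.call(rbind, lapply(genes, function(g) {
      donor <- txome$introns$start[txome$introns$gene == g][1L]
      data.frame(target = g, position = donor - 4L, run_length = run_length)
    }))
    txome <- plant_offtarget_sites(txome, mo, spec)
  }
  sim <- simulate_junction_counts(txome, depth = depth, delta_psi = delta_psi,
                                  seed = seed + 1L)
  hits <- scan_for_offtargets(mo, txome$sequences, min_run = min_run)
  hits <- annotate_hit_distances(hits, txome$splice_sites)
  clustered <- cluster_introns(sim$junctions)
  clustered <- filter_for_testing(clustered, sim$conditions)
  ds <- test_differential_splicing(clustered, sim$conditions,
                                   fdr_threshold = fdr_threshold)
  match_len <- junction_match_length(clustered, hits)
  # blocked set: canonical (donor-sharing) junctions of significant clusters;
  # background: junctions supported by >= background_min_reads split reads
  jid <- junction_id(clustered)
  totals <- rowSums(junction_counts(clustered))
  background <- jid[totals >= background_min_reads]
  sig_clusters <- ds$clusters$cluster_id[ds$clusters$significant %in% TRUE]
  is_canonical <- !duplicated(clustered$cluster_id)  # leftmost junction
  blocked <- jid[is_canonical & clustered$cluster_id %in% sig_clusters]
  enrichment <- NULL
  if (length(blocked) > 0L && length(background) > 0L) {
    enrichment <- match_vs_missplice_enrichment(
      blocked, background, match_len, n_boot = n_boot, seed = seed + 2L)
  }
  list(transcriptome = txome, sim = sim, hits = hits, clustered = clustered,
       diffsplice = ds, match_length = match_len, enrichment = enrichment,
       blocked_truth = sim$truth$clusters, seed = seed)
}
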