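# Synthetic-data generator: transcriptomes with planted MO off-target
# sites, split-read junction count tables under an MO-blocking model, and
# expression matrices with GC-content-dependent immune induction. Every
# dataset carries a ground-truth record and is reproducible from its seed.

.random_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.sample_donor <- function(consensus = "CAGGTAAGT", fidelity = 0.85) {
  cons <- strsplit(consensus, "")[[1L]]
  vapply(cons, function(b) {
    other <- setdiff(c("A", "C", "G", "T"), b)
    sample(c(b, other), 1L, prob = c(fidelity, rep((1 - fidelity) / 3, 3)))
  }, "")
}

#' Generate a synthetic multi-exon transcriptome
#'
#' Random pre-mRNA sequences with at least two exons per gene. Each
#' exon|intron boundary carries a canonical donor 9-mer sampled around the
#' donor consensus (positions -3..+6), and each intron ends in AG. Gene
#' structure, splice-site positions, and the master seed are recorded as
#' ground truth.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_exons_range inclusive range of exons per gene (default 2--4).
#' @param exon_len_range,intron_len_range inclusive bp ranges.
#' @param gc_background background GC fraction (default 0.40).
#' @param donor_consensus donor 9-mer consensus (default `"CAGGTAAGT"`).
#' @param donor_fidelity per-column probability of the consensus base
#'   (default 0.85; 1 forces every donor to the consensus).
#' @param seed master seed.
#' @return List of class `synthetic_transcriptome`: `sequences` (named
#'   character, pre-mRNA sense strands), `introns` (data.frame gene, start,
#'   end; 0-based half-open), `splice_sites` (named list of 0-based donor
#'   and acceptor positions per gene), `truth` (parameters + seed).
#' @export
generate_transcriptome <- function(n_genes, n_exons_range = c(2L, 4L),
                                   exon_len_range = c(80L, 250L),
                                   intron_len_range = c(150L, 600L),
                                   gc_background = 0.40,
                                   donor_consensus = "CAGGTAAGT",
                                   donor_fidelity = 0.85, seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (any(c(exon_len_range, intron_len_range) < 10L)) {
    stop("infeasible length configuration")
  }
  with_seed(seed, {
    seqs <- character(n_genes)
    introns <- list()
    sites <- list()
    for (g in seq_len(n_genes)) {
      ne <- sample(seq(n_exons_range[1L], n_exons_range[2L]), 1L)
      exl <- sample(seq(exon_len_range[1L], exon_len_range[2L]), ne, replace = TRUE)
      inl <- sample(seq(intron_len_range[1L], intron_len_range[2L]), ne - 1L,
                    replace = TRUE)
      bases <- character(0)
      gene_introns <- matrix(0L, nrow = ne - 1L, ncol = 2L)
      for (e in seq_len(ne)) {
        bases <- c(bases, .random_bases(exl[e], gc_background))
        if (e < ne) {
          donor <- .sample_donor(donor_consensus, donor_fidelity)
          # donor window spans exon -3..-1 | intron +1..+6
          nb <- length(bases)
          bases[(nb - 2L):nb] <- donor[1:3]
          intron_start <- nb                       # 0-based
          intron <- .random_bases(inl[e], gc_background)
          intron[1:6] <- donor[4:9]
          intron[(length(intron) - 1L):length(intron)] <- c("A", "G")
          bases <- c(bases, intron)
          gene_introns[e, ] <- c(intron_start, intron_start + inl[e])
        }
      }
      gid <- sprintf("gene_%03d", g)
      seqs[g] <- paste(bases, collapse = "")
      names(seqs)[g] <- gid
      introns[[gid]] <- data.frame(gene = gid, start = gene_introns[, 1L],
                                   end = gene_introns[, 2L])
      sites[[gid]] <- sort(unique(c(gene_introns[, 1L], gene_introns[, 2L])))
    }
    structure(list(
      sequences = seqs,
      introns = do.call(rbind, c(introns, list(make.row.names = FALSE))),
      splice_sites = sites,
      truth = list(seed = seed, n_genes = n_genes,
                   gc_background = gc_background,
                   donor_consensus = donor_consensus,
                   donor_fidelity = donor_fidelity,
                   planted_sites = NULL)),
      class = "synthetic_transcriptome")
  })
}

# base that neither Watson-Crick- nor wobble-pairs the given MO base
.non_pairing_base <- function(mo_base) {
  tb <- .pair_table(TRUE)
  cand <- c("A", "C", "G", "T")
  cand[!tb[mo_base, cand]][1L]
}

#' Plant MO off-target sites into a synthetic transcriptome
#'
#' Substitutes, at each requested position, the exact reverse complement of
#' an MO subsequence of the requested run length, optionally extending the
#' duplex with wobble-compatible bases. Flanking bases are set to
#' non-pairing residues so the realized Watson-Crick run equals the request
#' exactly; the result is re-verified with the scanner.
#'
#' @param txome a `synthetic_transcriptome`.
#' @param mo an [oligo] with role `"MO"`.
#' @param site_spec data.frame with columns `target` (gene id), `position`
#'   (0-based start of the planted run), `run_length`, and optionally
#'   `wobble_extension` (extra wobble-paired bases, default 0) and
#'   `mo_offset` (0-based offset of the MO subsequence, default 0).
#' @return The modified transcriptome; `truth$planted_sites` records each
#'   site with its realized Watson-Crick and wobble run lengths.
#' @export
plant_offtarget_sites <- function(txome, mo, site_spec) {
  mo <- as_oligo(mo, "MO")
  if (is.null(site_spec$wobble_extension)) site_spec$wobble_extension <- 0L
  if (is.null(site_spec$mo_offset)) site_spec$mo_offset <- 0L
  occupied <- list()
  for (i in seq_len(nrow(site_spec))) {
    gid <- site_spec$target[i]
    pos <- site_spec$position[i]           # 0-based
    L <- site_spec$run_length[i]
    wext <- site_spec$wobble_extension[i]
    moff <- site_spec$mo_offset[i]
    if (L > mo$length || moff + L > mo$length) stop("run_length exceeds MO length")
    seqchars <- strsplit(txome$sequences[[gid]], "")[[1L]]
    if (pos < 0L || pos + L > length(seqchars)) stop("position out of bounds")
    prev <- occupied[[gid]]
    if (!is.null(prev) &&
        any(pos < prev[, 2L] + 1L & pos + L + wext + 1L > prev[, 1L])) {
      stop("requested site collides with another planted site")
    }
    sub <- mo$residues[(moff + 1L):(moff + L)]
    # rc(sub) at target[pos..pos+L): target[pos+i] pairs mo[moff+L-i]
    rc <- rev(vapply(sub, function(b) c(A = "T", T = "A", G = "C", C = "G")[b], ""))
    seqchars[(pos + 1L):(pos + L)] <- rc
    # wobble extension to the left of the planted run: target[pos-k] pairs
    # the MO base following the subsequence (mo index moff+L+k)
    wdone <- 0L
    for (k in seq_len(wext)) {
      mi <- moff + L + k
      if (mi > mo$length || pos - k < 0L) break
      wb <- switch(mo$residues[mi], G = "T", T = "G", NULL)
      if (is.null(wb)) break
      seqchars[pos - k + 1L] <- wb
      wdone <- wdone + 1L
    }
    if (wdone < wext) {
      warning(sprintf("site %s:%d: only %d of %d wobble bases could be planted (the adjacent MO bases must be G or T)",
                      gid, pos, wdone, wext))
    }
    # break accidental extension at both flanks of the planted+wobble region
    left <- pos - wdone          # 0-based index just left of the region
    if (left >= 1L && moff + L + wdone + 1L <= mo$length) {
      seqchars[left] <- .non_pairing_base(mo$residues[moff + L + wdone + 1L])
    }
    if (pos + L + 1L <= length(seqchars) && moff >= 1L) {
      seqchars[pos + L + 1L] <- .non_pairing_base(mo$residues[moff])
    }
    txome$sequences[[gid]] <- paste(seqchars, collapse = "")
    occupied[[gid]] <- rbind(prev, c(pos - wdone, pos + L))
    # verify realized run lengths by scanning
    hit <- scan_for_offtargets(mo, txome$sequences[gid], min_run = 4L)
    hit <- hit[hit$run_start <= pos & hit$run_start + hit$run_length >= pos + L, ]
    if (nrow(hit) != 1L || hit$run_length[1L] != L) {
      stop(sprintf("planted site %s:%d realized run %s != requested %d",
                   gid, pos, paste(hit$run_length, collapse = ","), L))
    }
    txome$truth$planted_sites <- rbind(
      txome$truth$planted_sites,
      data.frame(target = gid, position = pos, run_length = L,
                 wobble_run_length = hit$wobble_run_length[1L],
                 mo_name = mo$name))
  }
  txome
}

#' Simulate split-read junction count tables under an MO-blocking model
#'
#' Each intron becomes a two-junction cluster (canonical plus a cryptic
#' junction sharing the acceptor). Per-sample junction usage is drawn from a
#' Dirichlet around the condition mean with concentration `theta`; cluster
#' read totals are negative binomial at the given depth and dispersion. In
#' the MO condition, canonical usage at blocked donors is reduced on the
#' logit scale by `beta_block * plogis(run_length - 8) * dose`, rerouting
#' the removed mass to the cryptic junction; alternatively a fixed
#' `delta_psi` may be requested per blocked site.
#'
#' @param txome a `synthetic_transcriptome` (typically after
#'   [plant_offtarget_sites]; blocked donors are introns whose donor lies
#'   within `window` bp of a planted site).
#' @param n_replicates samples per condition (default 3).
#' @param depth expected cluster read total per sample (default 100).
#' @param dispersion negative-binomial dispersion of totals (default 0.02).
#' @param theta Dirichlet concentration of usage replication (default 200).
#' @param base_canonical mean canonical usage in controls (default 0.85).
#' @param beta_block,dose logistic blocking-model parameters (defaults 4, 1).
#' @param delta_psi optional fixed PSI drop at blocked canonical junctions
#'   (overrides the logistic model).
#' @param window donor-to-site distance defining "blocked" (default 75).
#' @param seed master seed.
#' @return List: `junctions` (count table with conditions `control`/`mo`),
#'   `conditions`, `truth` (blocked cluster genes, expected delta PSI,
#'   parameters, seed).
#' @export
simulate_junction_counts <- function(txome, n_replicates = 3L, depth = 100,
                                     dispersion = 0.02, theta = 200,
                                     base_canonical = 0.85,
                                     beta_block = 4, dose = 1,
                                     delta_psi = NULL, window = 75L,
                                     seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  introns <- txome$introns
  planted <- txome$truth$planted_sites
  blocked <- rep(FALSE, nrow(introns))
  run_len <- rep(NA_real_, nrow(introns))
  if (!is.null(planted)) {
    for (i in seq_len(nrow(introns))) {
      ps <- planted[planted$target == introns$gene[i], , drop = FALSE]
      if (nrow(ps) == 0L) next
      gap <- pmax(0, pmin(abs(ps$position - introns$start[i]),
                          abs(ps$position + ps$run_length - introns$start[i])))
      near <- gap <= window |
        (ps$position <= introns$start[i] &
           ps$position + ps$run_length >= introns$start[i])
      if (any(near)) {
        blocked[i] <- TRUE
        run_len[i] <- max(ps$run_length[near])
      }
    }
  }
  with_seed(seed, {
    samples <- c(paste0("control_", seq_len(n_replicates)),
                 paste0("mo_", seq_len(n_replicates)))
    conditions <- factor(rep(c("control", "mo"), each = n_replicates),
                         levels = c("control", "mo"))
    rows <- list(); truth_rows <- list()
    for (i in seq_len(nrow(introns))) {
      gene <- introns$gene[i]
      st <- introns$start[i]; en <- introns$end[i]
      cr_start <- st + max(20L, (en - st) %/% 4L)   # cryptic donor inside intron
      p_ctrl <- c(base_canonical, 1 - base_canonical)
      if (blocked[i]) {
        if (!is.null(delta_psi)) {
          p_can <- max(0.02, base_canonical - delta_psi)
        } else {
          b <- beta_block * stats::plogis(run_len[i] - 8) * dose
          p_can <- stats::plogis(stats::qlogis(base_canonical) - b)
        }
        p_mo <- c(p_can, 1 - p_can)
      } else {
        p_mo <- p_ctrl
      }
      counts <- matrix(0L, nrow = 2L, ncol = length(samples))
      for (s in seq_along(samples)) {
        p_cond <- if (conditions[s] == "control") p_ctrl else p_mo
        u <- stats::rgamma(2L, shape = theta * p_cond)
        u <- u / sum(u)
        tot <- stats::rnbinom(1L, mu = depth, size = 1 / dispersion)
        counts[, s] <- stats::rmultinom(1L, tot, u)
      }
      jx <- data.frame(contig = gene, start = c(st, cr_start), end = en,
                       strand = "+")
      cmat <- as.data.frame(counts)
      colnames(cmat) <- samples
      rows[[i]] <- cbind(jx, cmat)
      truth_rows[[i]] <- data.frame(gene = gene, intron_start = st,
                                    intron_end = en, blocked = blocked[i],
                                    run_length = run_len[i],
                                    expected_delta_psi = p_mo[1L] - p_ctrl[1L])
    }
    list(junctions = do.call(rbind, rows), conditions = conditions,
         truth = list(clusters = do.call(rbind, truth_rows),
                      params = list(n_replicates = n_replicates, depth = depth,
                                    dispersion = dispersion, theta = theta,
                                    base_canonical = base_canonical,
                                    beta_block = beta_block, dose = dose,
                                    delta_psi = delta_psi, window = window),
                      seed = seed))
  })
}

#' Simulate an expression matrix with GC-dependent immune induction
#'
#' Immune-response genes receive a log2 fold change of
#' `beta * max(0, gc - 40)/25 * (dose/8) * stage_weight` plus Gaussian
#' noise, encoding the empirical behavior that induction appears above 40%
#' MO GC content, scales with dose, and intensifies with developmental
#' stage. Mis-spliced genes receive a transcript decay factor. Counts are
#' negative binomial around log-normal baselines.
#'
#' @param n_genes total genes (default 300).
#' @param n_immune number of immune-response genes (default 30).
#' @param mo_gc_percent GC content of the injected MO, percent.
#' @param dose_ng injected dose in ng (default 8, the single-MO assay dose).
#' @param stage `"neurula"`, `"mid_tailbud"`, or `"late_tailbud"`.
#' @param misspliced_genes indices of genes receiving transcript decay.
#' @param decay fold applied to mis-spliced genes (default 0.6).
#' @param beta induction slope on the log2 scale (default 2; illustrative).
#' @param n_replicates samples per condition (default 3).
#' @param noise_sd SD of the per-gene log2 fold-change noise (default 0.2).
#' @param dispersion negative-binomial dispersion (default 0.05).
#' @param seed master seed.
#' @return List: `counts` (genes x samples), `conditions`
#'   (`control`/`mo`), `truth` (immune gene ids, true log2 fold changes,
#'   parameters, seed).
#' @export
simulate_expression <- function(n_genes = 300L, n_immune = 30L,
                                mo_gc_percent, dose_ng = 8,
                                stage = c("neurula", "mid_tailbud", "late_tailbud"),
                                misspliced_genes = integer(0), decay = 0.6,
                                beta = 2, n_replicates = 3L, noise_sd = 0.2,
                                dispersion = 0.05, seed = 1L) {
  stage <- match.arg(stage)
  if (mo_gc_percent < 0 || mo_gc_percent > 100) stop("gc must be in [0, 100]")
  sw <- c(neurula = 0.5, mid_tailbud = 1, late_tailbud = 1.5)[[stage]]
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1)
    immune <- seq_len(min(n_immune, n_genes))
    lfc <- stats::rnorm(n_genes, 0, noise_sd)
    induction <- beta * max(0, mo_gc_percent - 40) / 25 * (dose_ng / 8) * sw
    lfc[immune] <- lfc[immune] + induction
    lfc[misspliced_genes] <- lfc[misspliced_genes] + log2(decay)
    mu <- cbind(matrix(base, n_genes, n_replicates),
                matrix(base * 2^lfc, n_genes, n_replicates))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = n_genes)
    rownames(counts) <- sprintf("gene_%03d", seq_len(n_genes))
    colnames(counts) <- c(paste0("control_", seq_len(n_replicates)),
                          paste0("mo_", seq_len(n_replicates)))
    list(counts = counts,
         conditions = factor(rep(c("control", "mo"), each = n_replicates),
                             levels = c("control", "mo")),
         truth = list(immune_genes = rownames(counts)[immune],
                      true_log2_fc = stats::setNames(lfc, rownames(counts)),
                      induction_log2 = induction,
                      params = list(mo_gc_percent = mo_gc_percent,
                                    dose_ng = dose_ng, stage = stage,
                                    stage_weight = sw, beta = beta,
                                    decay = decay, noise_sd = noise_sd),
                      seed = seed))
  })
}

#' Serialize a ground-truth record to JSON
#' @param truth a truth list from a generator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a ground-truth record back from JSON
#' @param path JSON path.
#' @return Truth list (data.frame fields restored).
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("planted_sites", "clusters")) {
    if (!is.null(tr[[f]])) tr[[f]] <- as.data.frame(tr[[f]])
  }
  tr
}
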