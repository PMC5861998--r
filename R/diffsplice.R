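# Per-cluster differential splicing: likelihood-ratio test of junction-usage
# proportions between conditions under a Dirichlet-multinomial model with a
# cluster-specific concentration parameter estimated by maximum likelihood.
# A G-test on pooled counts serves as fallback when a condition has fewer
# than two replicates.

# log-density of Dirichlet-multinomial counts x (vector over junctions)
# given usage proportions p and concentration theta, summed over samples.
.dm_loglik <- function(X, p, theta) {
  # X: samples x junctions
  n <- rowSums(X)
  a <- theta * p
  sum(lgamma(theta) - lgamma(theta + n)) +
    sum(lgamma(sweep(X, 2L, a, "+")) - rep(lgamma(a), each = nrow(X)))
}

.softmax <- function(eta) { e <- exp(c(eta, 0) - max(eta, 0)); e / sum(e) }

# Maximize DM likelihood for a list of sample x junction count blocks that
# share theta; each block gets its own proportion vector.
.dm_fit <- function(blocks, J) {
  pooled <- lapply(blocks, function(X) {
    p <- colSums(X) + 0.5
    p / sum(p)
  })
  init <- c(unlist(lapply(pooled, function(p) log(p[-J] / p[J]))), log(20))
  nll <- function(par) {
    theta <- exp(par[length(par)])
    if (!is.finite(theta) || theta > 1e8) return(1e10)
    ll <- 0
    for (b in seq_along(blocks)) {
      eta <- par[((b - 1) * (J - 1) + 1):(b * (J - 1))]
      p <- .softmax(eta)
      if (any(p < 1e-12)) p <- (p + 1e-12) / sum(p + 1e-12)
      ll <- ll + .dm_loglik(blocks[[b]], p, theta)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(loglik = -fit$value, par = fit$par)
}

# G-test of junction usage x condition independence on pooled counts.
.g_test <- function(X, groups) {
  pooled <- rowsum(X, groups)                 # conditions x junctions
  E <- outer(rowSums(pooled), colSums(pooled)) / sum(pooled)
  obs <- pooled[pooled > 0]
  G <- 2 * sum(pooled[pooled > 0] * log(pooled[pooled > 0] / E[pooled > 0]))
  df <- (nrow(pooled) - 1L) * (ncol(pooled) - 1L)
  list(stat = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Test clusters for differential junction usage between conditions
#'
#' For each intron cluster with at least two testable junctions, fits a
#' Dirichlet-multinomial model of per-sample junction counts with a
#' cluster-specific concentration, and compares a null with one shared usage
#' vector against an alternative with per-condition usage vectors by a
#' likelihood-ratio chi-squared test. When any condition has fewer than two
#' replicates the test falls back to a G-test on pooled counts. P-values are
#' adjusted across tested clusters by Benjamini-Hochberg.
#'
#' @param junctions clustered junction data.frame, ideally after
#'   [filter_for_testing] (a missing `testable` column means all junctions
#'   are testable).
#' @param conditions condition label per count column; the first factor
#'   level is the reference for delta-PSI signs.
#' @param fdr_threshold FDR used for the `significant` flag (default 0.01).
#' @param sd_factor passed to [select_extreme_events].
#' @return List of class `diffsplice` with elements `clusters` (cluster_id,
#'   statistic, df, p, fdr, significant, min/max event junction ids) and
#'   `junctions` (per-junction delta PSI, log2 usage fold change, event
#'   flags).
#' @export
test_differential_splicing <- function(junctions, conditions,
                                       fdr_threshold = 0.01,
                                       sd_factor = 1.5) {
  conditions <- as.factor(conditions)
  if (nlevels(conditions) < 2L) stop("need >= 2 conditions")
  counts <- junction_counts(junctions)
  if (length(conditions) != ncol(counts)) {
    stop("conditions must have one label per count column")
  }
  if (is.null(junctions$testable)) junctions$testable <- TRUE
  psi <- compute_psi(junctions)
  use_dm <- all(table(conditions) >= 2L)
  jid <- junction_id(junctions)

  cl_rows <- split(seq_len(nrow(junctions)), junctions$cluster_id)
  res <- lapply(names(cl_rows), function(cid) {
    rows <- cl_rows[[cid]]
    test_rows <- rows[junctions$testable[rows]]
    mean_psi <- t(apply(psi[rows, , drop = FALSE], 1L, function(v) {
      tapply(v, conditions, mean, na.rm = TRUE)
    }))
    dpsi <- mean_psi[, -1L, drop = FALSE] - mean_psi[, 1L]
    lfc <- log2((mean_psi[, -1L, drop = FALSE] + 1e-3) / (mean_psi[, 1L] + 1e-3))
    jt <- data.frame(cluster_id = cid, junction = jid[rows],
                     testable = junctions$testable[rows],
                     delta_psi = unname(dpsi[, 1L]), log2_usage_fc = unname(lfc[, 1L]),
                     min_event = FALSE, max_event = FALSE)
    if (length(test_rows) < 2L) {
      return(list(cl = data.frame(cluster_id = cid, statistic = NA_real_,
                                  df = NA_integer_, p = NA_real_,
                                  n_junctions = length(rows), skipped = TRUE),
                  jt = jt))
    }
    X <- t(counts[test_rows, , drop = FALSE])       # samples x junctions
    J <- ncol(X)
    if (use_dm) {
      null_fit <- .dm_fit(list(X), J)
      alt_fit <- .dm_fit(lapply(split.data.frame(as.data.frame(X), conditions), as.matrix), J)
      stat <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
      df <- (nlevels(conditions) - 1L) * (J - 1L)
      p <- stats::pchisq(stat, df, lower.tail = FALSE)
    } else {
      g <- .g_test(t(counts[test_rows, , drop = FALSE]) , conditions)
      stat <- g$stat; df <- g$df; p <- g$p
    }
    list(cl = data.frame(cluster_id = cid, statistic = stat, df = df, p = p,
                         n_junctions = length(rows), skipped = FALSE),
         jt = jt)
  })
  clusters <- do.call(rbind, lapply(res, `[[`, "cl"))
  jtab <- do.call(rbind, lapply(res, `[[`, "jt"))
  clusters$fdr <- NA_real_
  tested <- !clusters$skipped
  clusters$fdr[tested] <- stats::p.adjust(clusters$p[tested], method = "BH")
  clusters$significant <- !is.na(clusters$fdr) & clusters$fdr <= fdr_threshold
  # extreme PSI events per tested cluster
  clusters$max_event <- NA_character_
  clusters$min_event <- NA_character_
  starts <- junctions$start[match(jtab$junction, jid)]
  for (i in which(tested)) {
    cid <- clusters$cluster_id[i]
    sel <- which(jtab$cluster_id == cid)
    ev <- select_extreme_events(jtab$delta_psi[sel], starts[sel],
                                sd_factor = sd_factor)
    if (!is.na(ev$max_idx)) {
      jtab$max_event[sel[ev$max_idx]] <- TRUE
      clusters$max_event[i] <- jtab$junction[sel[ev$max_idx]]
    }
    if (!is.na(ev$min_idx)) {
      jtab$min_event[sel[ev$min_idx]] <- TRUE
      clusters$min_event[i] <- jtab$junction[sel[ev$min_idx]]
    }
  }
  structure(list(clusters = clusters, junctions = jtab,
                 fdr_threshold = fdr_threshold,
                 conditions = conditions, method = if (use_dm) "dirichlet_multinomial" else "g_test"),
            class = "diffsplice")
}

#' @export
print.diffsplice <- function(x, ...) {
  cat(sprintf("<diffsplice> %d clusters tested (%s), %d significant at FDR <= %g\n",
              sum(!x$clusters$skipped), x$method,
              sum(x$clusters$significant, na.rm = TRUE), x$fdr_threshold))
  invisible(x)
}

#' Select the extreme splice events of a cluster
#'
#' The max event is the junction whose condition-mean PSI change is largest
#' (ties broken by leftmost intron start). The min event is the junction
#' with the most negative change, reported only when that change lies at
#' least `sd_factor` standard deviations below the cluster mean change;
#' otherwise it is absent.
#'
#' @param delta_psi per-junction condition-mean PSI changes of one cluster.
#' @param starts intron start coordinates (for tie-breaking); defaults to
#'   the input order.
#' @param sd_factor multiple of the cluster SD below the mean required for a
#'   min event (default 1.5).
#' @return List with `max_idx` and `min_idx` (index into `delta_psi`;
#'   `min_idx` is `NA` when no junction passes the rule).
#' @export
select_extreme_events <- function(delta_psi, starts = seq_along(delta_psi),
                                  sd_factor = 1.5) {
  ok <- is.finite(delta_psi)
  if (!any(ok)) return(list(max_idx = NA_integer_, min_idx = NA_integer_))
  idx <- which(ok)
  max_idx <- idx[order(-delta_psi[idx], starts[idx])][1L]
  min_idx <- NA_integer_
  if (sum(ok) >= 2L) {
    mu <- mean(delta_psi[idx]); sdv <- stats::sd(delta_psi[idx])
    cand <- idx[order(delta_psi[idx], starts[idx])][1L]
    if (is.finite(sdv) && sdv > 0 && delta_psi[cand] <= mu - sd_factor * sdv) {
      min_idx <- cand
    }
  }
  list(max_idx = max_idx, min_idx = min_idx)
}
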