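# Enrichment of MO complementarity and transcript-level decreases at
# mis-spliced junctions, quantified against a Mann-Whitney rank null and a
# bootstrap expectation over a background junction set.

# Evaluate an expression with a temporarily seeded RNG, restoring state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mann-Whitney U test
#'
#' Rank-sum test of whether values in `x` tend to exceed those in `y`. In
#' exact mode the null distribution of U is obtained by full enumeration of
#' all assignments of the pooled values to the two groups (ties handled
#' through midranks), giving exact p-values even with ties. In normal mode
#' the large-sample approximation with tie correction and continuity
#' correction is used. Mode `"auto"` enumerates when `|x| + |y| <= 12`.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return List with `U` (for `x` relative to `y`), `p` (two-sided),
#'   and `mode` used.
#' @examples
#' mann_whitney_u(c(10, 12), c(1, 2, 3))  # U = 6, p = 0.2
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  if (mode == "auto") mode <- if (N <= 12L) "exact" else "normal"
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (mode == "exact") {
    combos <- utils::combn(N, nx)
    Us <- apply(combos, 2L, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(pooled)
    sigma2 <- nx * ny * (N + 1) / 12 -
      nx * ny * sum(ties^3 - ties) / (12 * N * (N - 1))
    if (sigma2 <= 0) return(list(U = U, p = 1, mode = mode))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p, mode = mode)
}

#' Bootstrap expectation of a feature count in random sets
#'
#' Draws `n_boot` resamples of `set_size` items with replacement from the
#' background and counts how many resampled items carry the feature,
#' yielding the expected count and a percentile confidence interval for a
#' set of that size drawn at random.
#'
#' @param background vector of background items (or their feature values).
#' @param feature predicate function mapping items to logical, or a logical
#'   vector aligned with `background`.
#' @param set_size size of each resample (usually the observed set size).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed; the summary is reproducible bit-for-bit.
#' @param conf confidence level of the percentile interval (default 0.95).
#' @return List with `expected` (mean count), `ci` (length-2 percentile
#'   interval), `boot_counts`, `n_boot`, `seed`.
#' @export
bootstrap_expected <- function(background, feature, set_size, n_boot = 1000L,
                               seed = 1L, conf = 0.95) {
  if (length(background) == 0L) stop("empty background")
  flags <- if (is.function(feature)) {
    vapply(background, feature, logical(1))
  } else {
    as.logical(feature)
  }
  if (length(flags) != length(background)) stop("feature length mismatch")
  counts <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      sum(flags[sample.int(length(flags), set_size, replace = TRUE)])
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  list(expected = mean(counts),
       ci = unname(stats::quantile(counts, c(a, 1 - a))),
       boot_counts = counts, n_boot = n_boot, seed = seed)
}

.enrichment_summary <- function(feature_name, obs_values, bg_values,
                                predicate, n_boot, seed) {
  obs <- sum(predicate(obs_values))
  boot <- bootstrap_expected(bg_values, predicate(bg_values),
                             set_size = length(obs_values),
                             n_boot = n_boot, seed = seed)
  mw <- mann_whitney_u(obs_values, bg_values, mode = "normal")
  structure(list(feature = feature_name, observed = obs,
                 expected = boot$expected, ci = boot$ci,
                 U = mw$U, p = mw$p, n_set = length(obs_values),
                 n_background = length(bg_values),
                 n_boot = n_boot, seed = seed),
            class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf("<enrichment> %s: observed %d vs expected %.1f [%.0f, %.0f] (n_boot %d); Mann-Whitney U %.0f, p = %.3g\n",
              x$feature, x$observed, x$expected, x$ci[1], x$ci[2],
              x$n_boot, x$U, x$p))
  invisible(x)
}

#' Enrichment of MO matches and transcript decreases at blocked junctions
#'
#' Joins differential-splicing calls to MO scan results and asks two
#' questions about the set of blocked (mis-spliced) junctions relative to a
#' background of active junctions: (a) do blocked junctions carry longer
#' consecutive MO complementarity runs (observed count of runs at or above
#' `match_threshold` vs a bootstrap expectation, plus a Mann-Whitney test on
#' run lengths), and (b) are their genes' transcript levels more often
#' reduced below `fc_threshold` of control.
#'
#' @param blocked character ids of blocked junctions.
#' @param background character ids of background junctions (convention:
#'   junctions with at least 20 split reads among all samples).
#' @param match_length named numeric vector: per junction id, the longest
#'   consecutive MO match within the splice-site window (0 when none).
#' @param fold_change named numeric vector: per junction id, the gene-level
#'   transcript fold change vs control (1 = unchanged).
#' @param match_threshold run length defining a "match" (default 10).
#' @param fc_threshold fold-change fraction defining "reduced" (default
#'   0.67).
#' @param n_boot,seed bootstrap settings.
#' @return List with elements `match` and `foldchange`, each an
#'   `enrichment_summary`, plus `p_adjusted` (BH across the two features).
#' @export
match_vs_missplice_enrichment <- function(blocked, background, match_length,
                                          fold_change = NULL,
                                          match_threshold = 10,
                                          fc_threshold = 0.67,
                                          n_boot = 1000L, seed = 1L) {
  miss <- setdiff(blocked, names(match_length))
  if (length(miss) > 0L) {
    stop(sprintf("missing match-length annotation for %d blocked junctions", length(miss)))
  }
  if (length(setdiff(background, names(match_length))) > 0L) {
    stop("missing match-length annotation for background junctions")
  }
  out <- list()
  out$match <- .enrichment_summary(
    sprintf(">=%d consecutive MO matches", match_threshold),
    match_length[blocked], match_length[background],
    function(v) v >= match_threshold, n_boot, seed)
  if (!is.null(fold_change)) {
    if (length(setdiff(blocked, names(fold_change))) > 0L ||
        length(setdiff(background, names(fold_change))) > 0L) {
      stop("missing fold-change annotation")
    }
    fc_blocked <- fold_change[blocked]
    fc_bg <- fold_change[background]
    s <- .enrichment_summary(
      sprintf("transcript level < %d%% of control", round(100 * fc_threshold)),
      fc_blocked, fc_bg, function(v) v < fc_threshold, n_boot, seed + 1L)
    # direction of interest is decreased levels: rank test on negated fc
    mw <- mann_whitney_u(-fc_blocked, -fc_bg, mode = "normal")
    s$U <- mw$U; s$p <- mw$p
    out$foldchange <- s
  }
  ps <- vapply(out, function(s) s$p, numeric(1))
  out$p_adjusted <- stats::p.adjust(ps, method = "BH")
  out
}
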