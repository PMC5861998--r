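# Independent oracles used across tests. These deliberately take different
# computational routes from the package implementation.

# pairing predicate, written out longhand
oracle_pairs <- function(mo_b, tg_b, wobble = FALSE) {
  wc <- (mo_b == "A" & tg_b %in% c("U", "T")) | (mo_b == "T" & tg_b == "A") |
    (mo_b == "G" & tg_b == "C") | (mo_b == "C" & tg_b == "G")
  if (wobble) {
    wc <- wc | (mo_b == "G" & tg_b %in% c("U", "T")) | (mo_b == "T" & tg_b == "G")
  }
  wc
}

# longest complementary run by per-position walking (no diagonal bookkeeping)
oracle_lcr <- function(mo, tg, wobble = FALSE) {
  mo <- strsplit(toupper(mo), "")[[1L]]
  tg <- strsplit(toupper(tg), "")[[1L]]
  mor <- rev(mo)
  m <- length(mo); n <- length(tg); best <- 0L
  for (d in (1L - m):(n - 1L)) {
    run <- 0L
    for (p in seq_len(m)) {
      q <- p + d
      if (q >= 1L && q <= n && oracle_pairs(mor[p], tg[q], wobble)) {
        run <- run + 1L
        if (run > best) best <- run
      } else {
        run <- 0L
      }
    }
  }
  best
}

# all maximal WC runs >= min_run via rle over diagonals of the match matrix
oracle_scan <- function(mo, tg, min_run = 8L) {
  mo <- strsplit(toupper(mo), "")[[1L]]
  tg <- strsplit(toupper(tg), "")[[1L]]
  mor <- rev(mo)
  m <- length(mo); n <- length(tg)
  M <- outer(seq_len(m), seq_len(n),
             function(p, q) oracle_pairs(mor[p], tg[q]))
  out <- NULL
  for (d in (1L - m):(n - 1L)) {
    p <- seq_len(m); q <- p + d
    ok <- q >= 1L & q <= n
    if (!any(ok)) next
    v <- M[cbind(p[ok], q[ok])]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    for (i in which(r$values & r$lengths >= min_run)) {
      p_end <- p[ok][ends[i]]
      out <- rbind(out, data.frame(start = p_end + d - r$lengths[i],
                                   length = r$lengths[i]))
    }
  }
  if (is.null(out)) data.frame(start = integer(0), length = integer(0))
  else out[order(out$start, out$length), , drop = FALSE]
}

# transitive-closure clustering oracle on shared boundaries
oracle_cluster <- function(df) {
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- df$contig[i] == df$contig[j] & df$strand[i] == df$strand[j] &
      (df$start[i] == df$start[j] | df$end[i] == df$end[j])
  }
  reach <- adj | diag(n)
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { cid <- cid + 1L; comp[reach[i, ]] <- cid }
  }
  comp
}

# two-sided exact Mann-Whitney p by enumerating group assignments and
# counting pairs (not rank sums)
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x); N <- length(pooled)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- nx * length(y) / 2
  u_obs <- ustat(x, y)
  combos <- utils::combn(N, nx)
  us <- apply(combos, 2L, function(ix) ustat(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_mo <- function(n = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  oligo(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
        role = "MO", name = "random_mo")
}
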