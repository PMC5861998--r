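make_junctions <- function(contig, start, end, strand = "+", ...) {
  counts <- data.frame(...)
  cbind(data.frame(contig = contig, start = start, end = end, strand = strand),
        counts)
}

test_that("STAR-style tables convert coordinates and merge duplicates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sj.tab")
  writeLines(c("chr1\t1001\t1100\t1\t3\t5",
               "chr1\t1001\t1100\t1\t4\t2",
               "chr2\t50\t900\t2\t10\t0"), path)
  j <- read_junction_table(path, dialect = "star_sj")
  expect_equal(nrow(j), 2L)
  expect_equal(j$start[j$contig == "chr1"], 1000L)  # 1-based inclusive -> 0-based
  expect_equal(j$end[j$contig == "chr1"], 1100L)
  expect_equal(unname(unlist(j[j$contig == "chr1", c("sample_1", "sample_2")])),
               c(7, 7))
  expect_equal(j$strand, c("+", "-"))
})

test_that("malformed or empty junction tables are handled explicitly", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tab")
  writeLines(c("chr1\t10\t100\t1\t5", "chr1\t20\t200\t1\t-3"), bad)
  expect_error(read_junction_table(bad, "star_sj"), "negative count at line 2")
  malformed <- file.path(dir, "mal.tab")
  writeLines(c("chr1\t10\t100\t1\tfive"), malformed)
  expect_error(read_junction_table(malformed, "star_sj"), "malformed")
  empty <- file.path(dir, "empty.tab")
  file.create(empty)
  expect_warning(j <- read_junction_table(empty, "star_sj"), "empty")
  expect_equal(nrow(j), 0L)
})

test_that("junction tables round-trip through the bed_counts dialect", {
  dir <- withr::local_tempdir()
  j <- make_junctions("g1", c(100L, 100L), c(500L, 900L), "+",
                      s1 = c(8, 9), s2 = c(7, 12))
  path <- file.path(dir, "j.tsv")
  write_junction_table(j, path)
  back <- read_junction_table(path, "bed_counts", sample_names = c("s1", "s2"))
  expect_equal(back, j)
})

test_that("introns sharing a boundary cluster together and small clusters drop", {
  j <- make_junctions("g1", c(100L, 100L, 5000L), c(500L, 900L, 5600L), "+",
                      s1 = c(5, 4, 6))
  cl <- cluster_introns(j)
  # A and B share donor 100 (total 9 >= 7); the lone junction totals 6 < 7
  expect_equal(sum(cl$start == 100L), 2L)
  expect_equal(length(unique(cl$cluster_id[cl$start == 100L])), 1L)
  expect_false(5000L %in% cl$start)
})

test_that("overlong introns are removed before clustering", {
  j <- make_junctions("g1", c(0L, 0L), c(600000L, 400L), "+", s1 = c(50, 50))
  cl <- cluster_introns(j)
  expect_equal(cl$end, 400L)
  expect_equal(nrow(cluster_introns(j, max_intron_len = 700000L)), 2L)
})

test_that("clustering is order-invariant and matches a transitive-closure oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(20:60, 1)
    bounds <- sample(seq(0L, 5000L, by = 100L), 2 * n, replace = TRUE)
    df <- data.frame(contig = sample(c("c1", "c2"), n, replace = TRUE),
                     start = pmin(bounds[1:n], bounds[(n + 1):(2 * n)]),
                     end = pmax(bounds[1:n], bounds[(n + 1):(2 * n)]) + 100L,
                     strand = sample(c("+", "-", "?"), n, replace = TRUE))
    df <- df[!duplicated(df), ]
    df$s1 <- 100  # keep every cluster above the read threshold
    cl <- cluster_introns(df)
    comp <- oracle_cluster(df)
    # same partition: membership maps 1:1 between oracle components and ids
    key <- junction_id(df)
    got <- cl$cluster_id[match(key, junction_id(cl))]
    expect_false(anyNA(got))
    expect_equal(length(unique(got)), length(unique(comp)))
    expect_true(all(tapply(got, comp, function(v) length(unique(v))) == 1L))
    # permutation of the input yields the identical labeled clustering
    perm <- sample(nrow(df))
    cl2 <- cluster_introns(df[perm, ])
    expect_equal(cl2[order(cl2$contig, cl2$start, cl2$end, cl2$strand), ],
                 cl[order(cl$contig, cl$start, cl$end, cl$strand), ],
                 ignore_attr = TRUE)
  }
})

test_that("strand-unknown junctions cluster separately from stranded ones", {
  j <- make_junctions("g1", c(100L, 100L), c(500L, 900L), c("+", "?"),
                      s1 = c(10, 10))
  cl <- cluster_introns(j)
  expect_equal(length(unique(cl$cluster_id)), 2L)
})

test_that("the per-sample read filter flags junctions, never removes them", {
  j <- make_junctions("g1", c(100L, 100L), c(500L, 900L), "+",
                      a1 = c(8, 8), a2 = c(9, 6), b1 = c(7, 9), b2 = c(12, 9))
  j <- cluster_introns(j)
  f <- filter_for_testing(j, c("ctl", "ctl", "mo", "mo"))
  expect_equal(f$testable, c(TRUE, FALSE))  # 6 < 7 in one sample
  expect_equal(nrow(f), 2L)
  expect_error(filter_for_testing(j, factor(c("a", "a", "a", "a"),
                                            levels = c("a", "b"))),
               "zero samples")
})

test_that("PSI is the within-cluster usage fraction and sums to one", {
  j <- make_junctions("g1", c(100L, 100L, 100L), c(500L, 900L, 1200L), "+",
                      s1 = c(30, 10, 0), s2 = c(20, 20, 10), s3 = c(0, 0, 0))
  j <- cluster_introns(j)
  psi <- compute_psi(j)
  expect_equal(unname(psi[, "s1"]), c(0.75, 0.25, 0))
  expect_equal(unname(psi[, "s2"]), c(0.4, 0.4, 0.2))
  expect_true(all(is.na(psi[, "s3"])))     # absent, not zero
  expect_equal(sum(psi[, "s2"]), 1, tolerance = 1e-9)
})

test_that("condition maps parse key=value and key: value dialects", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "conditions.cfg")
  writeLines(c("# sample map", "control_1=control", "control_2 = control",
               "mo_1: mo", ""), path)
  cm <- read_condition_map(path)
  expect_equal(cm, c(control_1 = "control", control_2 = "control", mo_1 = "mo"))
  writeLines("oops", path)
  expect_error(read_condition_map(path), "malformed config line")
})
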