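mos <- study_morpholinos()
rnas <- study_rna_oligos()

test_that("complementarity runs between printed oligos match reported lengths", {
  expect_equal(longest_complementary_run(mos$t_splice, rnas$t_target)$length, 25L)
  expect_equal(longest_complementary_run(mos$t_splice, rnas$dtymk_offtarget)$length, 8L)
  expect_equal(longest_complementary_run(mos$t_splice, rnas$dtymk_offtarget,
                                         allow_wobble = TRUE)$length, 10L)
  expect_equal(longest_complementary_run(mos$cMO, rnas$dtymk_offtarget)$length, 10L)
  # a scrambled off-target sequence stays below the 8-base scan threshold
  expect_lt(longest_complementary_run(mos$t_splice, rnas$scrambled)$length, 8L)
  # the G>C point mutation shortens the wobble-extended duplex
  expect_lt(longest_complementary_run(mos$t_splice, rnas$dtymk_GtoC,
                                      allow_wobble = TRUE)$length, 10L)
})

test_that("a perfect target is matched over the full MO length", {
  for (seed in 1:15) {
    mo <- random_mo(sample(8:30, 1), seed = seed)
    hit <- longest_complementary_run(mo, reverse_complement(mo, "RNA"))
    expect_equal(hit$length, length(mo))
    expect_equal(hit$target_offset, 0L)
  }
})

test_that("wobble-extended runs are never shorter than Watson-Crick runs", {
  for (seed in 1:25) {
    mo <- random_mo(20, seed = seed)
    tg <- random_dna(200, seed = seed + 1000)
    wc <- longest_complementary_run(mo, tg)$length
    wob <- longest_complementary_run(mo, tg, allow_wobble = TRUE)$length
    expect_gte(wob, wc)
  }
})

test_that("longest run agrees with the per-position walking oracle", {
  for (seed in 1:20) {
    mo <- random_mo(sample(10:25, 1), seed = seed)
    tg <- random_dna(sample(50:300, 1), seed = seed + 500)
    expect_equal(longest_complementary_run(mo, tg)$length,
                 oracle_lcr(as.character(mo), tg))
    expect_equal(longest_complementary_run(mo, tg, allow_wobble = TRUE)$length,
                 oracle_lcr(as.character(mo), tg, wobble = TRUE))
  }
})

test_that("scanner reports a planted site exactly once with its true length", {
  mo <- oligo(substr(as.character(mos$cMO), 1, 12), "MO", name = "cMO_12mer")
  set.seed(11)
  bg <- random_dna(1000)
  planted <- paste0(substr(bg, 1, 100),
                    as.character(reverse_complement(mo, "DNA")),
                    substr(bg, 113, 1000))
  hits <- scan_for_offtargets(mo, c(tx = planted), min_run = 12L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$run_start, 100L)
  expect_equal(hits$run_length, 12L)
})

test_that("a donor-like region complementary to the cMO yields a 10-base hit", {
  # donor region 5'-GAGGUAAGAG-3' pairs cMO bases CTCTTACCTC; flanks chosen
  # not to pair the adjacent MO bases
  target <- paste0("CCCC", "GAGGTAAGAG", "TTTT")
  hits <- scan_for_offtargets(mos$cMO, c(donor_tx = target), min_run = 8L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$run_length, 10L)
  expect_equal(hits$run_start, 4L)
  expect_equal(oracle_scan(as.character(mos$cMO), target, 8L)$length, 10L)
})

test_that("runs below the configured minimum are not reported", {
  mo <- oligo("ACGTACGTACGT", "MO", name = "m")
  seven <- as.character(reverse_complement(substr(as.character(mo), 1, 7), "DNA"))
  target <- paste0("CCCCCCCC", seven, "CCCCCCCC")
  expect_equal(nrow(scan_for_offtargets(mo, c(t = target), min_run = 8L)), 0L)
  expect_equal(nrow(scan_for_offtargets(mo, c(t = target), min_run = 7L)), 1L)
  expect_error(scan_for_offtargets(mo, c(t = target), min_run = 3L), "min_run")
})

test_that("scanner agrees with the rle-diagonal oracle on random sequences", {
  for (seed in 1:30) {
    mo <- random_mo(25, seed = seed)
    tg <- random_dna(sample(200:2000, 1), seed = seed + 2000)
    hits <- scan_for_offtargets(mo, c(tx = tg), min_run = 6L)
    orc <- oracle_scan(as.character(mo), tg, min_run = 6L)
    # oracle lists all maximal runs; scanner merges overlapping ones, so
    # compare the families: every scanner hit must be an oracle run, and the
    # maximum per overlapping family must agree
    if (nrow(orc) == 0L) {
      expect_equal(nrow(hits), 0L)
    } else {
      expect_true(all(paste(hits$run_start, hits$run_length) %in%
                        paste(orc$start, orc$length)))
      expect_equal(max(hits$run_length), max(orc$length))
    }
  }
})

test_that("genome mode finds minus-strand sites with plus-strand coordinates", {
  mo <- oligo("GGCTTCCAAGCG", "MO", name = "m")
  # embed the MO sequence itself: its reverse complement lies on the minus
  # strand, so only a genome scan can see it
  set.seed(3)
  bg <- random_dna(400)
  target <- paste0(substr(bg, 1, 150), as.character(mo), substr(bg, 163, 400))
  tx_hits <- scan_for_offtargets(mo, c(g = target), min_run = 12L,
                                 mode = "transcriptome")
  expect_equal(nrow(tx_hits), 0L)
  g_hits <- scan_for_offtargets(mo, c(g = target), min_run = 12L,
                                mode = "genome")
  expect_equal(g_hits$target_strand, "-")
  expect_equal(g_hits$run_start, 150L)
  expect_equal(g_hits$run_length, 12L)
})

test_that("splice-site distances use the interval gap and flag the 75-bp window", {
  hits <- data.frame(mo_name = "m", target_id = "t", target_strand = "+",
                     run_start = 100L, run_length = 10L,
                     wobble_run_length = 10L, mo_offset = 0L,
                     distance_to_splice_site = NA_integer_, within_window = NA)
  expect_equal(annotate_hit_distances(hits, 185L)$distance_to_splice_site, 75L)
  expect_true(annotate_hit_distances(hits, 185L)$within_window)
  expect_equal(annotate_hit_distances(hits, 186L)$distance_to_splice_site, 76L)
  expect_false(annotate_hit_distances(hits, 186L)$within_window)
  expect_equal(annotate_hit_distances(hits, 105L)$distance_to_splice_site, 0L)
  expect_equal(annotate_hit_distances(hits, c(50L, 185L))$distance_to_splice_site, 50L)
  ann <- annotate_hit_distances(hits, integer(0))
  expect_true(is.na(ann$distance_to_splice_site))
})

test_that("hits export to BED6 plus a TSV companion", {
  dir <- withr::local_tempdir()
  hits <- scan_for_offtargets(mos$cMO, c(tx = paste0("CCCC", "GAGGTAAGAG", "TTTT")),
                              min_run = 8L)
  paths <- export_hits(hits, bed_path = file.path(dir, "h.bed"),
                       tsv_path = file.path(dir, "h.tsv"))
  bed <- read.table(paths$bed, sep = "\t")
  expect_equal(ncol(bed), 6L)
  expect_equal(bed$V2, 4L)
  expect_equal(bed$V3, 14L)
  tsv <- read.table(paths$tsv, sep = "\t", header = TRUE)
  expect_true(all(c("wobble_run_length", "distance_to_splice_site") %in%
                    colnames(tsv)))
})
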