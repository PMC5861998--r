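test_that("the transcriptome generator is seed-deterministic", {
  t1 <- generate_transcriptome(20, seed = 5)
  t2 <- generate_transcriptome(20, seed = 5)
  expect_identical(t1$sequences, t2$sequences)
  expect_identical(t1$introns, t2$introns)
  t3 <- generate_transcriptome(20, seed = 6)
  expect_false(identical(t1$sequences, t3$sequences))
})

test_that("donor windows round-trip through the PWM builder at full fidelity", {
  tx <- generate_transcriptome(30, donor_fidelity = 1, seed = 9)
  windows <- vapply(seq_len(nrow(tx$introns)), function(i) {
    s <- tx$sequences[[tx$introns$gene[i]]]
    substr(s, tx$introns$start[i] - 2, tx$introns$start[i] + 6)
  }, "")
  pwm <- build_donor_pwm(windows, support = rep(10L, length(windows)))
  expect_equal(pwm$consensus, "CAGGTAAGT")
})

test_that("realized GC content tracks the background setting", {
  tx <- generate_transcriptome(60, gc_background = 0.32, seed = 13,
                               donor_fidelity = 0.85)
  seqs <- paste(unlist(tx$sequences), collapse = "")
  expect_gt(nchar(seqs), 50000)
  gc <- gc_content(oligo(seqs, "DNA")) / 100
  expect_equal(gc, 0.32, tolerance = 0.02)
})

test_that("planted off-target sites realize exactly the requested run", {
  mos <- study_morpholinos()
  tx <- generate_transcriptome(5, seed = 21)
  donor <- tx$introns$start[1]
  spec <- data.frame(target = tx$introns$gene[1], position = donor - 4L,
                     run_length = 10L)
  tx2 <- plant_offtarget_sites(tx, mos$cMO, spec)
  hits <- scan_for_offtargets(mos$cMO, tx2$sequences, min_run = 8L)
  hits <- annotate_hit_distances(hits, tx2$splice_sites)
  hits <- hits[hits$target_id == tx$introns$gene[1], ]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$run_length, 10L)
  expect_lte(hits$distance_to_splice_site, 75L)
  expect_equal(tx2$truth$planted_sites$run_length, 10L)
})

test_that("sub-threshold planted runs are invisible to the scanner", {
  mos <- study_morpholinos()
  tx <- generate_transcriptome(3, seed = 22)
  spec <- data.frame(target = "gene_001", position = 50L, run_length = 7L)
  tx2 <- plant_offtarget_sites(tx, mos$cMO, spec)
  hits <- scan_for_offtargets(mos$cMO, tx2$sequences["gene_001"], min_run = 8L)
  expect_equal(nrow(hits), 0L)
})

test_that("wobble extensions reproduce the 8-plus-wobble duplex structure", {
  # mirror of the dtymk case: an 8-base Watson-Crick core whose duplex
  # extends to 10 when wobble pairs are allowed
  mos <- study_morpholinos()
  tx <- generate_transcriptome(3, seed = 23)
  # mo_offset chosen so the two MO bases adjacent to the planted subsequence
  # are T,T and can wobble-pair planted G residues
  spec <- data.frame(target = "gene_002", position = 60L, run_length = 8L,
                     wobble_extension = 2L, mo_offset = 8L)
  tx2 <- plant_offtarget_sites(tx, mos$t_splice, spec)
  hits <- scan_for_offtargets(mos$t_splice, tx2$sequences["gene_002"],
                              min_run = 8L)
  hits <- hits[hits$run_start <= 60 & hits$run_start + hits$run_length >= 68, ]
  expect_equal(hits$run_length, 8L)
  expect_equal(hits$wobble_run_length, 10L)
})

test_that("colliding planted sites are rejected", {
  mos <- study_morpholinos()
  tx <- generate_transcriptome(2, seed = 24)
  spec <- data.frame(target = c("gene_001", "gene_001"),
                     position = c(50L, 55L), run_length = c(10L, 10L))
  expect_error(plant_offtarget_sites(tx, mos$cMO, spec), "collides")
})

test_that("junction count simulation is deterministic and carries truth", {
  tx <- generate_transcriptome(10, seed = 31)
  s1 <- simulate_junction_counts(tx, seed = 32)
  s2 <- simulate_junction_counts(tx, seed = 32)
  expect_identical(s1$junctions, s2$junctions)
  expect_equal(levels(s1$conditions), c("control", "mo"))
  expect_true(all(!s1$truth$clusters$blocked))
  # truth tables survive serialization
  dir <- withr::local_tempdir()
  path <- file.path(dir, "truth.json")
  write_truth(s1$truth, path)
  back <- read_truth(path)
  expect_equal(back$clusters$blocked, s1$truth$clusters$blocked)
  expect_equal(back$seed, 32L)
})

test_that("blocking strength decreases monotonically with dose", {
  mos <- study_morpholinos()
  tx <- generate_transcriptome(12, seed = 41)
  spec <- data.frame(target = tx$introns$gene[!duplicated(tx$introns$gene)][1:6],
                     position = NA, run_length = 10L)
  spec$position <- vapply(spec$target, function(g) {
    tx$introns$start[tx$introns$gene == g][1] - 4L
  }, numeric(1))
  tx <- plant_offtarget_sites(tx, mos$cMO, spec)
  shift <- vapply(c(0.25, 0.5, 1), function(dose) {
    sim <- simulate_junction_counts(tx, dose = dose, seed = 42)
    tr <- sim$truth$clusters
    mean(abs(tr$expected_delta_psi[tr$blocked]))
  }, numeric(1))
  expect_true(all(diff(shift) > 0))
})

test_that("immune induction follows GC content, dose, and stage by design", {
  low <- simulate_expression(n_genes = 50, mo_gc_percent = 32, seed = 51)
  expect_equal(low$truth$induction_log2, 0)
  ind <- vapply(c(48, 52, 65), function(gc) {
    simulate_expression(n_genes = 50, mo_gc_percent = gc, seed = 51)$truth$induction_log2
  }, numeric(1))
  expect_true(all(diff(ind) > 0))
  st <- vapply(c("neurula", "mid_tailbud", "late_tailbud"), function(s) {
    simulate_expression(n_genes = 50, mo_gc_percent = 65, stage = s,
                        seed = 51)$truth$induction_log2
  }, numeric(1))
  expect_true(all(diff(st) > 0))
  expect_error(simulate_expression(mo_gc_percent = 120), "gc")
})

test_that("realized induction ordering holds across seeded runs", {
  orderings <- vapply(1:20, function(seed) {
    mean_fc <- vapply(c(65, 52, 48), function(gc) {
      sim <- simulate_expression(n_genes = 40, n_immune = 10,
                                 mo_gc_percent = gc, stage = "late_tailbud",
                                 seed = seed)
      fc <- transcript_foldchange(sim$counts, sim$conditions)
      mean(fc$log2_fold_change[fc$gene %in% sim$truth$immune_genes])
    }, numeric(1))
    all(diff(mean_fc) < 0)
  }, logical(1))
  expect_gte(mean(orderings), 0.95)
})

test_that("generated junction tables pass the package's own format reader", {
  tx <- generate_transcriptome(8, seed = 61)
  sim <- simulate_junction_counts(tx, seed = 62)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "jx.tsv")
  write_junction_table(sim$junctions, path)
  back <- read_junction_table(path, "bed_counts",
                              sample_names = levels(factor(colnames(
                                junction_counts(sim$junctions)))))
  expect_equal(nrow(back), nrow(sim$junctions))
  expect_equal(sum(junction_counts(back)), sum(junction_counts(sim$junctions)))
})
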