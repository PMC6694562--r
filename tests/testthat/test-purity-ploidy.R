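test_that("noiseless forward-simulated segments recover the true purity", {
  segs <- noiseless_segments(0.74, list(c(2, 0), c(2, 0), c(1, 1), c(1, 1),
                                        c(2, 1), c(2, 2)))
  sols <- fit_candidates(segs)
  expect_lte(abs(sols[[1]]$purity - 0.74), 0.02)
  top <- sols[[1]]$segment_states
  expect_equal(top$major_cn, c(2L, 2L, 1L, 1L, 2L, 2L))
  expect_equal(top$minor_cn, c(0L, 0L, 1L, 1L, 1L, 2L))
  expect_lt(sols[[1]]$fit_score, 1e-8)
})

test_that("a between-integer segment keeps its tied subclonal interpretations", {
  # ratio 1.4 / BAF 0.357 in a pure tumor: one-copy gain in 80% of cells is
  # indistinguishable from a two-copy gain in 40%
  segs <- data.frame(chrom = "1", start = 1, end = 1e8,
                     copy_ratio = 1.4, baf = 1 / 2.8)
  sols <- fit_candidates(segs, purity_grid = 1)
  alts <- sols[[1]]$alternatives[[1]]
  expect_false(is.null(alts))
  key <- sprintf("%d,%d@%.2f", alts$major, alts$minor, alts$fraction)
  expect_true("2,1@0.80" %in% key)
  expect_true("3,1@0.40" %in% key)
  # smallest number of copy changes is preferred among the ties
  expect_equal(c(alts$major[1], alts$minor[1]), c(2, 1))
  expect_false(sols[[1]]$segment_states$clonal_flag[1])
})

test_that("an all-diploid genome is flagged as purity-unidentifiable", {
  segs <- data.frame(chrom = as.character(1:4), start = 1, end = 1e8,
                     copy_ratio = 1, baf = 0.5)
  sols <- fit_candidates(segs)
  expect_true(sols[[1]]$no_major_copy_changes)
  expect_gt(length(sols), 1)  # many purities tie
})

test_that("purity is twice the right-most clonal peak in copy-neutral regions", {
  set.seed(7)
  expect_equal(purity_from_snvs(draw_mafs(2000, 0.37, 200)), 0.74,
               tolerance = 0.02)
  expect_equal(purity_from_snvs(draw_mafs(2000, 0.50, 200)), 1.0,
               tolerance = 0.02)
  # depth-60 recovery at purity 0.6
  hits <- vapply(1:10, function(i) {
    set.seed(100 + i)
    abs(purity_from_snvs(draw_mafs(2000, 0.3, 60)) - 0.6) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(purity_from_snvs(runif(10)), class = "tc_insufficient_data")
})

test_that("subclone fractions invert the copy-ratio relation", {
  ctx <- sample_context(1)
  bg <- copy_state(1, 1); alt <- copy_state(2, 1)
  expect_equal(subclone_fraction_from_ratio(1.4, ctx, bg, alt), 0.8)
  expect_equal(subclone_fraction_from_ratio(1.0, ctx, bg, alt), 0)
  expect_equal(subclone_fraction_from_ratio(1.5, ctx, bg, alt), 1)
  expect_warning(subclone_fraction_from_ratio(1.8, ctx, bg, alt))
  expect_error(subclone_fraction_from_ratio(1.4, ctx, bg, copy_state(2, 0)),
               class = "tc_invalid_input")
})

test_that("MAF validation picks the generating subclonal interpretation", {
  # truth: mono-allelic two-copy gain carried by 40% of tumor cells; the
  # ratio/BAF-tied alternative (one-copy gain in 80%) predicts a different
  # post-event peak, which the observed MAFs rule out
  set.seed(9)
  p <- 0.9
  ctx <- sample_context(p)
  h <- Filter(function(x) x$name == "mono_allelic_two_copy_gain",
              enumerate_histories(4, FALSE))[[1]]
  pk <- peaks_for_history(h, ctx, carrier_fraction = 0.4)
  t_ev <- 0.5
  weights <- c(0.4 * (1 - t_ev) * 4, t_ev * 1, t_ev * 1)  # post, pre-m3, pre-m1
  ns <- round(3000 * weights / sum(weights))
  mafs <- unlist(Map(function(loc, n) draw_mafs(n, loc, 120),
                     pk$location, ns))
  segs <- data.frame(chrom = "1", start = 1, end = 1e8,
                     copy_ratio = expected_copy_ratio(
                       ctx, copy_state(3, 1, clone_fraction = 0.4)),
                     baf = expected_baf(
                       ctx, list(copy_state(3, 1, clone_fraction = 0.4)))$baf)
  sol <- fit_candidates(segs, purity_grid = p)[[1]]
  val <- validate_with_mafs(sol, list(mafs))
  seg <- val$segment_states
  expect_equal(c(seg$major_cn[1], seg$minor_cn[1]), c(3L, 1L))
  expect_equal(seg$subclone_fraction[1], 0.4, tolerance = 0.05)
  expect_false(val$status == "unresolved")
})

test_that("segments with too few SNVs are skipped by MAF validation", {
  segs <- noiseless_segments(0.74, list(c(2, 0), c(1, 1)))
  sol <- fit_candidates(segs)[[1]]
  val <- validate_with_mafs(sol, list(runif(5), NULL))
  expect_false(any(val$segment_states$maf_validated))
  expect_true(is.na(val$maf_consistency))
})
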