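small_config <- function(seed = 1, ...) {
  segments <- data.frame(
    chrom = c("5", "3", "6", "1"),
    start = 1, end = c(3e7, 3e7, 3e7, 5e7),
    history = c("cn_loh", "cn_loh", "one_copy_gain", "copy_neutral"),
    t1 = c(0.02, 0.68, 0.66, NA))
  simulation_config(purity = 0.74, segments = segments, seed = seed, ...)
}

test_that("the same seed reproduces byte-identical tables", {
  a <- simulate_tumor(small_config(seed = 5))
  b <- simulate_tumor(small_config(seed = 5))
  expect_identical(a$snvs, b$snvs)
  expect_identical(a$snps, b$snps)
  expect_identical(a$segments, b$segments)
  c <- simulate_tumor(small_config(seed = 6))
  expect_false(identical(a$snvs, c$snvs))
})

test_that("latent expected VAFs equal the closed-form peak model", {
  sim <- simulate_tumor(small_config(seed = 2))
  ctx <- sample_context(0.74)
  lab <- sim$truth$snv_labels
  # clonal CN-LOH classes on segment 1
  for (m in 1:2) {
    rows <- lab$segment == 1 & lab$clonal & lab$multiplicity == m
    expect_true(all(abs(lab$expected_vaf[rows] -
                          expected_maf_peak(ctx, copy_state(2, 0), m)) < 1e-12))
  }
  # subclonal SNVs carry the subclone fraction
  sub <- lab$segment == 4 & !lab$clonal
  expect_true(all(abs(lab$expected_vaf[sub] -
                        expected_maf_peak(ctx, copy_state(1, 1), 1, 0.3)) < 1e-12))
  # truth labels partition the SNV table
  expect_equal(nrow(lab), nrow(sim$snvs))
})

test_that("simulated MAF peaks land on the model's predictions", {
  sim <- simulate_tumor(example_config(seed = 8))
  expect_peak <- function(chrom, loc) {
    mafs <- sim$snvs$maf[sim$snvs$chrom == chrom]
    fitted <- find_peaks_and_valleys(smooth_density(mafs))
    expect_lt(min(abs(fitted$peaks$location - loc)), 0.04)
  }
  expect_peak("3", 0.74)  # CN-LOH at t = 0.68: ample pre-event mass
  expect_peak("1", 0.37)  # copy-neutral heterozygous
  expect_peak("6", 0.54)  # one-copy gain, duplicated allele
  expect_peak("7", 0.43)  # bi-allelic two-copy gain, pre-gain
})

test_that("per-class mean read-level VAFs are calibrated", {
  devs <- unlist(lapply(1:5, function(i) {
    sim <- simulate_tumor(small_config(seed = 20 + i))
    lab <- sim$truth$snv_labels
    key <- interaction(lab$segment, lab$multiplicity, lab$clonal, drop = TRUE)
    vapply(split(seq_len(nrow(lab)), key), function(ix) {
      if (length(ix) < 50) return(NA_real_)
      exp_v <- lab$expected_vaf[ix[1]]
      se <- sd(sim$snvs$maf[ix]) / sqrt(length(ix))
      (mean(sim$snvs$maf[ix]) - exp_v) / se
    }, numeric(1))
  }))
  devs <- devs[!is.na(devs)]
  # mean MAF per class within ~2 standard errors of the model expectation
  expect_gt(mean(abs(devs) < 2), 0.9)
})

test_that("event times are required and validated", {
  bad <- data.frame(chrom = "1", start = 1, end = 1e7,
                    history = "cn_loh", t1 = NA)
  expect_error(simulate_tumor(simulation_config(0.74, bad)),
               class = "tc_invalid_input")
  bad2 <- data.frame(chrom = "1", start = 1, end = 1e7,
                     history = "cn_loh", t1 = 1.5)
  expect_error(simulation_config(0.74, bad2), class = "tc_invalid_input")
  clones_bad <- data.frame(clone = c("major", "a", "b"),
                           parent = c(NA, "major", "major"),
                           fraction = c(1, 0.7, 0.7))
  ok_seg <- data.frame(chrom = "1", start = 1, end = 1e7,
                       history = "copy_neutral", t1 = NA)
  expect_error(simulation_config(0.74, ok_seg, clones = clones_bad),
               class = "tc_invalid_input")
})

test_that("the neutral tail follows its analytic truncated law", {
  q <- simulate_neutral_tail(2000, 0.1, 0.25, exact = TRUE)
  res <- neutrality_test(q, 0.1, 0.25)
  expect_gt(res$r_squared, 0.99)
  # f_min = f_max/2: the analytic median of the law is 1/(1/f_min - 1)
  med <- median(simulate_neutral_tail(4001, 0.25, 0.5, exact = TRUE))
  expect_equal(med, 1 / 3, tolerance = 1e-3)
  expect_identical(simulate_neutral_tail(0, 0.1), numeric(0))
  expect_error(simulate_neutral_tail(10, 0.6), class = "tc_invalid_input")
})

test_that("kataegis injection respects spans and leaves zero-count inputs alone", {
  bg <- data.frame(chrom = "1", pos = c(10L, 2000L), ref = "C", alt = "A",
                   depth = 50L, alt_count = 10L, maf = 0.2)
  out0 <- inject_kataegis(bg, "1", 0, span_start = 1, span_bp = 100)
  expect_identical(out0$snvs, bg)
  out <- inject_kataegis(bg, "1", 10, span_start = 1000, span_bp = 500)
  expect_equal(sum(out$injected), 10)
  expect_true(all(out$snvs$pos[out$injected] >= 1000 &
                    out$snvs$pos[out$injected] < 1500))
  expect_error(inject_kataegis(bg, "1", 5, span_start = 3e8, span_bp = 100),
               class = "tc_invalid_input")
  expect_error(inject_kataegis(bg, "ZZ", 5, span_start = 1, span_bp = 100),
               class = "tc_invalid_input")
})
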