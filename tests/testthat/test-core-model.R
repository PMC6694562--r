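test_that("MAF peak expectations reproduce the closed-form worked values", {
  ctx <- sample_context(0.74)
  # CN-LOH, both copies mutant
  expect_equal(expected_maf_peak(ctx, copy_state(2, 0), 2), 0.74)
  # copy-neutral heterozygous
  expect_equal(expected_maf_peak(ctx, copy_state(1, 1), 1), 0.37)
  # one-copy gain, duplicated allele
  expect_equal(round(expected_maf_peak(ctx, copy_state(2, 1), 2), 2), 0.54)
  # bi-allelic two-copy gain, pre-gain SNVs
  expect_equal(round(expected_maf_peak(ctx, copy_state(2, 2), 2), 2), 0.43)
  # all four copies mutant
  expect_equal(round(expected_maf_peak(ctx, copy_state(2, 2), 4), 2), 0.85)
})

test_that("pure tumor with all copies mutant gives MAF 1", {
  ctx <- sample_context(1)
  for (st in list(c(1, 0), c(1, 1), c(2, 1), c(3, 1), c(2, 2))) {
    s <- copy_state(st[1], st[2])
    expect_equal(expected_maf_peak(ctx, s, st[1] + st[2]), 1)
  }
})

test_that("invalid peak inputs are rejected", {
  ctx <- sample_context(0.74)
  expect_error(expected_maf_peak(ctx, copy_state(1, 1), 3),
               class = "tc_invalid_input")
  expect_error(sample_context(0), class = "tc_invalid_input")
  expect_error(expected_maf_peak(ctx, copy_state(1, 1), 1, carrier_fraction = 0),
               class = "tc_invalid_input")
  expect_error(copy_state(1, 2), class = "tc_invalid_input")
})

test_that("copy-ratio expectations reproduce the worked one-copy-gain values", {
  expect_equal(expected_copy_ratio(sample_context(1), copy_state(2, 1)), 1.5)
  expect_equal(expected_copy_ratio(sample_context(0.5), copy_state(2, 1)), 1.25)
  expect_equal(expected_copy_ratio(sample_context(1), copy_state(1, 1)), 1)
  expect_error(expected_copy_ratio(sample_context(0.5), list()),
               class = "tc_invalid_input")
})

test_that("BAF expectations reproduce the worked one-copy-gain values", {
  b <- expected_baf(sample_context(0.5), copy_state(2, 1))
  expect_equal(b$baf, 0.4)
  expect_equal(b$mirror, 0.6)
  expect_equal(expected_baf(sample_context(1), copy_state(2, 1))$baf, 1 / 3)
  for (p in c(0.2, 0.5, 0.74, 1)) {
    expect_equal(expected_baf(sample_context(p), copy_state(1, 1))$baf, 0.5)
  }
  expect_error(expected_baf(sample_context(0.5, normal_cn = 1), copy_state(2, 0)),
               class = "tc_invalid_input")
})

test_that("subclonal one-copy gain at 80% matches two-copy gain at 40%", {
  # the classical purity/ploidy degeneracy: identical ratio and BAF
  for (p in c(0.3, 0.5, 0.74, 1)) {
    ctx <- sample_context(p)
    a <- list(copy_state(2, 1, clone_fraction = 0.8))
    b <- list(copy_state(3, 1, clone_fraction = 0.4))
    expect_equal(expected_copy_ratio(ctx, a), expected_copy_ratio(ctx, b),
                 tolerance = 1e-12)
    expect_equal(expected_baf(ctx, a)$baf, expected_baf(ctx, b)$baf,
                 tolerance = 1e-12)
  }
})

test_that("MAF peaks increase strictly with multiplicity and purity", {
  for (st in list(c(2, 1), c(2, 2), c(3, 0))) {
    s <- copy_state(st[1], st[2])
    tot <- st[1] + st[2]
    for (p in c(0.3, 0.6, 0.9)) {
      ctx <- sample_context(p)
      peaks <- vapply(seq_len(tot), function(m) expected_maf_peak(ctx, s, m),
                      numeric(1))
      expect_true(all(diff(peaks) > 0))
    }
    for (m in seq_len(tot)) {
      by_p <- vapply(seq(0.1, 1, 0.1), function(p) {
        expected_maf_peak(sample_context(p), s, m)
      }, numeric(1))
      expect_true(all(diff(by_p) > 0))
    }
  }
})

test_that("at purity 1 the peak is exactly m over total copies", {
  for (st in list(c(1, 0), c(2, 0), c(2, 1), c(2, 2), c(3, 1))) {
    s <- copy_state(st[1], st[2])
    tot <- st[1] + st[2]
    for (m in seq_len(tot)) {
      expect_equal(expected_maf_peak(sample_context(1), s, m), m / tot)
    }
  }
})
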