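test_that("detection power rises monotonically and saturates", {
  pw <- detection_power(60, seed = 1)
  det <- pw$bins$detected_fraction
  expect_true(all(diff(det) >= 0))
  expect_lt(det[1], 0.05)            # allele fraction ~0: essentially nothing
  expect_gt(det[nrow(pw$bins)], 0.99)  # f ~0.3 at 60x: essentially everything
  expect_true(all(det >= 0 & det <= 1))
})

test_that("deeper coverage detects low-fraction SNVs more often", {
  f <- 0.05
  p30 <- detection_power(30, seed = 2)
  p70 <- detection_power(70, seed = 2)
  at <- function(pw) pw$bins$detected_fraction[pw$bins$f_low == 0.05]
  expect_gt(at(p70), at(p30))
  # oracle: exact binomial tails at the nominal depths
  expect_gt(1 - pbinom(2, 70, f), 1 - pbinom(2, 30, f))
  expect_equal(at(p30), 1 - pbinom(2, 30, 0.055), tolerance = 0.12)
})

test_that("subclonal bounds combine detection power and the MAF valley", {
  set.seed(10)
  # a tumor at ~0.66 purity: clonal peak near 0.33, subclonal mass below
  mafs <- c(draw_mafs(1500, 0.33, 79),
            rbinom(1200, 79, simulate_neutral_tail(1200, 0.07, 0.17)) / 79)
  pw <- detection_power(79, seed = 3)
  b <- subclonal_bounds(mafs, pw)
  expect_equal(b$status, "ok")
  expect_gte(b$lower, 0.05); expect_lte(b$lower, 0.07)
  expect_gt(b$upper, 0.15); expect_lt(b$upper, 0.30)
  expect_lt(b$lower, b$upper)
})

test_that("a clonal-only density leaves the upper bound undetermined", {
  set.seed(11)
  b <- subclonal_bounds(draw_mafs(800, 0.5, 60), detection_power(60, seed = 4))
  expect_equal(b$status, "upper_undetermined")
  # a zero power threshold degenerates to the first nonzero-detection bin
  pw <- detection_power(60, seed = 5)
  b0 <- subclonal_bounds(draw_mafs(800, 0.5, 60), pw, power_threshold = 0)
  expect_equal(b0$lower, pw$bins$f_low[1])
})

test_that("the exact neutral quantiles pass the 1/f linearity test", {
  mafs <- simulate_neutral_tail(2000, 0.1, 0.25, exact = TRUE)
  res <- neutrality_test(mafs, 0.1, 0.25)
  expect_equal(res$status, "ok")
  expect_gt(res$r_squared, 0.99)
  expect_true(res$is_neutral)
})

test_that("two discrete subclones are rejected as non-neutral", {
  hits <- vapply(1:20, function(i) {
    set.seed(300 + i)
    mafs <- c(draw_mafs(1000, 0.35 / 2, 100), draw_mafs(1000, 0.15 / 2, 100))
    res <- neutrality_test(mafs, 0.05, 0.25)
    !res$is_neutral
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a verdict is withheld below 500 subclonal SNVs", {
  mafs <- simulate_neutral_tail(499, 0.1, 0.25, exact = TRUE)
  res <- neutrality_test(mafs, 0.1, 0.25)
  expect_equal(res$status, "insufficient_data")
  expect_true(is.na(res$is_neutral))
  expect_error(neutrality_test(runif(600), 0.3, 0.2),
               class = "tc_invalid_input")
})

test_that("neutral read-sampled simulations are mostly classified neutral", {
  hits <- vapply(1:20, function(i) {
    set.seed(400 + i)
    f <- simulate_neutral_tail(2000, 0.1, 0.3)
    mafs <- rbinom(2000, 100, f) / 100
    isTRUE(neutrality_test(mafs, 0.1, 0.3)$is_neutral)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("a fixed allele-fraction window admits more clonal contamination", {
  # low-purity tumor: clonal peak ~0.27 overlaps the fixed 0.12-0.24 window
  set.seed(12)
  n_c <- 2000; n_s <- 1500
  clonal <- draw_mafs(n_c, 0.275, 60)
  sub <- rbinom(n_s, 60, simulate_neutral_tail(n_s, 0.06, 0.13)) / 60
  is_clonal <- rep(c(TRUE, FALSE), c(n_c, n_s))
  mafs <- c(clonal, sub)
  pw <- detection_power(60, seed = 6)
  b <- subclonal_bounds(mafs, pw)
  contam <- function(lo, hi) {
    inside <- mafs >= lo & mafs <= hi
    sum(is_clonal & inside) / sum(inside)
  }
  expect_gt(contam(0.12, 0.24), contam(b$lower, b$upper))
})

test_that("clonal SNVs in aneuploid regions fall inside the fixed window", {
  # one-copy SNVs on a 3-copy region at modest purity sit at p/(p+2)
  for (p in c(0.4, 0.5, 0.6)) {
    loc <- expected_maf_peak(sample_context(p), copy_state(2, 1), 1)
    expect_gte(loc, 0.12); expect_lte(loc, 0.24)
  }
})
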