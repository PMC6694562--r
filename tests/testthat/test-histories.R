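test_that("single-path states yield exactly one history", {
  h2 <- enumerate_histories(2, loh = TRUE)
  expect_length(h2, 1)
  expect_equal(h2[[1]]$name, "cn_loh")
  expect_setequal(unique(h2[[1]]$classes$m), c(2L, 1L))

  h1 <- enumerate_histories(1, loh = TRUE)
  expect_length(h1, 1)
  expect_equal(h1[[1]]$name, "copy_loss")
  expect_equal(unique(h1[[1]]$classes$m), 1L)

  expect_equal(enumerate_histories(2, loh = FALSE)[[1]]$name, "copy_neutral")
})

test_that("the (4,0) state has two paths with distinct class signatures", {
  hs <- enumerate_histories(4, loh = TRUE)
  expect_gte(length(hs), 2)
  sigs <- lapply(hs, function(h) sort(unique(h$classes$m)))
  # loss-then-three-copy-gain leaves only {4, 1}; CN-LOH followed by a
  # mono-allelic two-copy gain adds an m = 3 class
  expect_true(any(vapply(sigs, identical, logical(1), y = c(1L, 4L))))
  expect_true(any(vapply(sigs, identical, logical(1), y = c(1L, 3L, 4L))))
})

test_that("replaying events from (1,1) reaches each history's final state", {
  for (h in tumorclock:::history_catalog()) {
    got <- replay_history(h)
    expect_equal(c(got$major_cn, got$minor_cn),
                 c(h$final_state$major_cn, h$final_state$minor_cn),
                 info = h$name)
  }
})

test_that("high copy numbers are refused with a simple-solution fallback", {
  expect_error(enumerate_histories(5, loh = FALSE), class = "tc_unsupported")
  simp <- simple_histories(6, loh = FALSE)
  expect_length(simp, 2)
  tots <- vapply(simp, function(h) {
    h$final_state$major_cn + h$final_state$minor_cn
  }, integer(1))
  expect_true(all(tots == 6L))
  # one mono-allelic and one maximal bi-allelic representative
  expect_true(any(vapply(simp, function(h) h$final_state$minor_cn == 1L,
                         logical(1))))
  expect_true(any(vapply(simp, function(h) h$final_state$minor_cn == 3L,
                         logical(1))))
})

test_that("history peaks match the closed-form expectations", {
  ctx <- sample_context(0.74)
  pk <- peaks_for_history(enumerate_histories(2, TRUE)[[1]], ctx)
  expect_equal(pk$location, c(0.37, 0.74))

  pk1 <- peaks_for_history(
    Filter(function(h) h$name == "one_copy_gain",
           enumerate_histories(3, FALSE))[[1]],
    sample_context(1))
  expect_equal(pk1$location, c(1 / 3, 2 / 3))
})

test_that("the CN-LOH-first path to (4,0) adds an interior peak", {
  ctx <- sample_context(0.74)
  hs <- enumerate_histories(4, TRUE)
  names(hs) <- vapply(hs, `[[`, "", "name")
  via_loss <- peaks_for_history(hs[["loss_then_three_copy_gain"]], ctx)
  via_loh <- peaks_for_history(hs[["cn_loh_then_mono_allelic_two_copy_gain"]], ctx)
  # oracle: direct evaluation of the peak formula at (4,0)
  st <- copy_state(4, 0)
  expect_equal(via_loss$location,
               vapply(c(1, 4), function(m) expected_maf_peak(ctx, st, m),
                      numeric(1)))
  expect_equal(via_loh$location,
               vapply(c(1, 3, 4), function(m) expected_maf_peak(ctx, st, m),
                      numeric(1)))
  extra <- setdiff(round(via_loh$location, 9), round(via_loss$location, 9))
  expect_length(extra, 1)
  expect_true(extra > min(via_loss$location) && extra < max(via_loss$location))
})

test_that("subclonal carrier fractions move peaks onto the mixture scale", {
  ctx <- sample_context(0.8)
  h <- Filter(function(x) x$name == "one_copy_gain",
              enumerate_histories(3, FALSE))[[1]]
  pk <- peaks_for_history(h, ctx, carrier_fraction = 0.5)
  # average copies: 0.5*3 + 0.5*2 = 2.5; shared het SNV sits at p*1/denom
  denom <- 0.8 * 2.5 + 2 * 0.2
  expect_true(any(abs(pk$location - 0.8 / denom) < 1e-9))
  expect_false(pk$clonal[1])
})
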