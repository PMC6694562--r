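cn_loh_history <- function() enumerate_histories(2, TRUE)[[1]]

test_that("the raw proportion is the literal before/after ratio", {
  est <- time_copy_event(2, 98, cn_loh_history())
  expect_equal(est$value, 0.02)
  expect_equal(est$method, "raw_proportion")
  expect_lte(est$ci_low, est$value)
  expect_gte(est$ci_high, est$value)
})

test_that("zero before-counts give a degenerate lower-boundary estimate", {
  est <- time_copy_event(0, 60, cn_loh_history())
  expect_equal(est$value, 0)
  expect_equal(est$ci_low, 0)
  expect_equal(est$flag, "degenerate")
  expect_error(time_copy_event(0, 0, cn_loh_history()),
               class = "tc_invalid_input")
  expect_error(time_copy_event(2, 3, cn_loh_history()),
               class = "tc_insufficient_data")
})

test_that("per-copy correction removes the CN-LOH timing bias", {
  # truth: event at t; before-counts accrue on 1 copy, after on 2, so the
  # raw proportion estimates t/(2-t) (closed-form bias of the raw estimator)
  t_true <- 0.5
  raws <- numeric(10); corrs <- numeric(10)
  for (i in 1:10) {
    set.seed(200 + i)
    n <- 2000
    nb <- rbinom(1, n, t_true / (t_true + 2 * (1 - t_true)))
    raws[i] <- time_copy_event(nb, n - nb, cn_loh_history(), n_boot = 100)$value
    corrs[i] <- time_copy_event(nb, n - nb, cn_loh_history(),
                                method = "per_copy_corrected",
                                n_boot = 100)$value
  }
  expect_equal(mean(raws), t_true / (2 - t_true), tolerance = 0.03)
  expect_equal(mean(corrs), t_true, tolerance = 0.03)
  expect_true(all(raws <= corrs))
})

test_that("timing estimates and their intervals stay inside [0, 1]", {
  h <- cn_loh_history()
  set.seed(5)
  for (i in 1:20) {
    nb <- sample(0:50, 1); na <- 50 - nb + sample(0:50, 1)
    for (m in c("raw_proportion", "per_copy_corrected")) {
      est <- time_copy_event(nb, na, h, method = m, n_boot = 200)
      expect_gte(est$ci_low, 0); expect_lte(est$ci_high, 1)
      expect_gte(est$value, est$ci_low); expect_lte(est$value, est$ci_high)
    }
  }
})

test_that("clonal expansion time is the clonal SNV proportion", {
  est <- time_clonal_expansion(rep(c(TRUE, FALSE), c(900, 100)))
  expect_equal(est$value, 0.9)
  expect_equal(time_clonal_expansion(rep(TRUE, 100))$value, 1)
  expect_error(time_clonal_expansion(logical(0)), class = "tc_invalid_input")
})

test_that("subclonal expansion timing needs two separated quantifiable peaks", {
  est <- time_subclonal_expansion(40, 60)
  expect_equal(est$value, 0.4)
  one <- time_subclonal_expansion(40, 60, peak_locations = 0.1)
  expect_equal(one$status, "not_quantifiable")
  near <- time_subclonal_expansion(40, 60, peak_locations = c(0.10, 0.12))
  expect_equal(near$status, "not_quantifiable")
  low <- time_subclonal_expansion(40, 60, peak_locations = c(0.06, 0.15),
                                  detection_lower = 0.06)
  expect_equal(low$status, "not_quantifiable")
})

test_that("zygosity classification separates full- from partial-copy SNVs", {
  ctx <- sample_context(0.74)
  st <- copy_state(2, 0)
  expect_equal(classify_zygosity(74, 100, st, ctx), "mut_homozygous")
  expect_equal(classify_zygosity(37, 100, st, ctx), "mut_heterozygous")
  expect_equal(classify_zygosity(3, 5, st, ctx), "undetermined")
  expect_error(classify_zygosity(6, 5, st, ctx), class = "tc_invalid_input")
})

test_that("driver mutations are placed as intervals, never points", {
  h <- cn_loh_history()
  t_loh <- timing_estimate(0.3, 0.2, 0.4, 30, 70, "raw_proportion")
  hom <- place_driver_event("mut_homozygous", h, t_loh)
  expect_equal(hom$interval, c(0, 0.3))
  het <- place_driver_event("mut_heterozygous", h, t_loh)
  expect_equal(het$interval, c(0.3, 1))
  neutral <- place_driver_event("mut_heterozygous",
                                enumerate_histories(2, FALSE)[[1]])
  expect_equal(neutral$interval, c(0, 1))
  und <- place_driver_event("undetermined", h, t_loh)
  expect_equal(und$interval, c(0, 1))
  expect_equal(und$flag, "undetermined_zygosity")
})

test_that("progression maps sort events and enforce pigeonhole nesting", {
  ev <- data.frame(label = c("expansion", "5q cn_loh", "3p cn_loh"),
                   time = c(0.9, 0.02, 0.68),
                   ci_low = c(0.89, 0, 0.6), ci_high = c(0.91, 0.05, 0.7))
  map <- build_progression_map(ev)
  expect_equal(map$events$label, c("5q cn_loh", "3p cn_loh", "expansion"))
  clones_bad <- data.frame(clone = c("major", "s1", "s2"),
                           parent = c(NA, "major", "major"),
                           fraction = c(1, 0.6, 0.6))
  expect_error(build_progression_map(ev, clones_bad),
               class = "tc_invalid_input")
  clones_ok <- data.frame(clone = c("major", "s1", "s2"),
                          parent = c(NA, "major", "major"),
                          fraction = c(1, 0.6, 0.4))
  expect_s3_class(build_progression_map(ev, clones_ok), "progression_map")
  expect_error(build_progression_map(ev[0, ]), class = "tc_invalid_input")
})

test_that("progression maps serialize to JSON and back", {
  ev <- data.frame(label = "cn_loh", time = 0.5, ci_low = 0.4, ci_high = 0.6)
  path <- tempfile(fileext = ".json")
  progression_map_json(build_progression_map(ev), path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$events$time, 0.5)
})
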