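#' Timing estimate on the mutational clock
#'
#' Constructor for timing results. Time is expressed on [0, 1] as the
#' fraction of mutational accrual elapsed before the event — a relative
#' clock: calendar calibration is impossible from a single sample because
#' mutation rates differ across tumors and over time.
#'
#' @param value Point estimate in [0, 1].
#' @param ci_low,ci_high 95% bootstrap percentile interval.
#' @param n_before,n_after SNV counts the estimate is based on.
#' @param method `"raw_proportion"` or `"per_copy_corrected"`.
#' @param flag Optional character note (e.g. `"degenerate"`).
#' @return An object of class `timing_estimate`.
#' @export
timing_estimate <- function(value, ci_low, ci_high, n_before, n_after,
                            method, flag = NA_character_) {
  stopifnot(value >= 0, value <= 1, ci_low <= value + 1e-12,
            ci_high >= value - 1e-12)
  structure(list(value = value, ci_low = max(0, ci_low),
                 ci_high = min(1, ci_high),
                 n_before = n_before, n_after = n_after,
                 method = method, flag = flag),
            class = "timing_estimate")
}

#' @export
print.timing_estimate <- function(x, ...) {
  cat(sprintf("<timing_estimate> %.3f [%.3f, %.3f] (%s; n=%d+%d)%s\n",
              x$value, x$ci_low, x$ci_high, x$method, x$n_before, x$n_after,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Select the evolutionary history best matching observed MAF peaks
#'
#' Compares observed MAF peak locations of a region with the expected peak
#' locations of every candidate history for its copy state (from
#' [enumerate_histories()]), scoring each candidate by the mass-weighted
#' mean absolute deviation of matched peaks plus penalties for unmatched
#' expected or observed peaks. Histories with distinct multiplicity-class
#' signatures — e.g. the two paths to a (4,0) state, one of which predicts
#' an extra interior peak — are thereby distinguishable.
#'
#' @param mafs Somatic SNV allele fractions of the region.
#' @param state Assigned [copy_state()] of the region (integer copies).
#' @param ctx A [sample_context()].
#' @param min_snvs Minimum SNVs required (default 20).
#' @param tol If the best score exceeds this, status is
#'   `"no_fitting_history"` (complex or subclonal histories are then often
#'   involved).
#' @param carrier_fraction Fraction of tumor cells carrying the state.
#' @return List with `history` (an `evolution_history` or `NULL`), `score`,
#'   `status` (`"ok"` or `"no_fitting_history"`), and `scores` for all
#'   candidates.
#' @export
infer_region_history <- function(mafs, state, ctx, min_snvs = 20,
                                 tol = 0.08, carrier_fraction = 1) {
  stopifnot(inherits(state, "copy_state"), inherits(ctx, "sample_context"))
  mafs <- mafs[!is.na(mafs)]
  if (length(mafs) < min_snvs) {
    stop_insufficient(
      sprintf("need at least %d SNVs to infer a history, got %d",
              min_snvs, length(mafs)),
      n_obs = length(mafs), n_required = min_snvs)
  }
  cands <- enumerate_histories(total_cn(state), is_loh(state))
  cands <- Filter(function(h) {
    h$final_state$major_cn == state$major_cn &&
      h$final_state$minor_cn == state$minor_cn
  }, cands)
  if (length(cands) == 0) stop_invalid("no candidate history for this state")
  obs <- find_peaks_and_valleys(smooth_density(mafs, min_obs = min_snvs))
  if (nrow(obs$peaks) == 0) stop_invalid("no MAF peaks found in the region")
  scores <- vapply(cands, function(h) {
    exp_pk <- peaks_for_history(h, ctx, carrier_fraction)$location
    match_peak_sets(obs$peaks, exp_pk)
  }, numeric(1))
  k <- which.min(scores)
  status <- if (scores[k] > tol) "no_fitting_history" else "ok"
  list(history = if (status == "ok") cands[[k]] else NULL,
       score = scores[k], status = status,
       scores = stats::setNames(scores, vapply(cands, `[[`, "", "name")),
       observed_peaks = obs$peaks)
}

# accrual rates (copies x class share) before and after a gain/LOH event:
#   A = copies accruing amplified classes (m > 1) before the event
#   B = copies accruing the unamplified class (m = 1) before the event
#   C = copies accruing after the event
event_rates <- function(history, event_index) {
  cl <- history$classes
  pre <- cl[cl$interval == event_index - 1L, , drop = FALSE]
  post <- cl[cl$interval == event_index, , drop = FALSE]
  list(A = sum(pre$copies[pre$m > 1]),
       B = sum(pre$copies[pre$m == 1]),
       C = sum(post$copies))
}

#' Time a copy gain or CN-LOH event from SNV multiplicity counts
#'
#' The raw estimate is the proportion of somatic SNVs before the
#' amplification: `n_before / (n_before + n_after)`, where `n_before` counts
#' SNVs in the amplified (multiplicity > 1) peak(s) and `n_after` the
#' unamplified peak. Because copies accrue mutations at different rates
#' before and after the event, the raw proportion is a biased estimate of
#' mutational time (for CN-LOH its expectation is `t / (2 - t)`); the
#' `"per_copy_corrected"` method inverts that bias using the accrual rates
#' implied by the history's multiplicity classes:
#'
#'   t_hat = r * C / (A - r * (A + B - C)),   r = n_before / (n_before + n_after)
#'
#' with A, B, C the per-unit-time copy counts accruing amplified-class SNVs
#' before, unamplified-class SNVs before, and any SNVs after the event.
#' The 95% CI comes from `n_boot` bootstrap resamples of the SNV labels
#' (percentile method).
#'
#' @param n_before,n_after SNV counts assigned before (amplified peak) and
#'   after (unamplified peak) the event.
#' @param history The region's `evolution_history`.
#' @param event_index Which event of the history to time (default: the last).
#' @param method `"raw_proportion"` (default; the literal proportion) or
#'   `"per_copy_corrected"`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param min_snvs Minimum total SNVs (default 20).
#' @return A [timing_estimate()].
#' @export
time_copy_event <- function(n_before, n_after, history,
                            event_index = NULL,
                            method = c("raw_proportion", "per_copy_corrected"),
                            n_boot = 1000, min_snvs = 20) {
  method <- match.arg(method)
  stopifnot(inherits(history, "evolution_history"))
  if (history$n_events < 1) stop_invalid("history has no events to time")
  event_index <- event_index %||% history$n_events
  n <- n_before + n_after
  if (n == 0) stop_invalid("no SNVs to time the event with")
  if (n < min_snvs) {
    stop_insufficient(sprintf("need at least %d SNVs, got %d", min_snvs, n),
                      n_obs = n, n_required = min_snvs)
  }
  rates <- event_rates(history, event_index)
  est <- function(nb) {
    r <- nb / n
    if (method == "raw_proportion") return(r)
    denom <- rates$A - r * (rates$A + rates$B - rates$C)
    if (denom <= 0) return(1)
    min(1, max(0, r * rates$C / denom))
  }
  value <- est(n_before)
  flag <- NA_character_
  if (n_before == 0 || n_after == 0) flag <- "degenerate"
  boot <- vapply(stats::rbinom(n_boot, n, n_before / n), est, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  timing_estimate(value, min(ci[1], value), max(ci[2], value),
                  n_before, n_after, method, flag)
}

boot_proportion <- function(k, n, n_boot) {
  boot <- stats::rbinom(n_boot, n, k / n) / n
  stats::quantile(boot, c(0.025, 0.975), names = FALSE)
}

#' Time the major clonal expansion
#'
#' The clonal expansion is timed as the proportion of clonal SNVs out of all
#' somatic SNVs, using only regions with one or two total copies, where the
#' subclonal MAF peaks are well separated from clonal ones (on higher copy
#' numbers unamplified clonal SNVs blend into the subclonal range).
#'
#' @param is_clonal Logical vector: one entry per SNV in eligible (1- or
#'   2-copy) regions, `TRUE` for clonal.
#' @param n_boot Bootstrap replicates for the 95% CI.
#' @param min_snvs Minimum SNV count.
#' @return A [timing_estimate()].
#' @export
time_clonal_expansion <- function(is_clonal, n_boot = 1000, min_snvs = 50) {
  is_clonal <- is_clonal[!is.na(is_clonal)]
  n <- length(is_clonal)
  if (n == 0) stop_invalid("no SNVs in eligible regions")
  if (n < min_snvs) {
    stop_insufficient(sprintf("need at least %d SNVs, got %d", min_snvs, n),
                      n_obs = n, n_required = min_snvs)
  }
  k <- sum(is_clonal)
  ci <- boot_proportion(k, n, n_boot)
  timing_estimate(k / n, min(ci[1], k / n), max(ci[2], k / n),
                  n_before = k, n_after = n - k, method = "raw_proportion",
                  flag = if (k == 0 || k == n) "degenerate" else NA_character_)
}

#' Time a subclonal expansion from two subclonal MAF peaks
#'
#' When the subclonal MAF distribution shows two well-separated peaks —
#' evidence of a further expansion within the subclone — its timing is the
#' proportion of subclonal SNVs in the higher-MAF peak (those accrued before
#' the second expansion).
#'
#' @param n_peak_high,n_peak_low SNV counts in the higher- and lower-MAF
#'   subclonal peaks.
#' @param peak_locations Optional numeric length-2 vector of the peak
#'   locations; used for the separation / detection-limit checks.
#' @param detection_lower Lower allele-fraction detection bound; a peak
#'   below `detection_lower + margin` makes the timing not quantifiable.
#' @param min_separation Minimum distance between the two peaks.
#' @param margin Safety margin above the detection bound (default 0.02).
#' @param n_boot Bootstrap replicates.
#' @return A [timing_estimate()], or a list with `status =
#'   "not_quantifiable"` and a `reason` when the peaks are unusable.
#' @export
time_subclonal_expansion <- function(n_peak_high, n_peak_low,
                                     peak_locations = NULL,
                                     detection_lower = 0,
                                     min_separation = 0.04,
                                     margin = 0.02, n_boot = 1000) {
  if (!is.null(peak_locations)) {
    if (length(peak_locations) < 2) {
      return(list(status = "not_quantifiable", reason = "single subclonal peak"))
    }
    if (abs(diff(sort(peak_locations)[1:2])) < min_separation) {
      return(list(status = "not_quantifiable", reason = "peaks unseparated"))
    }
    if (min(peak_locations) < detection_lower + margin) {
      return(list(status = "not_quantifiable",
                  reason = "peak too close to detection limit"))
    }
  }
  n <- n_peak_high + n_peak_low
  if (n == 0) stop_invalid("no subclonal SNVs")
  ci <- boot_proportion(n_peak_high, n, n_boot)
  v <- n_peak_high / n
  timing_estimate(v, min(ci[1], v), max(ci[2], v),
                  n_before = n_peak_high, n_after = n_peak_low,
                  method = "raw_proportion")
}

#' Call whole-genome duplication from per-region duplication timings
#'
#' A genome duplication manifests as CN-LOH, one-copy gains and bi-allelic
#' (two or more)-copy gains across many chromosomes, all at the same
#' mutational time. Regions are clustered by timing (two timings are
#' synchronous when they differ by at most `sync_tol` or their 95% CIs
#' overlap; clusters are grown by single linkage) and the genome fraction of
#' the largest cluster is computed over chromosomes 1–22 plus X, counting a
#' chromosome arm as half a chromosome. GD is called when that fraction
#' exceeds 0.5 — sequential per-chromosome duplications spread over time do
#' not qualify. The GD time is the inverse-variance-weighted mean of the
#' member timings.
#'
#' @param regions Data frame with one row per duplicated region and columns
#'   `chrom`, `weight` (1 whole chromosome, 0.5 arm), `time`, `ci_low`,
#'   `ci_high`.
#' @param sync_tol Synchrony tolerance in mutational time (default 0.1).
#' @param genome_chromosomes Number of chromosomes making up the genome
#'   (default 23: autosomes plus X).
#' @return An object of class `gd_call`: list with `is_gd`,
#'   `fraction_genome_co_duplicated`, `gd_time` (a [timing_estimate()] or
#'   `NULL`), `member_regions` (row indices of the winning cluster), and
#'   `clusters`.
#' @export
call_genome_duplication <- function(regions, sync_tol = 0.1,
                                    genome_chromosomes = 23) {
  empty <- structure(list(is_gd = FALSE, fraction_genome_co_duplicated = 0,
                          gd_time = NULL, member_regions = integer(0),
                          clusters = list()),
                     class = "gd_call")
  if (is.null(regions) || nrow(regions) == 0) return(empty)
  regions <- as.data.frame(regions)
  stopifnot(all(c("chrom", "weight", "time") %in% names(regions)))
  if (is.null(regions$ci_low)) regions$ci_low <- regions$time
  if (is.null(regions$ci_high)) regions$ci_high <- regions$time
  n <- nrow(regions)
  # single-linkage clustering under the synchrony relation
  synced <- function(i, j) {
    abs(regions$time[i] - regions$time[j]) <= sync_tol ||
      (regions$ci_low[i] <= regions$ci_high[j] &&
         regions$ci_low[j] <= regions$ci_high[i])
  }
  cluster_id <- seq_len(n)
  repeat {
    merged <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cluster_id[i] != cluster_id[j] && synced(i, j)) {
        cluster_id[cluster_id == cluster_id[j]] <- cluster_id[i]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  clusters <- split(seq_len(n), cluster_id)
  frac <- vapply(clusters, function(ix) {
    # a chromosome contributes at most its full weight once
    sum(tapply(regions$weight[ix], regions$chrom[ix], function(w) min(1, sum(w))))
  }, numeric(1)) / genome_chromosomes
  best <- which.max(frac)
  members <- clusters[[best]]
  gd_time <- pooled_timing(regions[members, , drop = FALSE])
  structure(list(is_gd = unname(frac[best]) > 0.5,
                 fraction_genome_co_duplicated = unname(frac[best]),
                 gd_time = gd_time, member_regions = members,
                 clusters = unname(clusters)),
            class = "gd_call")
}

pooled_timing <- function(members) {
  se <- (members$ci_high - members$ci_low) / (2 * 1.96)
  w <- ifelse(se > 0, 1 / se^2, max(1 / pmax(se, 1e-6)^2))
  v <- sum(w * members$time) / sum(w)
  se_pool <- sqrt(1 / sum(w))
  timing_estimate(min(1, max(0, v)),
                  max(0, v - 1.96 * se_pool), min(1, v + 1.96 * se_pool),
                  n_before = nrow(members), n_after = 0L,
                  method = "raw_proportion", flag = "pooled")
}

#' Classify the zygosity of a somatic SNV
#'
#' Tests whether an SNV sits on all tumor copies (mut_homozygous) or only
#' some (mut_heterozygous) by comparing the exact binomial confidence
#' interval of its observed allele fraction against the expected peaks for
#' multiplicity equal to the total copy number versus lower multiplicities.
#' When the interval is compatible with both (e.g. at low depth),
#' `"undetermined"` is returned.
#'
#' @param alt_count,depth Read counts at the SNV.
#' @param state The region's [copy_state()].
#' @param ctx A [sample_context()].
#' @param conf Confidence level of the binomial interval (default 0.95).
#' @return One of `"mut_homozygous"`, `"mut_heterozygous"`, `"undetermined"`.
#' @export
classify_zygosity <- function(alt_count, depth, state, ctx, conf = 0.95) {
  stopifnot(inherits(state, "copy_state"), inherits(ctx, "sample_context"))
  if (depth < 1 || alt_count < 0 || alt_count > depth) {
    stop_invalid("need 0 <= alt_count <= depth, depth >= 1")
  }
  ci <- stats::binom.test(alt_count, depth, conf.level = conf)$conf.int
  tot <- total_cn(state)
  hom_peak <- expected_maf_peak(ctx, state, tot)
  het_peaks <- if (tot > 1) {
    vapply(seq_len(tot - 1), function(m) expected_maf_peak(ctx, state, m),
           numeric(1))
  } else numeric(0)
  hom_ok <- ci[1] <= hom_peak && hom_peak <= ci[2]
  het_ok <- length(het_peaks) > 0 && any(ci[1] <= het_peaks & het_peaks <= ci[2])
  if (hom_ok && !het_ok) "mut_homozygous"
  else if (het_ok && !hom_ok) "mut_heterozygous"
  else "undetermined"
}

#' Place a driver mutation in the event timeline
#'
#' Point mutations cannot be timed to a point: their multiplicity class only
#' brackets them between events. A mutation on all copies of a CN-LOH (or
#' gained) region must predate the event; one on a single copy must
#' postdate it; on a copy-neutral region the whole lifetime is possible.
#'
#' @param zygosity Output of [classify_zygosity()].
#' @param history The region's `evolution_history`.
#' @param event_time Optional [timing_estimate()] of the history's (last)
#'   event; its value is used as the interval boundary, else `NA`.
#' @return A list with `interval` (`c(start, end)`, entries may be `NA` when
#'   no timing is supplied), `description`, and `flag`
#'   (`"undetermined_zygosity"` gives the whole lifetime).
#' @export
place_driver_event <- function(zygosity, history, event_time = NULL) {
  stopifnot(inherits(history, "evolution_history"))
  t_ev <- if (inherits(event_time, "timing_estimate")) event_time$value else NA_real_
  if (history$n_events == 0) {
    return(list(interval = c(0, 1), description = "any time (copy-neutral region)",
                flag = NA_character_))
  }
  ev_name <- history$name
  if (identical(zygosity, "mut_homozygous")) {
    list(interval = c(0, t_ev),
         description = sprintf("before %s", ev_name), flag = NA_character_)
  } else if (identical(zygosity, "mut_heterozygous")) {
    list(interval = c(t_ev, 1),
         description = sprintf("after %s", ev_name), flag = NA_character_)
  } else {
    list(interval = c(0, 1), description = "any time (zygosity undetermined)",
         flag = "undetermined_zygosity")
  }
}

#' Assemble a tumor progression map
#'
#' Orders all timed events (copy events, clonal and subclonal expansions,
#' GD) by their timing values, attaches driver placements, and validates the
#' clone tree against the pigeonhole principle: the fractions of sibling
#' subclones may not sum beyond their parent clone's fraction, and a child
#' may not exceed its parent.
#'
#' @param events Data frame with columns `label`, `time`, `ci_low`,
#'   `ci_high`, and optionally `kind`.
#' @param clones Optional data frame describing the clone tree: columns
#'   `clone`, `parent` (`NA` for the root), `fraction` (of tumor cells).
#' @param drivers Optional list of driver placements (from
#'   [place_driver_event()]), named by gene.
#' @return An object of class `progression_map` (events sorted by time).
#'   A pigeonhole violation raises a `tc_invalid_input` error naming the
#'   offending clones.
#' @export
build_progression_map <- function(events, clones = NULL, drivers = NULL) {
  events <- as.data.frame(events)
  if (nrow(events) == 0) stop_invalid("no events to map")
  stopifnot(all(c("label", "time") %in% names(events)))
  if (!is.null(clones)) {
    clones <- as.data.frame(clones)
    for (p in unique(clones$parent)) {
      if (is.na(p)) next
      parent_frac <- clones$fraction[clones$clone == p]
      kids <- clones[!is.na(clones$parent) & clones$parent == p, ]
      if (length(parent_frac) != 1) {
        stop_invalid(sprintf("clone tree references unknown parent '%s'", p))
      }
      if (sum(kids$fraction) > parent_frac + 1e-9) {
        stop_invalid(sprintf(
          "pigeonhole violation: children of clone '%s' (%s) sum to %.3f > parent fraction %.3f",
          p, paste(kids$clone, collapse = ", "), sum(kids$fraction), parent_frac))
      }
    }
  }
  events <- events[order(events$time), , drop = FALSE]
  structure(list(events = events, clones = clones, drivers = drivers),
            class = "progression_map")
}

#' @export
print.progression_map <- function(x, ...) {
  cat("<progression_map>\n")
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' Serialize a progression map to JSON
#'
#' @param map A `progression_map`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
progression_map_json <- function(map, path = NULL) {
  stopifnot(inherits(map, "progression_map"))
  obj <- list(events = map$events,
              clones = map$clones,
              drivers = map$drivers)
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           pretty = TRUE, na = "null", digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
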