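#' A ready-made genome-scale simulation layout
#'
#' A tumor emulating the canonical worked example of the method: purity
#' 0.74; a very early CN-LOH (t = 0.02) on one chromosome and a later one
#' (t = 0.68) on another; a one-copy gain at t = 0.66; a bi-allelic
#' two-copy gain at t = 0.71; several copy-neutral chromosomes; clonal
#' expansion at 0.9 with a 0.3-fraction subclone.
#'
#' @param seed RNG seed for the config.
#' @param snv_rate_per_mb Mutation rate knob (default 12).
#' @param purity Tumor purity (default 0.74).
#' @return A [simulation_config()].
#' @export
example_config <- function(seed = 1L, snv_rate_per_mb = 12, purity = 0.74) {
  sizes <- default_chrom_sizes()
  seg <- function(chrom, history, t1 = NA, t2 = NA) {
    data.frame(chrom = chrom, start = 1, end = unname(sizes[chrom]),
               history = history, t1 = t1, t2 = t2)
  }
  segments <- rbind(
    seg("5", "cn_loh", 0.02),
    seg("3", "cn_loh", 0.68),
    seg("6", "one_copy_gain", 0.66),
    seg("7", "bi_allelic_two_copy_gain", 0.71),
    seg("1", "copy_neutral"),
    seg("2", "copy_neutral"),
    seg("10", "copy_neutral"),
    seg("15", "copy_neutral"),
    seg("22", "copy_neutral")
  )
  simulation_config(purity = purity, segments = segments,
                    snv_rate_per_mb = snv_rate_per_mb, seed = seed)
}

snvs_by_segment <- function(snvs, segments) {
  lapply(seq_len(nrow(segments)), function(i) {
    sel <- snvs$chrom == segments$chrom[i] &
      snvs$pos >= segments$start[i] & snvs$pos <= segments$end[i]
    snvs[sel, , drop = FALSE]
  })
}

# map observed peaks to multiplicity classes of `state` under `ctx`;
# peaks below the lowest clonal expectation are subclonal
classify_region_peaks <- function(fitted, state, ctx, tol = 0.05) {
  exp_pk <- vapply(seq_len(total_cn(state)), function(m) {
    expected_maf_peak(ctx, state, m)
  }, numeric(1))
  loc <- fitted$peaks$location
  cls <- vapply(loc, function(x) {
    dev <- abs(x - exp_pk)
    m <- which.min(dev)
    if (dev[m] <= tol) m
    else if (x < min(exp_pk) - tol) 0L  # subclonal
    else m
  }, numeric(1))
  as.integer(cls)
}

#' Reconstruct the full progression history of one tumor
#'
#' Chains the pipeline stages: purity/ploidy fitting from segments (validated
#' and, where needed, adjusted against somatic MAF peaks), per-region history
#' selection, mutational-clock timing of copy events and the clonal
#' expansion, genome-duplication calling, the neutral-evolution test and
#' kataegis detection, assembled into a progression map.
#'
#' @param snvs Somatic SNV table (`chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `maf`).
#' @param segments Segment table (`chrom`, `start`, `end`, `copy_ratio`,
#'   optional `baf`), 1-based inclusive.
#' @param snps Optional germline heterozygous SNP table (`chrom`, `pos`,
#'   `baf`); used to fill missing segment BAFs (folded median).
#' @param coverage Mean tumor coverage, for the detection-power model.
#' @param purity Optional known purity; skips the grid fit when given.
#' @param chrom_sizes Chromosome lengths for arm weighting in the GD call.
#' @param timing_method Timing estimator (see [time_copy_event()]); the
#'   pipeline defaults to `"per_copy_corrected"`, which is unbiased on the
#'   mutational-time axis (the raw proportion under-estimates gain times
#'   because post-event copies accrue mutations faster).
#' @param min_snvs_region Minimum SNVs to analyze a region.
#' @param seed Seed for the stochastic stages (detection power, bootstrap).
#' @return A list of class `tumorclock_report` with elements `purity`,
#'   `solution`, `regions` (per-segment history, timing, counts), `clonal_expansion`,
#'   `gd`, `neutrality`, `kataegis`, `progression` (a `progression_map` or
#'   `NULL`).
#' @export
run_pipeline <- function(snvs, segments, snps = NULL, coverage = 60,
                         purity = NULL, chrom_sizes = default_chrom_sizes(),
                         timing_method = "per_copy_corrected",
                         min_snvs_region = 50, seed = 1L) {
  set.seed(seed)
  segments <- as.data.frame(segments)
  snvs <- as.data.frame(snvs)
  if (is.null(segments$baf) && !is.null(snps)) {
    segments$baf <- vapply(seq_len(nrow(segments)), function(i) {
      sel <- snps$chrom == segments$chrom[i] &
        snps$pos >= segments$start[i] & snps$pos <= segments$end[i]
      if (sum(sel) < 10) return(NA_real_)
      estimate_segment_baf(snps$b_count[sel], snps$depth[sel])
    }, numeric(1))
  }
  groups <- snvs_by_segment(snvs, segments)
  maf_groups <- lapply(groups, function(g) g$maf)

  # --- purity and copy states ---
  if (is.null(purity)) {
    sols <- fit_candidates(segments)
    sol <- sols[[1]]
    if (isTRUE(sol$no_major_copy_changes)) {
      purity <- purity_from_snvs(unlist(maf_groups))
      sols <- fit_candidates(segments, purity_grid = purity)
      sol <- sols[[1]]
    }
    sol <- validate_with_mafs(sol, maf_groups)
    purity <- sol$purity
  } else {
    sol <- fit_candidates(segments, purity_grid = purity)[[1]]
    sol <- validate_with_mafs(sol, maf_groups)
  }
  ctx <- sample_context(purity, mean_depth = coverage)
  seg_states <- sol$segment_states

  # --- per-region history and timing ---
  regions <- vector("list", nrow(seg_states))
  clonal_labels <- list()
  for (i in seq_len(nrow(seg_states))) {
    st <- copy_state(seg_states$major_cn[i], seg_states$minor_cn[i])
    g <- maf_groups[[i]]
    if (length(g) < min_snvs_region) {
      regions[[i]] <- list(status = "too_few_snvs", state = st)
      next
    }
    inf <- tryCatch(
      infer_region_history(g, st, ctx, min_snvs = min_snvs_region),
      tumorclock_error = function(e) NULL)
    if (is.null(inf) || inf$status != "ok") {
      regions[[i]] <- list(status = inf$status %||% "error", state = st)
      next
    }
    fitted <- find_peaks_and_valleys(smooth_density(g, min_obs = min_snvs_region))
    cls <- classify_region_peaks(fitted, st, ctx)
    asg <- assign_snvs(g, fitted)
    counts_by_class <- tapply(asg$counts, cls, sum)
    n_before <- sum(asg$counts[cls > 1])
    n_after <- sum(asg$counts[cls <= 1])
    timing <- NULL
    if (inf$history$n_events > 0 && n_before + n_after >= min_snvs_region) {
      timing <- tryCatch(
        time_copy_event(n_before, n_after, inf$history,
                        method = timing_method),
        tumorclock_error = function(e) NULL)
    }
    # clonal/subclonal labels from 1- and 2-copy regions
    if (total_cn(st) %in% c(1L, 2L)) {
      clonal_labels[[length(clonal_labels) + 1]] <- cls[asg$labels] > 0
    }
    regions[[i]] <- list(
      status = "ok", state = st, history = inf$history,
      score = inf$score, timing = timing,
      n_before = n_before, n_after = n_after,
      n_subclonal = sum(asg$counts[cls == 0]),
      chrom = seg_states$chrom[i],
      counts_by_class = counts_by_class)
  }

  # --- clonal expansion ---
  expansion <- NULL
  labels <- unlist(clonal_labels)
  if (length(labels) >= 50) {
    expansion <- time_clonal_expansion(labels)
  }

  # --- genome duplication ---
  dup_names_re <- "cn_loh$|one_copy_gain$|^bi_allelic|^cn_loh_then|^loss_then"
  dup_rows <- list()
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (!identical(r$status, "ok") || is.null(r$timing)) next
    if (!grepl(dup_names_re, r$history$name)) next
    size <- chrom_sizes[[as.character(r$chrom)]] %||% NA
    span <- seg_states$end[i] - seg_states$start[i] + 1
    w <- if (!is.na(size) && span >= 0.8 * size) 1 else 0.5
    dup_rows[[length(dup_rows) + 1]] <- data.frame(
      chrom = r$chrom, weight = w, time = r$timing$value,
      ci_low = r$timing$ci_low, ci_high = r$timing$ci_high)
  }
  gd <- call_genome_duplication(
    if (length(dup_rows)) do.call(rbind, dup_rows) else NULL)

  # --- neutral evolution test on 1-2 copy regions ---
  neutral <- NULL
  tot_by_seg <- seg_states$major_cn + seg_states$minor_cn
  eligible_mafs <- unlist(maf_groups[tot_by_seg %in% c(1L, 2L)])
  if (length(eligible_mafs) >= 500) {
    pw <- detection_power(coverage, seed = seed + 1L)
    b <- subclonal_bounds(eligible_mafs, pw)
    if (identical(b$status, "ok")) {
      neutral <- neutrality_test(eligible_mafs, b$lower, b$upper)
    } else {
      neutral <- b
    }
  }

  # --- kataegis ---
  kat <- tryCatch(detect_kataegis(rainfall(snvs)),
                  tumorclock_error = function(e) NULL)

  # --- progression map ---
  ev <- list()
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (!identical(r$status, "ok") || is.null(r$timing)) next
    ev[[length(ev) + 1]] <- data.frame(
      label = sprintf("chr%s %s", r$chrom, r$history$name),
      kind = "copy_event", time = r$timing$value,
      ci_low = r$timing$ci_low, ci_high = r$timing$ci_high)
  }
  if (!is.null(expansion)) {
    ev[[length(ev) + 1]] <- data.frame(
      label = "clonal expansion", kind = "expansion",
      time = expansion$value, ci_low = expansion$ci_low,
      ci_high = expansion$ci_high)
  }
  if (isTRUE(gd$is_gd)) {
    ev[[length(ev) + 1]] <- data.frame(
      label = "genome duplication", kind = "gd", time = gd$gd_time$value,
      ci_low = gd$gd_time$ci_low, ci_high = gd$gd_time$ci_high)
  }
  progression <- if (length(ev)) {
    build_progression_map(do.call(rbind, ev))
  } else NULL

  structure(list(purity = purity, solution = sol, regions = regions,
                 clonal_expansion = expansion, gd = gd,
                 neutrality = neutral, kataegis = kat,
                 progression = progression),
            class = "tumorclock_report")
}

#' @export
print.tumorclock_report <- function(x, ...) {
  cat(sprintf("<tumorclock_report> purity %.2f (%s)\n", x$purity,
              x$solution$status))
  ok <- sum(vapply(x$regions, function(r) identical(r$status, "ok"), logical(1)))
  cat(sprintf("  regions analyzed: %d/%d\n", ok, length(x$regions)))
  if (!is.null(x$clonal_expansion)) {
    cat(sprintf("  clonal expansion: %.2f [%.2f, %.2f]\n",
                x$clonal_expansion$value, x$clonal_expansion$ci_low,
                x$clonal_expansion$ci_high))
  }
  cat(sprintf("  genome duplication: %s (fraction %.2f)\n",
              x$gd$is_gd, x$gd$fraction_genome_co_duplicated))
  if (!is.null(x$neutrality) && inherits(x$neutrality, "neutrality_result")) {
    print(x$neutrality)
  }
  invisible(x)
}
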