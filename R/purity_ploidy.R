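#' Grid fit of tumor purity and per-segment copy states
#'
#' For every purity on the grid, each segment is assigned the integer
#' allele-specific copy state (n1, n2) minimizing the squared deviation of
#' its expected copy ratio and BAF from the observed values; solutions are
#' ranked by the mean of those per-segment deviations. Because purity and
#' ploidy are jointly underdetermined, solutions whose scores tie within
#' `tie_tol` are all retained — including the classical degeneracy where a
#' subclonal one-copy gain in 80% of cells is indistinguishable from a
#' two-copy gain in 40% on ratio and BAF alone (somatic MAFs break such
#' ties; see [validate_with_mafs()]).
#'
#' Segments whose ratio sits between integer expectations by more than
#' `subclonal_tol` are interpreted as subclonal copy changes: for each
#' candidate altered state the carried fraction is solved from the ratio
#' (see [subclone_fraction_from_ratio()]) and interpretations consistent
#' with the BAF are kept, ordered by the smallest number of copy changes.
#'
#' @param segments Data frame with columns `chrom`, `start`, `end`,
#'   `copy_ratio` and optionally `baf` (folded minor-allele BAF, <= 0.5;
#'   `NA` allowed).
#' @param purity_grid Purities to scan (default `seq(0.1, 1, 0.01)`).
#' @param max_total_cn Largest total copy number considered per segment.
#' @param baf_weight Relative weight of the squared BAF deviation (default
#'   5: segment BAFs pooled over thousands of SNPs are far more precise than
#'   a segment's copy ratio).
#' @param tie_tol Solutions within this score of the best are retained.
#' @param subclonal_tol Residual ratio deviation above which a segment is
#'   re-interpreted as a subclonal change.
#' @param normal_cn Normal copies for all segments (2 for autosomes).
#' @return A list of `purity_solution` objects, best first. Each carries
#'   `purity`, `segment_states` (data frame with assigned `major_cn`,
#'   `minor_cn`, `clonal_flag`, `subclone_fraction`, per-segment residual),
#'   `fit_score`, `alternatives` (per-segment list of tied subclonal
#'   interpretations), and `no_major_copy_changes` (purity unidentifiable
#'   from segments alone when every segment is diploid-like).
#' @export
fit_candidates <- function(segments, purity_grid = seq(0.1, 1, by = 0.01),
                           max_total_cn = 4, baf_weight = 5,
                           tie_tol = 1e-6, subclonal_tol = 0.08,
                           normal_cn = 2) {
  segments <- as.data.frame(segments)
  if (nrow(segments) == 0) stop_invalid("no segments supplied")
  if (!all(c("copy_ratio") %in% names(segments))) {
    stop_invalid("segments need a `copy_ratio` column")
  }
  if (any(segments$copy_ratio <= 0)) stop_invalid("copy ratios must be > 0")
  if (any(purity_grid <= 0 | purity_grid > 1)) {
    stop_invalid("purity grid must lie in (0, 1]")
  }
  if (is.null(segments$baf)) segments$baf <- NA_real_

  states <- integer_states(max_total_cn)
  # purities are ranked on clonal-only assignments: a subclonal
  # reinterpretation can absorb arbitrary ratio error (its fraction is
  # solved from the ratio), so letting it into the score would flatten the
  # purity landscape
  sols <- lapply(purity_grid, function(p) {
    ctx <- sample_context(p, normal_cn = normal_cn)
    fit <- fit_segments_at_purity(segments, ctx, states, baf_weight,
                                  subclonal_tol = Inf)
    structure(list(purity = p,
                   segment_states = fit$assign,
                   fit_score = fit$score,
                   alternatives = fit$alternatives,
                   maf_consistency = NA_real_,
                   status = "unvalidated",
                   no_major_copy_changes = fit$all_diploid,
                   normal_cn = normal_cn),
              class = "purity_solution")
  })
  scores <- vapply(sols, function(s) s$fit_score, numeric(1))
  sols <- sols[order(scores)]
  scores <- sort(scores)
  # drop clearly-worse purities but keep all ties with the best
  keep <- scores <= scores[1] + max(tie_tol, 1e-12)
  if (sum(keep) < length(sols)) keep <- keep | seq_along(sols) <= 5
  sols <- sols[keep]
  # subclonal reinterpretation of poorly-fitting segments, per solution
  lapply(sols, function(s) {
    ctx <- sample_context(s$purity, normal_cn = normal_cn)
    fit <- fit_segments_at_purity(segments, ctx, states, baf_weight,
                                  subclonal_tol = subclonal_tol)
    s$segment_states <- fit$assign
    s$alternatives <- fit$alternatives
    s
  })
}

integer_states <- function(max_total) {
  grid <- expand.grid(major = 0:max_total, minor = 0:max_total)
  grid <- grid[grid$major >= grid$minor &
                 grid$major + grid$minor >= 1 &
                 grid$major + grid$minor <= max_total, ]
  grid[order(grid$major + grid$minor), ]
}

fit_segments_at_purity <- function(segments, ctx, states, baf_weight,
                                   subclonal_tol) {
  n <- nrow(segments)
  assign <- data.frame(
    chrom = segments$chrom %||% rep(NA, n),
    start = segments$start %||% rep(NA, n),
    end = segments$end %||% rep(NA, n),
    copy_ratio = segments$copy_ratio, baf = segments$baf,
    major_cn = NA_integer_, minor_cn = NA_integer_,
    clonal_flag = TRUE, subclone_fraction = 1, residual = NA_real_)
  alternatives <- vector("list", n)
  for (i in seq_len(n)) {
    obs_r <- segments$copy_ratio[i]
    obs_b <- segments$baf[i]
    sc <- vapply(seq_len(nrow(states)), function(j) {
      st <- copy_state(states$major[j], states$minor[j])
      er <- expected_copy_ratio(ctx, st)
      eb <- expected_baf(ctx, st)$baf
      (obs_r - er)^2 + if (is.na(obs_b)) 0 else baf_weight * (obs_b - eb)^2
    }, numeric(1))
    j <- which.min(sc)
    assign$major_cn[i] <- states$major[j]
    assign$minor_cn[i] <- states$minor[j]
    assign$residual[i] <- sc[j]
    best_state <- copy_state(states$major[j], states$minor[j])
    ratio_dev <- abs(obs_r - expected_copy_ratio(ctx, best_state))
    if (is.finite(subclonal_tol) && ratio_dev > subclonal_tol) {
      alts <- subclonal_interpretations(obs_r, obs_b, ctx, states, baf_weight)
      if (nrow(alts) > 0) {
        # keep the clonal assignment on the candidate list: MAF validation
        # may still prefer it over any between-integer interpretation
        alts <- rbind(alts, data.frame(
          major = best_state$major_cn, minor = best_state$minor_cn,
          fraction = 1, delta_copies = abs(total_cn(best_state) - 2),
          score = sc[j]))
        assign$major_cn[i] <- alts$major[1]
        assign$minor_cn[i] <- alts$minor[1]
        assign$clonal_flag[i] <- alts$fraction[1] >= 1
        assign$subclone_fraction[i] <- alts$fraction[1]
        assign$residual[i] <- alts$score[1]
        alternatives[[i]] <- alts
      }
    }
  }
  diploid <- assign$major_cn == 1 & assign$minor_cn == 1 &
    abs(assign$copy_ratio - 1) < 0.05 &
    (is.na(assign$baf) | abs(assign$baf - 0.5) < 0.05)
  list(assign = assign, score = mean(assign$residual),
       alternatives = alternatives, all_diploid = all(diploid))
}

subclonal_interpretations <- function(obs_r, obs_b, ctx, states, baf_weight,
                                      tie_tol = 1e-6) {
  bg <- copy_state(1, 1)
  rows <- lapply(seq_len(nrow(states)), function(j) {
    st_tot <- states$major[j] + states$minor[j]
    if (st_tot == 2 && states$minor[j] == 1) return(NULL)  # background itself
    alt <- copy_state(states$major[j], states$minor[j])
    phi <- tryCatch(
      subclone_fraction_from_ratio(obs_r, ctx, bg, alt, quiet = TRUE),
      tumorclock_error = function(e) NA_real_)
    if (is.na(phi) || phi <= 0.01 || phi > 1) return(NULL)
    alt$clone_fraction <- phi
    eb <- expected_baf(ctx, list(alt))$baf
    score <- if (is.na(obs_b)) 0 else baf_weight * (obs_b - eb)^2
    data.frame(major = alt$major_cn, minor = alt$minor_cn, fraction = phi,
               delta_copies = abs(st_tot - 2), score = score)
  })
  alts <- do.call(rbind, rows)
  if (is.null(alts)) return(data.frame())
  alts <- alts[alts$score <= min(alts$score) + tie_tol, , drop = FALSE]
  # smallest-possible-number-of-copy-changes preference among ties
  alts[order(alts$delta_copies, alts$score), , drop = FALSE]
}

#' Solve the fraction of tumor cells carrying a subclonal copy change
#'
#' Inverts the linear copy-ratio expectation for the mixing fraction phi of
#' an altered state against a background state:
#' `ratio = (p * (phi * T_alt + (1 - phi) * T_bg) + nc * (1 - p)) / nc`.
#'
#' @param observed_ratio Observed copy ratio of the segment.
#' @param ctx A [sample_context()].
#' @param background_state,altered_state [copy_state()]s with different
#'   total copy numbers.
#' @param tol Out-of-range tolerance before clamping triggers a warning.
#' @param quiet Suppress the clamping warning.
#' @return Fraction in [0, 1] (clamped; a warning is emitted when the
#'   unclamped solution is outside by more than `tol`).
#' @export
subclone_fraction_from_ratio <- function(observed_ratio, ctx,
                                         background_state, altered_state,
                                         tol = 0.05, quiet = FALSE) {
  stopifnot(inherits(ctx, "sample_context"))
  t_bg <- total_cn(background_state)
  t_alt <- total_cn(altered_state)
  if (t_bg == t_alt) {
    stop_invalid("background and altered states have the same total copy number")
  }
  p <- ctx$purity
  nc <- ctx$normal_cn
  phi <- (nc * observed_ratio - p * t_bg - nc * (1 - p)) / (p * (t_alt - t_bg))
  if ((phi < -tol || phi > 1 + tol) && !quiet) {
    warning(sprintf("subclone fraction %.3f outside [0, 1]; clamped", phi))
  }
  min(1, max(0, phi))
}

#' Infer purity from somatic SNVs in copy-neutral regions
#'
#' For tumors without major copy changes (typically hyper- and ultra-mutated
#' ones) purity cannot be read off segments; instead the right-most clonal
#' MAF peak of SNVs in (1,1) regions sits at p/2, so purity is twice its
#' location.
#'
#' @param mafs Allele fractions of somatic SNVs in copy-neutral regions.
#' @param min_snvs Minimum number of SNVs required (default 100).
#' @param min_weight Peaks holding less than this fraction of SNVs are
#'   ignored when picking the right-most clonal peak (default 0.05).
#' @param ... Passed to [smooth_density()].
#' @return Estimated purity in (0, 1].
#' @export
purity_from_snvs <- function(mafs, min_snvs = 100, min_weight = 0.05, ...) {
  mafs <- mafs[!is.na(mafs)]
  if (length(mafs) < min_snvs) {
    stop_insufficient(
      sprintf("need at least %d copy-neutral SNVs, got %d", min_snvs, length(mafs)),
      n_obs = length(mafs), n_required = min_snvs)
  }
  curve <- smooth_density(mafs, ...)
  fitted <- find_peaks_and_valleys(curve)
  pk <- fitted$peaks[fitted$peaks$weight >= min_weight, , drop = FALSE]
  if (nrow(pk) == 0) pk <- fitted$peaks
  if (nrow(pk) == 0) stop_invalid("no MAF peak found in copy-neutral regions")
  min(1, 2 * max(pk$location))
}

#' Validate (and adjust) a purity solution against somatic MAF peaks
#'
#' A correct purity/ploidy call must be supported by the somatic MAF
#' distribution: for each segment with enough SNVs, the observed MAF peaks
#' are compared with the peaks expected under each candidate interpretation
#' of the segment (its assigned state plus any tied subclonal alternatives,
#' e.g. one-copy gain in 80% of cells vs two-copy gain in 40%). The
#' interpretation minimizing the mean absolute peak deviation is selected;
#' the solution-level `maf_consistency` is the mean over validated segments.
#'
#' @param sol A `purity_solution` from [fit_candidates()].
#' @param snvs_by_segment List (one element per segment row, `NULL` allowed)
#'   of numeric MAF vectors.
#' @param min_snvs Segments with fewer SNVs are skipped and flagged.
#' @param tol Maximum mean peak deviation for a segment to count as
#'   consistent (default 0.05, accommodating the typical 0.04 gap between
#'   predicted and observed peak locations at 60x depth).
#' @return The solution with `maf_consistency` filled in, per-segment
#'   updates applied (subclonal interpretation switches), and `status` set
#'   to `"accept"`, `"adjust"` (some segment switched interpretation) or
#'   `"unresolved"` (some validated segment fit no interpretation).
#' @export
validate_with_mafs <- function(sol, snvs_by_segment, min_snvs = 50,
                               tol = 0.05) {
  stopifnot(inherits(sol, "purity_solution"))
  ctx <- sample_context(sol$purity, normal_cn = sol$normal_cn)
  seg <- sol$segment_states
  devs <- rep(NA_real_, nrow(seg))
  seg$maf_validated <- FALSE
  adjusted <- FALSE
  unresolved <- FALSE
  for (i in seq_len(nrow(seg))) {
    mafs <- if (i <= length(snvs_by_segment)) snvs_by_segment[[i]] else NULL
    if (is.null(mafs) || length(mafs) < min_snvs) next
    obs <- tryCatch(find_peaks_and_valleys(smooth_density(mafs)),
                    tc_insufficient_data = function(e) NULL)
    if (is.null(obs) || nrow(obs$peaks) == 0) next
    interps <- segment_interpretations(sol, i)
    dev_per <- vapply(seq_len(nrow(interps)), function(k) {
      st <- copy_state(interps$major[k], interps$minor[k])
      hists <- tryCatch(enumerate_histories(total_cn(st), is_loh(st)),
                        tc_unsupported = function(e) simple_histories(
                          total_cn(st), is_loh(st)))
      hists <- Filter(function(h) {
        h$final_state$major_cn == st$major_cn &&
          h$final_state$minor_cn == st$minor_cn
      }, hists)
      if (length(hists) == 0) return(Inf)
      # score against the best-matching history of this interpretation
      min(vapply(hists, function(h) {
        match_peak_sets(obs$peaks,
                        peaks_for_history(h, ctx, interps$fraction[k])$location)
      }, numeric(1)))
    }, numeric(1))
    k <- which.min(dev_per)
    devs[i] <- dev_per[k]
    seg$maf_validated[i] <- TRUE
    if (dev_per[k] > tol) {
      unresolved <- TRUE
    } else if (interps$major[k] != seg$major_cn[i] ||
               interps$minor[k] != seg$minor_cn[i]) {
      adjusted <- TRUE
      seg$major_cn[i] <- interps$major[k]
      seg$minor_cn[i] <- interps$minor[k]
      seg$subclone_fraction[i] <- interps$fraction[k]
      seg$clonal_flag[i] <- interps$fraction[k] >= 1
    }
  }
  sol$segment_states <- seg
  sol$maf_consistency <- if (all(is.na(devs))) NA_real_ else mean(devs, na.rm = TRUE)
  sol$status <- if (unresolved) "unresolved" else if (adjusted) "adjust" else "accept"
  sol
}

segment_interpretations <- function(sol, i) {
  seg <- sol$segment_states
  base <- data.frame(major = seg$major_cn[i], minor = seg$minor_cn[i],
                     fraction = seg$subclone_fraction[i])
  alts <- sol$alternatives[[i]]
  if (!is.null(alts) && nrow(alts) > 0) {
    base <- unique(rbind(base, alts[, c("major", "minor", "fraction")]))
  }
  base
}

# mean absolute deviation between observed peak locations and their nearest
# expected peak, weighted by observed peak mass, plus a penalty for expected
# peaks with no observed mass nearby. Observed peaks below the lowest
# expected clonal peak are subclonal — every history predicts none, some or
# all of them — and are excluded from the match.
match_peak_sets <- function(obs_peaks, expected, unmatched_penalty = 0.05,
                            subclonal_margin = 0.05) {
  keep <- obs_peaks$location >= min(expected) - subclonal_margin
  obs_peaks <- obs_peaks[keep, , drop = FALSE]
  exp_dev <- vapply(expected, function(e) {
    if (nrow(obs_peaks) == 0) Inf else min(abs(e - obs_peaks$location))
  }, numeric(1))
  penalty <- unmatched_penalty * mean(exp_dev > 0.08)
  if (nrow(obs_peaks) == 0) return(penalty)
  dev_obs <- vapply(obs_peaks$location, function(x) min(abs(x - expected)),
                    numeric(1))
  w <- obs_peaks$weight / sum(obs_peaks$weight)
  sum(w * dev_obs) + penalty
}

#' Estimate a segment's minor-allele BAF from SNP read counts
#'
#' Germline heterozygous SNP BAFs mirror around 0.5 because the parental
#' phase of each SNP is unknown; a naive fold-then-average estimate is
#' biased downward near 0.5. This maximum-likelihood estimator fits the
#' mirrored binomial mixture `0.5 B(n, q) + 0.5 B(n, 1 - q)` for
#' `q` in [0, 0.5].
#'
#' @param b_counts,depths Integer vectors of B-allele read counts and total
#'   depths, one entry per SNP.
#' @return Estimated minor-allele BAF in [0, 0.5].
#' @export
estimate_segment_baf <- function(b_counts, depths) {
  stopifnot(length(b_counts) == length(depths), all(depths >= 1))
  nll <- function(q) {
    -sum(log(0.5 * stats::dbinom(b_counts, depths, q) +
               0.5 * stats::dbinom(b_counts, depths, 1 - q) + 1e-300))
  }
  stats::optimize(nll, c(0, 0.5))$minimum
}
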