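#' Approximate hg19-like chromosome lengths
#'
#' Chromosome lengths (bp) for chromosomes 1-22 and X, rounded to the Mb,
#' used to give simulated coordinates realistic inter-mutation distances.
#'
#' @return Named numeric vector of lengths.
#' @export
default_chrom_sizes <- function() {
  stats::setNames(1e6 * c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
                          135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48,
                          51, 155),
                  c(as.character(1:22), "X"))
}

#' Simulation configuration for a synthetic tumor
#'
#' Describes a tumor generatively: purity, clone tree, per-segment copy
#' histories with event times on the mutational-time axis, a homogeneous
#' per-copy mutation rate, the clonal expansion time, read depths and
#' copy-ratio noise. [simulate_tumor()] turns a config into SNV/SNP/segment
#' tables plus full ground truth.
#'
#' Mutational time runs on [0, 1] over the tumor's total SNV accrual per
#' copy: copy events happen at their `t1`/`t2`, SNVs arising before
#' `clonal_expansion_time` are clonal, later ones subclonal (assigned to the
#' subclones of the clone tree in proportion to their fractions).
#'
#' @param purity Tumor purity in (0, 1].
#' @param segments Data frame: `chrom`, `start`, `end`, `history` (a name
#'   from the history catalog, e.g. `"cn_loh"`, `"one_copy_gain"`,
#'   `"copy_neutral"`), `t1`, `t2` (event times, `NA` when unused), and
#'   optionally `clone_fraction` (< 1 makes the copy change subclonal).
#' @param clones Data frame `clone`, `parent`, `fraction`; default a single
#'   major clone plus one subclone of fraction 0.3. Must satisfy pigeonhole
#'   nesting.
#' @param snv_rate_per_mb Expected somatic SNVs per copy, per unit
#'   mutational time, per Mb (default 12, giving a few thousand SNVs on a
#'   genome-scale layout).
#' @param clonal_expansion_time Fraction of accrual before the major clonal
#'   expansion (default 0.9).
#' @param depth_tumor Mean tumor depth at a copy-2 site (default 60).
#' @param depth_normal Mean normal depth (default 30; only reported).
#' @param snp_rate_per_mb Heterozygous germline SNPs per Mb (default 40).
#' @param ratio_noise_sd Gaussian noise sd on segment copy ratios.
#' @param normal_cn Normal copy number for all segments (default 2).
#' @param seed RNG seed; every simulation is fully reproducible from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(purity, segments,
                              clones = NULL,
                              snv_rate_per_mb = 12,
                              clonal_expansion_time = 0.9,
                              depth_tumor = 60, depth_normal = 30,
                              snp_rate_per_mb = 40,
                              ratio_noise_sd = 0.05,
                              normal_cn = 2,
                              seed = 1L) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("chrom", "start", "end", "history") %in% names(segments)))
  if (is.null(segments$t1)) segments$t1 <- NA_real_
  if (is.null(segments$t2)) segments$t2 <- NA_real_
  if (is.null(segments$clone_fraction)) segments$clone_fraction <- 1
  if (is.null(clones)) {
    clones <- data.frame(clone = c("major", "sub1"),
                         parent = c(NA, "major"),
                         fraction = c(1, 0.3))
  }
  kids <- clones[!is.na(clones$parent), ]
  for (p in unique(kids$parent)) {
    pf <- clones$fraction[clones$clone == p]
    if (length(pf) != 1) stop_invalid(sprintf("unknown parent clone '%s'", p))
    if (sum(kids$fraction[kids$parent == p]) > pf + 1e-9) {
      stop_invalid(sprintf("clone nesting violated under parent '%s'", p))
    }
  }
  tms <- c(segments$t1, segments$t2)
  if (any(!is.na(tms) & (tms < 0 | tms > 1))) {
    stop_invalid("event times must lie in [0, 1]")
  }
  if (snv_rate_per_mb < 0 || snp_rate_per_mb < 0 || ratio_noise_sd < 0) {
    stop_invalid("rates and noise must be >= 0")
  }
  structure(list(purity = purity, segments = segments, clones = clones,
                 snv_rate_per_mb = snv_rate_per_mb,
                 clonal_expansion_time = clonal_expansion_time,
                 depth_tumor = depth_tumor, depth_normal = depth_normal,
                 snp_rate_per_mb = snp_rate_per_mb,
                 ratio_noise_sd = ratio_noise_sd,
                 normal_cn = normal_cn, seed = as.integer(seed)),
            class = "simulation_config")
}

lookup_history <- function(name) {
  cat_ <- history_catalog()
  if (!name %in% names(cat_)) {
    stop_invalid(sprintf("unknown history '%s'; see history_catalog()", name))
  }
  cat_[[name]]
}

# expected VAF of an SNV present on m_in copies in the cells carrying the
# segment's altered state (fraction phi of tumor cells), m_out copies in the
# remaining tumor cells, further restricted to a clone of fraction `cf`
mixture_vaf <- function(ctx, phi, t_alt, t_bg, m_in, m_out, cf = 1) {
  p <- ctx$purity
  t_avg <- phi * t_alt + (1 - phi) * t_bg
  num <- p * cf * (phi * m_in + (1 - phi) * m_out)
  num / (p * t_avg + ctx$normal_cn * (1 - p))
}

#' Simulate a tumor with known ground truth
#'
#' Generates somatic SNVs, germline heterozygous SNP BAFs and noisy
#' copy-ratio segments from a [simulation_config()]. Per segment and
#' multiplicity class, SNV counts are Poisson with rate proportional to the
#' number of copies accruing the class times the length of its accrual
#' interval; each SNV's expected allele fraction follows the closed-form
#' peak model, its read depth is Poisson around `depth_tumor` scaled by the
#' segment's expected copy ratio, and its variant reads are Binomial.
#' Everything is reproducible from `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `snvs` (chrom, pos, ref, alt, depth, alt_count, maf),
#'   `snps` (chrom, pos, depth, b_count, baf), `segments` (chrom, start,
#'   end, copy_ratio, baf — the observed, noisy table), and `truth` (the
#'   config plus per-SNV latent labels: segment row, clone, multiplicity,
#'   accrual interval, expected VAF).
#' @export
simulate_tumor <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  ctx <- sample_context(cfg$purity, cfg$normal_cn, cfg$depth_tumor)
  tau <- cfg$clonal_expansion_time
  subclones <- cfg$clones[!is.na(cfg$clones$parent), , drop = FALSE]
  segs <- cfg$segments
  bases <- c("A", "C", "G", "T")

  snv_rows <- list(); snp_rows <- list(); seg_rows <- list(); truth_rows <- list()
  for (i in seq_len(nrow(segs))) {
    h <- lookup_history(segs$history[i])
    times <- c(segs$t1[i], segs$t2[i])[seq_len(h$n_events)]
    if (h$n_events > 0 && any(is.na(times))) {
      stop_invalid(sprintf("segment %d: history '%s' needs %d event time(s)",
                           i, h$name, h$n_events))
    }
    phi <- segs$clone_fraction[i]
    size_mb <- (segs$end[i] - segs$start[i] + 1) / 1e6
    t_alt <- total_cn(h$final_state)
    t_bg <- cfg$normal_cn
    exp_ratio <- {
      st <- h$final_state; st$clone_fraction <- phi
      expected_copy_ratio(ctx, st)
    }
    exp_baf <- {
      st <- h$final_state; st$clone_fraction <- phi
      tryCatch(expected_baf(ctx, st)$baf, tumorclock_error = function(e) NA_real_)
    }

    bounds <- c(0, times, 1)
    # --- clonal SNVs: per multiplicity class, truncated at tau ---
    class_df <- h$classes
    for (k in seq_len(nrow(class_df))) {
      iv <- class_df$interval[k]
      a <- bounds[iv + 1]; b <- min(bounds[iv + 2], tau)
      len <- max(0, b - a)
      lambda <- cfg$snv_rate_per_mb * class_df$copies[k] * len * size_mb
      n_k <- stats::rpois(1, lambda)
      if (n_k == 0) next
      m_in <- class_df$m[k]
      # outside the carrying cells a pre-event SNV sits on one copy;
      # SNVs arising after a subclonal event exist only in the carriers
      event_iv <- iv >= 1
      m_out <- if (phi < 1 && !event_iv) 1 else 0
      vaf <- if (phi < 1) {
        mixture_vaf(ctx, phi, t_alt, t_bg, m_in,
                    if (event_iv) 0 else 1, cf = 1)
      } else {
        expected_maf_peak(ctx, h$final_state, m_in, 1)
      }
      snv_rows[[length(snv_rows) + 1]] <- sim_reads(
        cfg, ctx, segs[i, ], n_k, vaf, exp_ratio, bases)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        segment = i, clone = "major", multiplicity = m_in,
        interval = iv, clonal = TRUE, expected_vaf = vaf,
        t_start = a, t_end = b)[rep(1, n_k), ]
    }
    # --- subclonal SNVs: arise after the clonal expansion, m = 1 ---
    if (tau < 1 && nrow(subclones) > 0) {
      for (j in seq_len(nrow(subclones))) {
        lambda <- cfg$snv_rate_per_mb * t_alt * (1 - tau) * size_mb *
          (subclones$fraction[j] / sum(subclones$fraction))
        n_j <- stats::rpois(1, lambda)
        if (n_j == 0) next
        cf <- subclones$fraction[j]
        vaf <- if (phi < 1) mixture_vaf(ctx, phi, t_alt, t_bg, 1, 1, cf = cf)
               else expected_maf_peak(ctx, h$final_state, 1, cf)
        snv_rows[[length(snv_rows) + 1]] <- sim_reads(
          cfg, ctx, segs[i, ], n_j, vaf, exp_ratio, bases)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          segment = i, clone = subclones$clone[j], multiplicity = 1,
          interval = h$n_events, clonal = FALSE, expected_vaf = vaf,
          t_start = tau, t_end = 1)[rep(1, n_j), ]
      }
    }
    # --- germline heterozygous SNPs ---
    n_snp <- stats::rpois(1, cfg$snp_rate_per_mb * size_mb)
    if (n_snp > 0) {
      depth <- stats::rpois(n_snp, cfg$depth_tumor * exp_ratio)
      depth <- pmax(depth, 1)
      minor <- if (is.na(exp_baf)) 0.5 else exp_baf
      # random parental phase: the designated B allele is minor or major
      pb <- ifelse(stats::runif(n_snp) < 0.5, minor, 1 - minor)
      b <- stats::rbinom(n_snp, depth, pb)
      snp_rows[[length(snp_rows) + 1]] <- data.frame(
        chrom = segs$chrom[i],
        pos = sort(sample.int(segs$end[i] - segs$start[i] + 1, n_snp,
                              replace = TRUE)) + segs$start[i] - 1,
        depth = depth, b_count = b, baf = b / depth)
    }
    # --- observed segment row ---
    obs_baf <- if (n_snp > 0) {
      last <- snp_rows[[length(snp_rows)]]
      estimate_segment_baf(last$b_count, last$depth)
    } else NA_real_
    seg_rows[[length(seg_rows) + 1]] <- data.frame(
      chrom = segs$chrom[i], start = segs$start[i], end = segs$end[i],
      copy_ratio = max(0.01, exp_ratio + stats::rnorm(1, 0, cfg$ratio_noise_sd)),
      baf = obs_baf, true_ratio = exp_ratio, true_baf = exp_baf)
  }

  snvs <- if (length(snv_rows)) do.call(rbind, snv_rows) else empty_snvs()
  truth_snv <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  rownames(snvs) <- NULL
  if (!is.null(truth_snv)) rownames(truth_snv) <- NULL
  list(snvs = snvs,
       snps = if (length(snp_rows)) do.call(rbind, snp_rows) else NULL,
       segments = do.call(rbind, seg_rows),
       truth = list(config = cfg, snv_labels = truth_snv))
}

sim_reads <- function(cfg, ctx, seg, n, vaf, exp_ratio, bases) {
  depth <- pmax(stats::rpois(n, cfg$depth_tumor * exp_ratio), 1)
  alt_count <- stats::rbinom(n, depth, min(1, vaf))
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  data.frame(chrom = seg$chrom,
             pos = sample.int(seg$end - seg$start + 1, n, replace = TRUE) +
               seg$start - 1,
             ref = ref, alt = alt, depth = depth, alt_count = alt_count,
             maf = alt_count / depth)
}

empty_snvs <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), depth = integer(0), alt_count = integer(0),
             maf = numeric(0))
}

#' Sample allele fractions from the neutral 1/f law
#'
#' Draws subclonal allele fractions whose expected cumulative count follows
#' `M(f) proportional to 1/f - 1/f_max` on `[f_min, f_max]` — the null of the
#' neutral-evolution test — by inverse-CDF sampling. With `exact = TRUE` the
#' deterministic quantiles of the law are returned instead of random draws.
#'
#' @param n Number of allele fractions.
#' @param f_min Lower truncation (detection limit), 0 < f_min < f_max.
#' @param f_max Upper truncation (default 0.5: heterozygous clonal limit).
#' @param exact Return exact quantiles rather than random draws.
#' @return Numeric vector of length `n`.
#' @export
simulate_neutral_tail <- function(n, f_min, f_max = 0.5, exact = FALSE) {
  if (n == 0) return(numeric(0))
  if (!(f_min > 0 && f_min < f_max && f_max <= 0.5 + 1e-12)) {
    stop_invalid("need 0 < f_min < f_max <= 0.5")
  }
  u <- if (exact) (seq_len(n) - 0.5) / n else stats::runif(n)
  1 / (1 / f_min - u * (1 / f_min - 1 / f_max))
}

#' Inject a kataegis cluster into an SNV table
#'
#' Adds `n_events` SNVs of the given substitution classes uniformly within a
#' span of one chromosome — a positive control for [detect_kataegis()].
#'
#' @param snvs SNV data frame (`chrom`, `pos`, `ref`, `alt`, read columns
#'   optional).
#' @param chrom Chromosome receiving the cluster.
#' @param n_events Number of SNVs to add (0 returns the table unchanged).
#' @param span_start,span_bp Location and width of the cluster.
#' @param classes Substitution classes to draw from (pyrimidine notation).
#' @param chrom_sizes Named lengths used to validate the span (default
#'   [default_chrom_sizes()]).
#' @param depth Mean read depth given to the injected SNVs.
#' @param vaf Allele fraction used for their read counts.
#' @return A list with `snvs` (augmented, position-sorted within chromosome)
#'   and `injected` (logical vector marking the new rows in `snvs`).
#' @export
inject_kataegis <- function(snvs, chrom, n_events, span_start, span_bp,
                            classes = c("C>T", "C>G"),
                            chrom_sizes = default_chrom_sizes(),
                            depth = 60, vaf = 0.35) {
  snvs <- as.data.frame(snvs)
  if (n_events == 0) {
    return(list(snvs = snvs, injected = rep(FALSE, nrow(snvs))))
  }
  size <- unname(chrom_sizes[as.character(chrom)])[1]
  if (is.null(size) || is.na(size)) {
    stop_invalid(sprintf("unknown chromosome '%s'", chrom))
  }
  if (span_start < 1 || span_start + span_bp - 1 > size) {
    stop_invalid("span extends outside the chromosome")
  }
  cls <- sample(classes, n_events, replace = TRUE)
  ref <- rep("C", n_events)
  alt <- sub("^C>", "", cls)
  if (any(!alt %in% c("A", "G", "T"))) {
    stop_invalid("classes must be pyrimidine substitutions like 'C>T'")
  }
  d <- pmax(stats::rpois(n_events, depth), 1)
  new <- data.frame(chrom = chrom,
                    pos = span_start + sample.int(span_bp, n_events,
                                                  replace = TRUE) - 1,
                    ref = ref, alt = alt, depth = d,
                    alt_count = stats::rbinom(n_events, d, vaf))
  new$maf <- new$alt_count / new$depth
  common <- intersect(names(snvs), names(new))
  if (nrow(snvs) == 0) common <- names(new)
  out <- rbind(snvs[, common, drop = FALSE], new[, common, drop = FALSE])
  injected <- c(rep(FALSE, nrow(snvs)), rep(TRUE, n_events))
  ord <- order(out$chrom, out$pos)
  list(snvs = out[ord, , drop = FALSE], injected = injected[ord])
}
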