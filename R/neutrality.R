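#' Simulated SNV detection power by allele fraction
#'
#' Estimates, for each 0.01 allele-fraction bin on [0, 0.3], the probability
#' that an SNV at that allele fraction is detected at the given coverage.
#' Read depth at a site is drawn Poisson around the coverage and the number
#' of variant-supporting reads Binomial at the bin's allele fraction; a site
#' is detected when the variant reads reach `min_alt_reads` (default 3, the
#' usual minimum evidence a somatic caller demands). The curve is made
#' non-decreasing by isotonic regression to remove Monte-Carlo ripple at bin
#' edges before it is thresholded.
#'
#' @param coverage Mean sequencing depth.
#' @param min_alt_reads Detection rule: minimum variant-supporting reads.
#' @param n_sim Simulated sites per bin (default 2000).
#' @param seed Optional RNG seed for reproducibility.
#' @param f_max Upper end of the modeled allele-fraction range (default 0.3).
#' @return An object of class `detection_power_curve`: list with `bins`
#'   (data frame: `f_low`, `f_mid`, `detected_fraction`), `coverage`,
#'   `min_alt_reads`, `n_sim`, `seed`.
#' @export
detection_power <- function(coverage, min_alt_reads = 3, n_sim = 2000,
                            seed = NULL, f_max = 0.3) {
  if (coverage < 1) stop_invalid("`coverage` must be >= 1")
  if (n_sim < 100) stop_invalid("`n_sim` must be >= 100 per bin")
  if (!is.null(seed)) set.seed(seed)
  f_low <- seq(0, f_max - 0.01, by = 0.01)
  f_mid <- f_low + 0.005
  det <- vapply(f_mid, function(f) {
    depth <- stats::rpois(n_sim, coverage)
    alt <- stats::rbinom(n_sim, depth, f)
    mean(alt >= min_alt_reads)
  }, numeric(1))
  iso <- stats::isoreg(f_mid, det)$yf
  structure(list(
    bins = data.frame(f_low = f_low, f_mid = f_mid,
                      detected_fraction = pmin(1, pmax(0, iso))),
    coverage = coverage, min_alt_reads = min_alt_reads,
    n_sim = n_sim, seed = seed),
    class = "detection_power_curve")
}

#' Allele-fraction bounds for the subclonal window
#'
#' The window of allele fractions regarded as genuinely subclonal is
#' tumor-specific: the lower bound is the lowest allele fraction at which at
#' least `power_threshold` (default 80%) of SNVs are detectable at the
#' sample's coverage (from [detection_power()]), and the upper bound is the
#' valley of the MAF density separating the subclonal mass from the clonal
#' peak. A fixed window shared across tumors mixes clonal SNVs into the
#' subclonal set whenever purity, ploidy or depth differ.
#'
#' @param mafs Somatic SNV allele fractions from 1- and 2-copy regions.
#' @param power_curve A `detection_power_curve`.
#' @param power_threshold Detection fraction required at the lower bound.
#' @param min_snvs Minimum SNVs to model the density (default 500).
#' @return A list with `lower`, `upper` (allele fractions; `upper` is `NA`
#'   with `status = "upper_undetermined"` when no valley is found,
#'   otherwise `status = "ok"`) and the `fitted_peaks` used.
#' @export
subclonal_bounds <- function(mafs, power_curve, power_threshold = 0.8,
                             min_snvs = 500) {
  stopifnot(inherits(power_curve, "detection_power_curve"))
  mafs <- mafs[!is.na(mafs)]
  if (length(mafs) < min_snvs) {
    stop_insufficient(
      sprintf("need at least %d SNVs to model the MAF density, got %d",
              min_snvs, length(mafs)),
      n_obs = length(mafs), n_required = min_snvs)
  }
  bins <- power_curve$bins
  ok <- which(bins$detected_fraction >= power_threshold)
  lower <- if (length(ok) == 0) max(bins$f_low) else bins$f_low[min(ok)]
  fitted <- find_peaks_and_valleys(smooth_density(mafs))
  if (length(fitted$valleys) == 0) {
    return(list(lower = lower, upper = NA_real_,
                status = "upper_undetermined", fitted = fitted))
  }
  # valley bounding the clonal (right-most) peak from below
  clonal_loc <- max(fitted$peaks$location)
  below <- fitted$valleys[fitted$valleys < clonal_loc]
  if (length(below) == 0) {
    return(list(lower = lower, upper = NA_real_,
                status = "upper_undetermined", fitted = fitted))
  }
  list(lower = lower, upper = max(below), status = "ok", fitted = fitted)
}

#' Test subclonal SNVs for neutral evolution (1/f power law)
#'
#' Under neutral growth the cumulative number of subclonal SNVs with allele
#' fraction at least f grows linearly in 1/f. The test regresses
#' M(f) = #\{SNVs with MAF >= f\} against 1/f over the subclonal window and
#' declares neutral evolution when the ordinary-least-squares R-squared
#' reaches the cutoff (default 0.98). A verdict requires at least
#' `min_snvs` (default 500) SNVs inside the window.
#'
#' @param mafs Subclonal SNV allele fractions (will be restricted to
#'   `[lower, upper]`).
#' @param lower,upper Subclonal window (from [subclonal_bounds()]).
#' @param cutoff R-squared cutoff for neutrality (default 0.98).
#' @param min_snvs Minimum SNVs inside the window for a verdict.
#' @param grid `"observed"` (default): M evaluated at each observed MAF (the
#'   step-function construction of the original test); `"fixed"`: M
#'   evaluated on a regular 0.01 grid over the window.
#' @return An object of class `neutrality_result`: list with `lower_bound`,
#'   `upper_bound`, `n_subclonal_snvs`, `r_squared`, `is_neutral`, `cutoff`,
#'   `status` (`"ok"` or `"insufficient_data"`, in which case `r_squared`
#'   and `is_neutral` are `NA`).
#' @export
neutrality_test <- function(mafs, lower, upper, cutoff = 0.98,
                            min_snvs = 500, grid = c("observed", "fixed")) {
  grid <- match.arg(grid)
  if (!(lower > 0 && lower < upper && upper < 1)) {
    stop_invalid("need 0 < lower < upper < 1")
  }
  f <- mafs[!is.na(mafs) & mafs >= lower & mafs <= upper]
  n <- length(f)
  res <- structure(list(lower_bound = lower, upper_bound = upper,
                        n_subclonal_snvs = n, r_squared = NA_real_,
                        is_neutral = NA, cutoff = cutoff,
                        status = "insufficient_data"),
                   class = "neutrality_result")
  if (n < min_snvs) return(res)
  if (grid == "observed") {
    # one point per distinct observed fraction: read depths discretize the
    # MAFs, and tied fractions must not contribute a vertical staircase
    fs <- sort(unique(f))
    M <- vapply(fs, function(x) sum(f >= x), numeric(1))
  } else {
    fs <- seq(lower, upper, by = 0.01)
    M <- vapply(fs, function(x) sum(f >= x), numeric(1))
  }
  fit <- stats::lm(M ~ I(1 / fs))
  # the exact neutral quantiles fit perfectly; that is the null, not a fault
  r2 <- suppressWarnings(summary(fit)$r.squared)
  res$r_squared <- r2
  res$is_neutral <- r2 >= cutoff
  res$status <- "ok"
  res
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf(
    "<neutrality_result> window [%.2f, %.2f], n = %d, R^2 = %s, verdict: %s\n",
    x$lower_bound, x$upper_bound, x$n_subclonal_snvs,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
    if (x$status != "ok") x$status
    else if (isTRUE(x$is_neutral)) "neutral" else "non-neutral"))
  invisible(x)
}
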