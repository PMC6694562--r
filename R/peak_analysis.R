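#' Smooth an allele-fraction distribution
#'
#' Bins the observed allele fractions into fixed-width intervals on [0, 1]
#' and fits a cubic smoothing spline (smoothness chosen by generalized
#' cross-validation) to the bin counts, yielding a non-negative density
#' curve that integrates to 1. The 0.01 default bin width matches the
#' granularity at which detection power is modeled elsewhere in the package.
#'
#' @param mafs Numeric vector of allele fractions in [0, 1].
#' @param grid_step Bin width of the density grid (default 0.01).
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects it by GCV.
#' @param min_obs Minimum number of observations required (default 50);
#'   fewer raises a `tc_insufficient_data` condition carrying the count.
#' @return An object of class `density_curve`: list with `grid` (bin
#'   midpoints), `density` (non-negative, integrates to 1), `n_obs`.
#' @export
smooth_density <- function(mafs, grid_step = 0.01, spar = NULL, min_obs = 50) {
  mafs <- mafs[!is.na(mafs)]
  if (length(mafs) < min_obs) {
    stop_insufficient(
      sprintf("need at least %d allele fractions, got %d", min_obs, length(mafs)),
      n_obs = length(mafs), n_required = min_obs)
  }
  if (any(mafs < 0 | mafs > 1)) stop_invalid("allele fractions must lie in [0, 1]")
  breaks <- seq(0, 1, by = grid_step)
  mids <- head(breaks, -1) + grid_step / 2
  counts <- tabulate(findInterval(mafs, breaks, rightmost.closed = TRUE),
                     nbins = length(mids))
  fit <- if (is.null(spar)) {
    stats::smooth.spline(mids, counts, cv = FALSE)  # GCV
  } else {
    stats::smooth.spline(mids, counts, spar = spar)
  }
  dens <- pmax(stats::predict(fit, mids)$y, 0)
  area <- sum(dens) * grid_step
  if (area <= 0) dens <- rep(1 / length(mids), length(mids)) else dens <- dens / area
  structure(list(grid = mids, density = dens / 1, n_obs = length(mafs),
                 grid_step = grid_step),
            class = "density_curve")
}

peak_prominence <- function(density, i_peaks) {
  # prominence of each local maximum: height above the higher of the two
  # saddle minima separating it from higher terrain (or the grid edge)
  n <- length(density)
  vapply(seq_along(i_peaks), function(k) {
    i <- i_peaks[k]
    h <- density[i]
    left <- if (i > 1) density[seq_len(i - 1)] else numeric(0)
    right <- if (i < n) density[seq(i + 1, n)] else numeric(0)
    base_side <- function(side, from_peak_outward) {
      # minimum density between the peak and the nearest higher point on
      # that side (or the grid edge if no higher point exists)
      if (length(side) == 0) return(min(density))
      higher <- which(side >= h)
      if (length(higher) == 0) return(min(side))
      if (from_peak_outward) min(side[seq_len(min(higher))])
      else min(side[seq(max(higher), length(side))])
    }
    h - max(base_side(left, FALSE), base_side(right, TRUE))
  }, numeric(1))
}

#' Locate peaks and valleys of a density curve
#'
#' Peaks are local maxima whose prominence is at least `min_prominence`
#' times the tallest peak's height; valleys are the minimum-density grid
#' points between each pair of adjacent retained peaks. Peak weights are the
#' density mass of each valley-bounded interval.
#'
#' @param curve A `density_curve` from [smooth_density()].
#' @param min_prominence Minimum relative prominence, as a fraction of the
#'   maximum density (default 0.1).
#' @return An object of class `fitted_peaks`: list with `peaks` (data frame:
#'   `location`, `height`, `weight`), `valleys` (numeric vector of boundary
#'   locations, length `nrow(peaks) - 1`), and the source `curve`.
#' @export
find_peaks_and_valleys <- function(curve, min_prominence = 0.1) {
  stopifnot(inherits(curve, "density_curve"))
  d <- curve$density
  n <- length(d)
  # local maxima (plateau-safe: strict rise before, non-rise after)
  is_max <- vapply(seq_len(n), function(i) {
    lo <- if (i > 1) d[i] > d[i - 1] else d[i] > 0
    hi <- if (i < n) d[i] >= d[i + 1] else TRUE
    lo && hi
  }, logical(1))
  idx <- which(is_max)
  if (length(idx) > 0 && max(d) > 0) {
    prom <- peak_prominence(d, idx)
    idx <- idx[prom >= min_prominence * max(d)]
  }
  if (length(idx) == 0) {
    return(structure(list(
      peaks = data.frame(location = numeric(0), height = numeric(0),
                         weight = numeric(0)),
      valleys = numeric(0), curve = curve), class = "fitted_peaks"))
  }
  valleys_i <- if (length(idx) > 1) {
    vapply(seq_len(length(idx) - 1), function(k) {
      seg <- seq(idx[k], idx[k + 1])
      seg[which.min(d[seg])]
    }, integer(1))
  } else integer(0)
  bounds <- c(0, curve$grid[valleys_i], 1)
  weight <- vapply(seq_along(idx), function(k) {
    in_int <- curve$grid > bounds[k] & curve$grid <= bounds[k + 1]
    sum(d[in_int]) * curve$grid_step
  }, numeric(1))
  structure(list(
    peaks = data.frame(location = curve$grid[idx], height = d[idx],
                       weight = weight),
    valleys = curve$grid[valleys_i],
    curve = curve), class = "fitted_peaks")
}

#' Assign SNVs to fitted peaks
#'
#' Labels each allele fraction by the peak whose valley-bounded interval
#' contains it. A value lying exactly on a valley is assigned to the lower
#' peak (conservative toward the later/subclonal class); this tie rule can
#' be flipped with `ties`.
#'
#' @param mafs Numeric vector of allele fractions.
#' @param fitted A `fitted_peaks` object with at least one peak.
#' @param ties `"lower"` (default) or `"upper"`: which peak receives a value
#'   exactly on a valley boundary.
#' @return A list with `labels` (integer peak index per SNV) and `counts`
#'   (per-peak tabulation; sums to `length(mafs)`).
#' @export
assign_snvs <- function(mafs, fitted, ties = c("lower", "upper")) {
  stopifnot(inherits(fitted, "fitted_peaks"))
  ties <- match.arg(ties)
  n_peaks <- nrow(fitted$peaks)
  if (n_peaks == 0) stop_invalid("cannot assign SNVs: no peaks were found")
  labels <- findInterval(mafs, fitted$valleys,
                         left.open = (ties == "lower")) + 1L
  list(labels = labels,
       counts = tabulate(labels, nbins = n_peaks))
}
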