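#' Sample context: purity, normal copy number and coverage
#'
#' Bundles the sample-level quantities every expectation depends on: the
#' fraction of sequenced cells that are tumor (purity `p`), the number of
#' copies a normal cell carries for the region under consideration
#' (2 for autosomes and female X, 1 for male X/Y), and the mean sequencing
#' depth at a two-copy site.
#'
#' @param purity Tumor cell fraction, in (0, 1].
#' @param normal_cn Copies per normal cell for the region: 2 (default) or 1.
#' @param mean_depth Expected read depth at a copy-number-2 site.
#' @return An object of class `sample_context`.
#' @examples
#' ctx <- sample_context(0.74)
#' expected_maf_peak(ctx, copy_state(2, 0), multiplicity = 2)
#' @export
sample_context <- function(purity, normal_cn = 2, mean_depth = 60) {
  if (!is.numeric(purity) || length(purity) != 1 || is.na(purity) ||
      purity <= 0 || purity > 1) {
    stop_invalid("`purity` must be a single number in (0, 1]")
  }
  if (!normal_cn %in% c(1L, 2L)) {
    stop_invalid("`normal_cn` must be 1 or 2")
  }
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop_invalid("`mean_depth` must be positive")
  }
  structure(
    list(purity = purity, normal_cn = as.integer(normal_cn),
         mean_depth = mean_depth),
    class = "sample_context"
  )
}

#' Allele-specific copy state
#'
#' A copy state is the pair (n1, n2) of major and minor parental allele copy
#' numbers in the tumor cells that carry it, together with the fraction of
#' tumor cells carrying it (1 for a clonal state).
#'
#' @param major_cn Copies of the major parental allele (n1), integer >= 0.
#' @param minor_cn Copies of the minor parental allele (n2), integer >= 0,
#'   with `minor_cn <= major_cn`.
#' @param clone_fraction Fraction of tumor cells carrying this state, (0, 1].
#' @return An object of class `copy_state`.
#' @export
copy_state <- function(major_cn, minor_cn, clone_fraction = 1) {
  if (length(major_cn) != 1 || length(minor_cn) != 1 ||
      major_cn != round(major_cn) || minor_cn != round(minor_cn)) {
    stop_invalid("copy numbers must be single integers")
  }
  if (minor_cn < 0 || major_cn < minor_cn) {
    stop_invalid("need major_cn >= minor_cn >= 0")
  }
  if (clone_fraction <= 0 || clone_fraction > 1) {
    stop_invalid("`clone_fraction` must be in (0, 1]")
  }
  structure(
    list(major_cn = as.integer(major_cn), minor_cn = as.integer(minor_cn),
         clone_fraction = clone_fraction),
    class = "copy_state"
  )
}

total_cn <- function(state) state$major_cn + state$minor_cn

is_loh <- function(state) state$minor_cn == 0L && state$major_cn >= 1L

#' Expected mutant allele fraction peak
#'
#' Location of the MAF peak for somatic SNVs present on `multiplicity` copies
#' in a region with copy state (n1, n2), carried by a fraction
#' `carrier_fraction` of tumor cells, in a sample of purity p:
#'
#'   p * phi * m / (p * (n1 + n2) + normal_cn * (1 - p))
#'
#' The clonal autosomal case (phi = 1, normal_cn = 2) is the classical
#' purity/ploidy peak formula; e.g. at p = 0.74 an SNV on both copies of a
#' CN-LOH region peaks at 0.74, and a heterozygous SNV on a copy-neutral
#' region peaks at 0.37.
#'
#' @param ctx A [sample_context()].
#' @param state A [copy_state()] for the region (of the carrying cells).
#' @param multiplicity Number of copies carrying the SNV (m), 1..n1+n2.
#' @param carrier_fraction Fraction of tumor cells carrying the SNV
#'   (1 = clonal).
#' @return Expected allele fraction in (0, 1].
#' @export
expected_maf_peak <- function(ctx, state, multiplicity, carrier_fraction = 1) {
  stopifnot(inherits(ctx, "sample_context"), inherits(state, "copy_state"))
  tot <- total_cn(state)
  if (multiplicity < 1 || multiplicity > tot) {
    stop_invalid(sprintf(
      "multiplicity %s outside 1..%d (total copies of the state)",
      format(multiplicity), tot))
  }
  if (carrier_fraction <= 0 || carrier_fraction > 1) {
    stop_invalid("`carrier_fraction` must be in (0, 1]")
  }
  p <- ctx$purity
  p * carrier_fraction * multiplicity /
    (p * tot + ctx$normal_cn * (1 - p))
}

sum_states <- function(states) {
  if (inherits(states, "copy_state")) states <- list(states)
  if (length(states) == 0) stop_invalid("need at least one copy state")
  phi <- vapply(states, function(s) s$clone_fraction, numeric(1))
  if (sum(phi) > 1 + 1e-9) {
    stop_invalid("clone fractions of the states sum above 1")
  }
  list(
    states = states, phi = phi,
    tot = sum(phi * vapply(states, total_cn, numeric(1))),
    minor = sum(phi * vapply(states, function(s) s$minor_cn, numeric(1)))
  )
}

#' Expected tumor/normal copy ratio of a region
#'
#' Average copies per tumor cell across the given states (clone fractions
#' must sum to at most 1; pass the diploid background explicitly for
#' subclonal mixtures), mixed with the normal contamination and anchored to
#' the normal copy number of the region, so a diploid region is 1 at any
#' purity. A clonal one-copy gain gives 1.5 at purity 1 and 1.25 at
#' purity 0.5. No average-ploidy renormalization is applied.
#'
#' @param ctx A [sample_context()].
#' @param states A [copy_state()] or list of them; `clone_fraction`s sum <= 1.
#' @return Expected copy ratio (> 0).
#' @export
expected_copy_ratio <- function(ctx, states) {
  stopifnot(inherits(ctx, "sample_context"))
  s <- sum_states(states)
  p <- ctx$purity
  # cells not covered by any listed state are implicitly normal-like
  residual <- (1 - sum(s$phi)) * ctx$normal_cn
  (p * (s$tot + residual) + ctx$normal_cn * (1 - p)) / ctx$normal_cn
}

#' Expected B-allele fraction of germline heterozygous SNPs
#'
#' Minor-allele fraction expected at heterozygous germline SNPs in a region
#' with the given copy states: the normal cells contribute one minor of two
#' copies each. Returns the minor-allele value and its mirror (the
#' major-allele fraction). Undefined for hemizygous regions
#' (`normal_cn == 1`), where there are no germline heterozygous sites.
#'
#' @inheritParams expected_copy_ratio
#' @return A list with `baf` (minor, in (0, 0.5]) and `mirror` (1 - baf).
#' @export
expected_baf <- function(ctx, states) {
  stopifnot(inherits(ctx, "sample_context"))
  if (ctx$normal_cn == 1L) {
    stop_invalid("BAF is undefined when normal_cn = 1: no germline heterozygous SNPs")
  }
  s <- sum_states(states)
  p <- ctx$purity
  res <- 1 - sum(s$phi)  # normal-like residual tumor cells: (1,1)
  minor <- s$minor + res * 1
  tot <- s$tot + res * 2
  baf <- (p * minor + (1 - p) * 1) / (p * tot + (1 - p) * 2)
  list(baf = baf, mirror = 1 - baf)
}
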