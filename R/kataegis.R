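SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "other")

# pyrimidine-strand normalization: purine-reference substitutions are
# reported as their reverse complement (G>A is the same event as C>T)
normalize_substitution <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- toupper(ref); alt <- toupper(alt)
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  cls <- paste0(ref, ">", alt)
  ifelse(cls %in% c("C>A", "C>G", "C>T"), cls, "other")
}

#' Inter-mutation distance (rainfall) series
#'
#' Sorts SNVs per chromosome, computes successive inter-mutation distances
#' and pyrimidine-normalized substitution classes — the data behind a
#' rainfall plot. Chromosomes with fewer than two SNVs are excluded and
#' listed in `excluded`.
#'
#' @param snvs Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @return An object of class `rainfall_series`: list with `per_chrom`
#'   (named list; each element a data frame with `pos`, `class`, `imd` —
#'   distance to the previous SNV, `NA` for the first — and `nn_dist`, the
#'   nearest-neighbor distance) and `excluded` (chromosome names).
#' @export
rainfall <- function(snvs) {
  snvs <- as.data.frame(snvs)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snvs)))
  per <- split(snvs, as.character(snvs$chrom))
  excluded <- names(per)[vapply(per, nrow, integer(1)) < 2]
  per <- per[!names(per) %in% excluded]
  per_chrom <- lapply(per, function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (any(diff(d$pos) == 0)) d <- d[!duplicated(d$pos), , drop = FALSE]
    imd <- c(NA, diff(d$pos))
    lead <- c(diff(d$pos), NA)
    data.frame(pos = d$pos,
               class = normalize_substitution(d$ref, d$alt),
               imd = imd,
               nn_dist = pmin(imd, lead, na.rm = TRUE))
  })
  structure(list(per_chrom = per_chrom, excluded = excluded),
            class = "rainfall_series")
}

#' Detect kataegis chromosomes
#'
#' Kataegis — localized hypermutation of C>T/C>G substitutions — is called
#' per chromosome by a Fisher's exact test: among all C>T/C>G SNVs
#' genome-wide, those whose inter-mutation distance (within the C>T/C>G
#' subset of the same chromosome) falls in the genome-wide lowest `top_pct`
#' (default 3%) are "close"; the 2x2 table contrasts close vs not-close
#' counts on the chromosome against the background. P-values are Bonferroni
#' corrected over the chromosomes tested and a chromosome is significant
#' when the corrected p falls below `alpha` (default 0.01).
#'
#' @param series A `rainfall_series` from [rainfall()].
#' @param top_pct Quantile of inter-mutation distances defining "close"
#'   (default 0.03).
#' @param alpha Significance level on the Bonferroni-corrected p.
#' @param min_total Minimum genome-wide C>T/C>G SNVs to run the test.
#' @param background `"rest"` (default): each chromosome is contrasted
#'   against the rest of the genome, keeping the table cells disjoint;
#'   `"genome"`: against all C>T/C>G SNVs including the chromosome itself.
#' @param distance `"left"` (default) or `"nearest"`: closeness by the
#'   distance to the previous SNV, or by the nearest-neighbor distance.
#'   Left-distance marks one SNV per tight pair and keeps the Fisher counts
#'   calibrated on uniform genomes; nearest-neighbor marks both members,
#'   which overdisperses the table and inflates significance.
#' @return An object of class `kataegis_result`: data frame `table` with one
#'   row per tested chromosome (`chrom`, `n_ct_cg`, `n_close`, `fisher_p`,
#'   `bonferroni_p`, `significant`) plus attributes `threshold_bp` and
#'   `n_tested`; or a list with `status = "no_test"` when too few SNVs.
#' @export
detect_kataegis <- function(series, top_pct = 0.03, alpha = 0.01,
                            min_total = 100,
                            background = c("rest", "genome"),
                            distance = c("left", "nearest")) {
  stopifnot(inherits(series, "rainfall_series"))
  background <- match.arg(background)
  distance <- match.arg(distance)
  # recompute distances within the C>T/C>G subset per chromosome: clusters
  # are clusters of these classes, interleaved other-class SNVs do not break them
  per <- lapply(series$per_chrom, function(d) {
    d <- d[d$class %in% c("C>T", "C>G"), , drop = FALSE]
    if (nrow(d) < 2) return(d[0, , drop = FALSE])
    imd <- c(NA, diff(d$pos))
    lead <- c(diff(d$pos), NA)
    d$imd <- imd
    d$nn_dist <- if (distance == "nearest") pmin(imd, lead, na.rm = TRUE) else imd
    d
  })
  per <- per[vapply(per, nrow, integer(1)) > 0]
  all_d <- unlist(lapply(per, function(d) d$nn_dist), use.names = FALSE)
  all_d <- all_d[!is.na(all_d)]
  n_total <- sum(vapply(per, nrow, integer(1)))
  if (n_total < min_total) {
    return(list(status = "no_test", n_total = n_total, min_total = min_total))
  }
  threshold <- stats::quantile(all_d, top_pct, names = FALSE, type = 1)
  rows <- lapply(names(per), function(ch) {
    d <- per[[ch]]
    close <- !is.na(d$nn_dist) & d$nn_dist <= threshold
    n_close_chr <- sum(close)
    n_chr <- nrow(d)
    if (background == "rest") {
      others <- per[names(per) != ch]
      n_close_bg <- sum(vapply(others, function(x) {
        sum(!is.na(x$nn_dist) & x$nn_dist <= threshold)
      }, numeric(1)))
      n_bg <- sum(vapply(others, nrow, integer(1)))
    } else {
      n_close_bg <- sum(vapply(per, function(x) {
        sum(!is.na(x$nn_dist) & x$nn_dist <= threshold)
      }, numeric(1)))
      n_bg <- n_total
    }
    tab <- matrix(c(n_close_chr, n_chr - n_close_chr,
                    n_close_bg, n_bg - n_close_bg), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    data.frame(chrom = ch, n_ct_cg = n_chr, n_close = n_close_chr,
               fisher_p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_tested <- nrow(tab)
  tab$bonferroni_p <- pmin(1, tab$fisher_p * n_tested)
  tab$significant <- tab$bonferroni_p < alpha
  structure(list(table = tab, threshold_bp = threshold,
                 n_tested = n_tested, status = "ok"),
            class = "kataegis_result")
}

#' @export
print.kataegis_result <- function(x, ...) {
  cat(sprintf("<kataegis_result> %d chromosomes tested, close threshold %d bp\n",
              x$n_tested, as.integer(x$threshold_bp)))
  print(x$table[order(x$table$fisher_p), ], row.names = FALSE)
  invisible(x)
}
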