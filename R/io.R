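# Coordinate discipline: segment files are BED-like (0-based, half-open);
# everything internal is 1-based inclusive. SNV/SNP tables are 1-based
# throughout (VCF convention). TSVs are tab-separated with a header line,
# '#' comments, and "NA" for missing values.

#' Read somatic SNVs from a VCF or TSV
#'
#' TSV input needs columns `chrom`, `pos`, `ref`, `alt`, `depth`,
#' `alt_count` (header line, tab-separated). VCF input (via the vcfR
#' package) takes depth from `DP` and the variant-read count from the
#' second `AD` field of the first sample. Indels and multi-allelic records
#' are skipped with a message reporting the counts.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`; guessed from the extension by default.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `maf`. Records violating `0 <= alt_count <= depth` raise a
#'   format error naming the record.
#' @export
read_snvs <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") return(read_snvs_vcf(path))
  # pin the base columns: a lone "T" allele must not parse as logical
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character",
                                        ref = "character",
                                        alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_count")
  if (!all(need %in% names(d))) {
    stop_invalid(sprintf("SNV TSV must have columns: %s",
                         paste(need, collapse = ", ")))
  }
  validate_snv_table(d[, need])
}

read_snvs_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_invalid("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)[, 1]
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  alt_count <- suppressWarnings(
    as.numeric(vapply(strsplit(ad, ","), function(x) x[2] %||% NA_character_, "")))
  d <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT,
                  depth = dp, alt_count = alt_count,
                  stringsAsFactors = FALSE)
  multi <- grepl(",", d$alt)
  indel <- !multi & (nchar(d$ref) != 1 | nchar(d$alt) != 1)
  if (any(multi) || any(indel)) {
    message(sprintf("skipped %d multi-allelic and %d indel record(s)",
                    sum(multi), sum(indel)))
  }
  d <- d[!multi & !indel, , drop = FALSE]
  if (anyNA(d$depth) || anyNA(d$alt_count)) {
    bad <- which(is.na(d$depth) | is.na(d$alt_count))[1]
    tc_error("tc_format_error", sprintf(
      "record %s:%d lacks DP/AD depth fields", d$chrom[bad], d$pos[bad]))
  }
  validate_snv_table(d)
}

validate_snv_table <- function(d) {
  snv <- nchar(d$ref) == 1 & nchar(d$alt) == 1 &
    toupper(d$ref) %in% c("A", "C", "G", "T") &
    toupper(d$alt) %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    message(sprintf("skipped %d non-SNV record(s)", sum(!snv)))
    d <- d[snv, , drop = FALSE]
  }
  bad <- which(d$alt_count < 0 | d$alt_count > d$depth | d$depth < 1)
  if (length(bad) > 0) {
    tc_error("tc_format_error", sprintf(
      "record %s:%d has alt_count %d outside [0, depth = %d]",
      d$chrom[bad[1]], d$pos[bad[1]], d$alt_count[bad[1]], d$depth[bad[1]]))
  }
  d$maf <- d$alt_count / d$depth
  rownames(d) <- NULL
  d
}

#' Read copy-ratio segments from a BED-like TSV
#'
#' Expects tab-separated columns `chrom`, `start`, `end`, `copy_ratio`
#' (and optionally `baf`). Input coordinates are BED convention (0-based,
#' half-open) and are converted to the 1-based inclusive coordinates used
#' internally.
#'
#' @param path Input file.
#' @return Data frame with 1-based inclusive `start`/`end`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("no such file: %s", path))
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "copy_ratio")
  if (!all(need %in% names(d))) {
    stop_invalid(sprintf("segment TSV must have columns: %s",
                         paste(need, collapse = ", ")))
  }
  if (any(d$start >= d$end)) {
    tc_error("tc_format_error", "segment with start >= end (BED half-open expected)")
  }
  if (any(d$copy_ratio <= 0)) {
    tc_error("tc_format_error", "segment with copy_ratio <= 0")
  }
  d$start <- d$start + 1L  # BED 0-based -> 1-based inclusive
  d
}

#' Write a table as tab-separated text
#'
#' Writes with a header line, `NA` for missing values, and (for segment
#' tables via `bed = TRUE`) converts internal 1-based inclusive coordinates
#' back to BED 0-based half-open.
#'
#' @param d Data frame.
#' @param path Output path.
#' @param bed Convert `start` to 0-based before writing.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(d, path, bed = FALSE) {
  if (bed && all(c("start", "end") %in% names(d))) d$start <- d$start - 1L
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read germline heterozygous SNP BAFs from a TSV
#'
#' Columns `chrom`, `pos`, `depth`, `b_count` (reads supporting the
#' designated B allele); `baf` is computed.
#'
#' @param path Input file.
#' @return Data frame with a `baf` column.
#' @export
read_snps <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("no such file: %s", path))
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "depth", "b_count")
  if (!all(need %in% names(d))) {
    stop_invalid(sprintf("SNP TSV must have columns: %s",
                         paste(need, collapse = ", ")))
  }
  d$baf <- d$b_count / d$depth
  d
}
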