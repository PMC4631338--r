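# Post-calling hard filters for SNVs, indels and differential CNV regions.
#
# Rules are conjunctive: a record passes only if it satisfies every rule,
# so the passed set is invariant to rule order. The report attributes each
# removed record to the first rule it fails, in a fixed rule order.

#' Default hard-filter thresholds
#'
#' SNVs: per-sample total depth >= 10, called allele number = 4 (all four
#' alleles of the two diploid samples called), base quality >= 30, quality
#' by depth >= 5, at most 4 reads with mapping quality zero, not within an
#' indel's reference footprint +/- 1 base, and not in an SNV cluster (any
#' 10-base window containing >= 3 SNV calls; all members of the window are
#' removed). Indels: depth >= 8 and allele number = 4. Differential CNVs:
#' case/control mapped-read ratio beyond 2-fold in either direction and
#' Bonferroni-adjusted p-value < 0.01.
#'
#' @return named list of thresholds.
#' @export
default_filter_thresholds <- function() {
  list(snv_min_depth = 10, snv_allele_number = 4, snv_min_base_quality = 30,
       snv_min_quality_by_depth = 5, snv_max_zero_mapq = 4,
       cluster_window = 10L, cluster_count = 3L, indel_pad = 1L,
       indel_min_depth = 8, indel_allele_number = 4,
       cnv_min_ratio = 2, cnv_adjusted_alpha = 0.01)
}

filter_report <- function(n_input, failed_rule) {
  removed <- failed_rule[!is.na(failed_rule)]
  counts <- if (length(removed)) {
    tab <- table(removed)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  list(n_input = n_input, n_passed = n_input - length(removed),
       counts_per_rule = as.list(counts))
}

# first-failing-rule attribution over a named list of logical fail vectors
attribute_first_failure <- function(fails) {
  n <- length(fails[[1]])
  failed <- rep(NA_character_, n)
  for (rule in names(fails)) {
    hit <- is.na(failed) & fails[[rule]]
    failed[hit] <- rule
  }
  failed
}

# rows with any missing QC field fail with rule "missing_qc"
missing_qc <- function(records, fields) {
  miss <- rep(FALSE, nrow(records))
  for (f in fields) miss <- miss | is.na(records[[f]])
  miss
}

#' Positions belonging to SNV clusters
#'
#' A cluster is any window of `window` consecutive bases containing at
#' least `min_count` SNV calls on one chromosome; every member of such a
#' window is flagged. Linear sweep over sorted positions: positions i and
#' i + min_count - 1 lie in one window iff they are at most window - 1
#' bases apart.
#'
#' @param chrom,pos chromosome and 1-based position vectors of SNV calls.
#' @param window window width in bases.
#' @param min_count calls required to form a cluster.
#' @return logical vector along the input: TRUE for cluster members.
#' @export
snv_cluster_members <- function(chrom, pos, window = 10L, min_count = 3L) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    o <- idx[order(pos[idx])]
    p <- pos[o]
    n <- length(p)
    if (n < min_count) next
    flag <- logical(n)
    for (i in seq_len(n - min_count + 1L)) {
      j <- i + min_count - 1L
      if (p[j] - p[i] <= window - 1L) flag[i:j] <- TRUE
    }
    out[o] <- flag
  }
  out
}

# is each SNV position inside any indel reference footprint +/- pad?
in_indel_region <- function(chrom, pos, indels, pad = 1L) {
  if (is.null(indels) || nrow(indels) == 0) return(logical(length(pos)))
  span <- GenomicRanges::GRanges(
    indels$chrom,
    IRanges::IRanges(start = pmax(1L, indels$pos - pad),
                     end = indels$pos + nchar(indels$ref) - 1L + pad))
  snv <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(snv, span)
}

#' Hard-filter SNV records
#'
#' @param records SNV variant table with the site QC fields populated.
#' @param indels raw indel records (for the indel-region rule), or `NULL`.
#' @param thresholds threshold list, see [default_filter_thresholds()].
#' @return list with `passed` (the surviving records) and `report`
#'   (a filter report: `n_input`, `n_passed`, `counts_per_rule` with
#'   first-failing-rule attribution).
#' @export
filter_snvs <- function(records, indels = NULL,
                        thresholds = default_filter_thresholds()) {
  th <- thresholds
  .assert(all(records$class == "SNV"), "filter_snvs expects SNV records")
  fails <- list(
    missing_qc = missing_qc(records, QC_FIELDS),
    depth = !is.na(records$depth) & records$depth < th$snv_min_depth,
    allele_number = !is.na(records$allele_number) &
      records$allele_number != th$snv_allele_number,
    base_quality = !is.na(records$base_quality) &
      records$base_quality < th$snv_min_base_quality,
    quality_by_depth = !is.na(records$quality_by_depth) &
      records$quality_by_depth < th$snv_min_quality_by_depth,
    zero_mapq_count = !is.na(records$zero_mapq_count) &
      records$zero_mapq_count > th$snv_max_zero_mapq,
    indel_region = in_indel_region(records$chrom, records$pos, indels,
                                   pad = th$indel_pad),
    snv_cluster = snv_cluster_members(records$chrom, records$pos,
                                      window = th$cluster_window,
                                      min_count = th$cluster_count)
  )
  failed <- attribute_first_failure(fails)
  list(passed = records[is.na(failed), , drop = FALSE],
       report = filter_report(nrow(records), failed))
}

#' Hard-filter indel records
#'
#' @param records indel variant table.
#' @param thresholds threshold list.
#' @return list with `passed` and `report`, as [filter_snvs()].
#' @export
filter_indels <- function(records,
                          thresholds = default_filter_thresholds()) {
  th <- thresholds
  .assert(all(records$class %in% c("insertion", "deletion")),
          "filter_indels expects indel records")
  fields <- c("depth", "allele_number")
  fails <- list(
    missing_qc = missing_qc(records, fields),
    depth = !is.na(records$depth) & records$depth < th$indel_min_depth,
    allele_number = !is.na(records$allele_number) &
      records$allele_number != th$indel_allele_number
  )
  failed <- attribute_first_failure(fails)
  list(passed = records[is.na(failed), , drop = FALSE],
       report = filter_report(nrow(records), failed))
}

#' Filter differential CNV regions
#'
#' A CNV region is kept when the case/control mapped-read ratio is beyond
#' 2-fold in either direction (ratio > 2 or ratio < 1/2) and its
#' Bonferroni-adjusted p-value (raw p times `n_tests`) is below 0.01.
#'
#' @param features interval feature data frame (CNV rows with `ratio` and
#'   raw `p_value`).
#' @param n_tests total number of tests for the Bonferroni correction
#'   (defaults to the number of input features).
#' @param thresholds threshold list.
#' @return list with `passed` and `report`.
#' @export
filter_differential_cnv <- function(features, n_tests = nrow(features),
                                    thresholds = default_filter_thresholds()) {
  th <- thresholds
  fails <- list(
    missing_ratio = is.na(features$ratio),
    missing_p = is.na(features$p_value),
    ratio = !is.na(features$ratio) &
      !(features$ratio > th$cnv_min_ratio |
          features$ratio < 1 / th$cnv_min_ratio),
    adjusted_p = !is.na(features$p_value) &
      !(pmin(1, features$p_value * n_tests) < th$cnv_adjusted_alpha)
  )
  failed <- attribute_first_failure(fails)
  list(passed = features[is.na(failed), , drop = FALSE],
       report = filter_report(nrow(features), failed))
}
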