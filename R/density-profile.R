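# Coverage-normalized variant density in fixed-width genomic bins.

#' Tile chromosomes into fixed-width bins
#'
#' Bins are 0-based half-open, anchored at coordinate 0 on every
#' chromosome; the last partial bin keeps its true width.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin_size bin width in bases.
#' @return data frame `chrom`, `start`, `end`.
#' @export
tile_bins <- function(chrom_lengths, bin_size = 1e6) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Profile variant density in genomic bins
#'
#' Assigns each variant to the bin containing its position (1-based VCF
#' position converted to 0-based) and divides the per-bin variant count by
#' the number of bases in the bin covered by at least three reads. Bins
#' with zero covered bases keep a missing density but are retained.
#'
#' @param variants variant table (`chrom`, `pos`).
#' @param coverage per-bin coverage data frame (`chrom`, `start`, `end`,
#'   `covered_bases`) on the same bin grid, e.g. from
#'   [generate_coverage()] or [read_coverage_bedgraph()].
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin_size bin width in bases.
#' @return data frame of density bins: `chrom`, `start`, `end`,
#'   `n_variants`, `n_covered_bases`, `density`.
#' @export
profile_density <- function(variants, coverage, chrom_lengths,
                            bin_size = 1e6) {
  bins <- tile_bins(chrom_lengths, bin_size)
  if (nrow(variants)) {
    over <- variants$pos - 1L >= chrom_lengths[variants$chrom] |
      variants$pos < 1L
    if (any(is.na(over)) || any(over)) {
      stop("variant beyond chromosome length: coordinate mismatch at ",
           variants$chrom[which(is.na(over) | over)[1]], ":",
           variants$pos[which(is.na(over) | over)[1]])
    }
  }
  key <- paste(bins$chrom, bins$start %/% bin_size)
  vkey <- paste(variants$chrom, (variants$pos - 1L) %/% bin_size)
  counts <- table(factor(vkey, levels = key))
  bins$n_variants <- as.integer(counts)
  ckey <- paste(coverage$chrom, coverage$start %/% bin_size)
  m <- match(key, ckey)
  .assert(!anyNA(m), "coverage does not cover every bin of the grid")
  bins$n_covered_bases <- coverage$covered_bases[m]
  bins$density <- ifelse(bins$n_covered_bases > 0,
                         bins$n_variants / bins$n_covered_bases, NA_real_)
  bins
}

#' Correlate two density profiles
#'
#' Pearson correlation of per-bin densities over the bins where both
#' profiles have a defined density.
#'
#' @param snv_bins,indel_bins density-bin data frames on the same grid.
#' @return list with `pearson_r`, `r_squared`, and `n_pairs`.
#' @export
correlate_densities <- function(snv_bins, indel_bins) {
  .assert(nrow(snv_bins) == nrow(indel_bins) &&
            all(snv_bins$chrom == indel_bins$chrom) &&
            all(snv_bins$start == indel_bins$start),
          "density profiles must share one bin grid")
  ok <- !is.na(snv_bins$density) & !is.na(indel_bins$density)
  if (sum(ok) < 3) stop("fewer than 3 complete bin pairs")
  r <- stats::cor(snv_bins$density[ok], indel_bins$density[ok])
  list(pearson_r = r, r_squared = r^2, n_pairs = sum(ok))
}

#' Extract extreme-density bins
#'
#' Top bins are the `ceiling(fraction * n)` highest-density bins; bottom
#' bins the same count of lowest-density bins after removing bins that
#' overlap an assembly-gap interval (low density caused by gaps is an
#' artifact, not conservation). Ties are broken by (chromosome, start)
#' order; bins without a defined density are ignored.
#'
#' @param bins density-bin data frame.
#' @param fraction extreme fraction, in (0, 0.5].
#' @param gap_mask optional data frame of gap intervals (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @return list with `top` and `bottom` data frames.
#' @export
extreme_bins <- function(bins, fraction = 0.05, gap_mask = NULL) {
  .assert(fraction > 0 && fraction <= 0.5, "fraction must be in (0, 0.5]")
  usable <- bins[!is.na(bins$density), , drop = FALSE]
  n_take <- ceiling(fraction * nrow(usable))
  chrom_rank <- match(usable$chrom, unique(bins$chrom))
  ord_hi <- order(-usable$density, chrom_rank, usable$start)
  top <- usable[ord_hi[seq_len(min(n_take, nrow(usable)))], , drop = FALSE]

  bottom_pool <- usable
  if (!is.null(gap_mask) && nrow(gap_mask)) {
    bgr <- GenomicRanges::GRanges(
      bottom_pool$chrom,
      IRanges::IRanges(bottom_pool$start + 1L, bottom_pool$end))
    ggr <- GenomicRanges::GRanges(
      gap_mask$chrom, IRanges::IRanges(gap_mask$start + 1L, gap_mask$end))
    bottom_pool <- bottom_pool[!IRanges::overlapsAny(bgr, ggr), ,
                               drop = FALSE]
  }
  chrom_rank_b <- match(bottom_pool$chrom, unique(bins$chrom))
  ord_lo <- order(bottom_pool$density, chrom_rank_b, bottom_pool$start)
  bottom <- bottom_pool[ord_lo[seq_len(min(n_take, nrow(bottom_pool)))], ,
                        drop = FALSE]
  list(top = top, bottom = bottom)
}
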