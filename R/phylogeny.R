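# Strain phylogeny: Nei's dA net nucleotide substitution distance between
# genotype vectors, and a UPGMA tree over all strains.

# per-site probability that one allele drawn from gt_a differs from one
# drawn from gt_b (NA when either genotype is missing)
.pi_between <- function(a1, a2, b1, b2) {
  ((a1 != b1) + (a1 != b2) + (a2 != b1) + (a2 != b2)) / 4
}

# split a panel genotype column into two integer allele vectors (NA = missing)
.allele_cols <- function(gt) {
  m <- matrix(NA_integer_, nrow = length(gt), ncol = 2)
  ok <- gt != "./." & !is.na(gt)
  if (any(ok)) {
    parts <- strsplit(gt[ok], "/", fixed = TRUE)
    m[ok, 1] <- as.integer(vapply(parts, `[`, character(1), 1))
    m[ok, 2] <- as.integer(vapply(parts, `[`, character(1), 2))
  }
  m
}

#' Net nucleotide substitution distance between two strains
#'
#' Nei's dA: `dA = pi_XY - (pi_X + pi_Y) / 2`, where `pi_XY` is the mean
#' per-site probability that an allele drawn from strain X differs from an
#' allele drawn from strain Y, and `pi_X`, `pi_Y` are the mean per-site
#' within-strain heterozygosities (probability that two alleles drawn with
#' replacement from the strain differ: 1/2 for a heterozygote, 0 for a
#' homozygote). Sites missing a genotype in either strain are excluded
#' (pairwise deletion); the result is floored at 0.
#'
#' @param panel a `panel_matrix`.
#' @param strain_a,strain_b strain (column) names.
#' @return non-negative distance.
#' @export
net_distance <- function(panel, strain_a, strain_b) {
  ga <- .allele_cols(panel$genotypes[, strain_a])
  gb <- .allele_cols(panel$genotypes[, strain_b])
  ok <- !is.na(ga[, 1]) & !is.na(gb[, 1])
  if (!any(ok)) stop("no shared genotyped sites between ", strain_a,
                     " and ", strain_b)
  pi_xy <- mean(.pi_between(ga[ok, 1], ga[ok, 2], gb[ok, 1], gb[ok, 2]))
  pi_x <- mean((ga[ok, 1] != ga[ok, 2]) / 2)
  pi_y <- mean((gb[ok, 1] != gb[ok, 2]) / 2)
  max(0, pi_xy - (pi_x + pi_y) / 2)
}

#' Pairwise net-distance matrix over all panel strains
#'
#' @param panel a `panel_matrix`.
#' @param strains strain names (default: all panel columns).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(panel, strains = colnames(panel$genotypes)) {
  n <- length(strains)
  d <- matrix(0, n, n, dimnames = list(strains, strains))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- net_distance(panel, strains[i], strains[j])
    }
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Unweighted pair-group clustering with arithmetic means: at each step
#' the two closest clusters merge, and distances to the merged cluster are
#' the size-weighted average of the member distances (average linkage).
#' Node heights are half the merge distance, so the tree is ultrametric.
#' Labels are sorted lexicographically before clustering so that ties are
#' broken deterministically by smallest member label.
#'
#' @param d symmetric distance matrix with strain labels, or a `dist`.
#' @return an ultrametric `ape` `phylo` tree.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  .assert(is.matrix(d) && nrow(d) == ncol(d) && nrow(d) >= 2,
          "need a square distance matrix over >= 2 strains")
  .assert(all(is.finite(d)), "non-finite distance entries")
  .assert(max(abs(d - t(d))) <= 1e-12, "distance matrix must be symmetric")
  .assert(all(diag(d) == 0), "distance diagonal must be zero")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  h <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(h)
}
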