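# Strain comparison: case-specific variant derivation, five-way genotype
# group classification, and QC / validation statistics.

GROUPS <- c("Group1", "Group2", "Group3", "Group4", "Group5")

#' Classify a (case, control) genotype pair into a genotype group
#'
#' The five groups of case-specific variants, by (case, control) genotype:
#' Group1 = (0/1, 0/0), Group2 = (1/1, 0/0), Group3 = (1/1, 0/1),
#' Group4 = (1/2, 0/0), Group5 = (1/2, 0/1). Any other pair — including
#' any pair with a missing genotype — is `NotSpecific`. Genotypes are
#' unordered (`1/0` is `0/1`); allele indices above 2 are rejected since
#' the scheme covers at most two alternate alleles.
#'
#' @param case_gt,control_gt genotype code vectors (recycled to a common
#'   length).
#' @return character vector of group labels.
#' @export
classify_group <- function(case_gt, control_gt) {
  n <- max(length(case_gt), length(control_gt))
  case_gt <- normalize_gt(rep_len(case_gt, n))
  control_gt <- normalize_gt(rep_len(control_gt, n))
  all_gt <- c(case_gt, control_gt)
  idx <- suppressWarnings(
    as.integer(unlist(strsplit(all_gt[all_gt != "./."], "/", fixed = TRUE))))
  if (length(idx) && any(idx > 2L)) {
    stop("allele index above 2: the genotype-group scheme covers at most ",
         "two alternate alleles")
  }
  key <- paste(case_gt, control_gt)
  map <- stats::setNames(GROUP_GENOTYPES$group,
                         paste(GROUP_GENOTYPES$case,
                               GROUP_GENOTYPES$control))
  out <- map[key]
  out[is.na(out)] <- "NotSpecific"
  unname(out)
}

# alt alleles (as bases) carried by the case genotype at one record
case_alt_bases <- function(gt, alt) {
  a <- gt_alleles(gt)
  if (is.null(a)) return(character(0))
  a <- unique(a[a >= 1L])
  if (!length(a)) return(character(0))
  strsplit(alt, ",", fixed = TRUE)[[1]][a]
}

#' Derive case-specific variants and comparison statistics
#'
#' Specific variants are the records whose (case, control) genotype pair
#' falls in one of the five groups. Transition/transversion counts are
#' taken over the alternate alleles carried by the case genotype only,
#' per allele at multi-allelic SNV sites.
#'
#' @param records filtered variant table.
#' @param case,control sample names of the case and control strains.
#' @return list with `specific` (the specific records, with a `group`
#'   column) and `stats`: `n_specific_snvs`, `n_specific_indels`,
#'   `group_counts` (per variant class), `n_homozygous`,
#'   `homozygosity_pct` (case strain, over its variant sites),
#'   `n_transitions`, `n_transversions`, `titv`.
#' @export
derive_specific <- function(records, case, control) {
  case_col <- paste0("gt_", case)
  control_col <- paste0("gt_", control)
  .assert(all(c(case_col, control_col) %in% names(records)),
          "case/control samples not found in the variant table")
  grp <- classify_group(records[[case_col]], records[[control_col]])
  records$group <- grp
  specific <- records[grp %in% GROUPS, , drop = FALSE]

  is_snv <- specific$class == "SNV"
  group_counts <- function(sel) {
    stats::setNames(
      vapply(GROUPS, function(g) sum(specific$group[sel] == g),
             integer(1)), GROUPS)
  }
  snv_specific <- specific[is_snv, , drop = FALSE]
  ti <- tv <- 0L
  if (nrow(snv_specific)) {
    for (i in seq_len(nrow(snv_specific))) {
      alts <- case_alt_bases(snv_specific[[case_col]][i],
                             snv_specific$alt[i])
      if (!length(alts)) next
      tr <- is_transition(snv_specific$ref[i], alts)
      ti <- ti + sum(tr); tv <- tv + sum(!tr)
    }
  }
  hom <- homozygosity(records, case)
  list(
    specific = specific,
    stats = list(
      n_specific_snvs = sum(is_snv),
      n_specific_indels = sum(!is_snv),
      group_counts = list(SNV = as.list(group_counts(is_snv)),
                          indel = as.list(group_counts(!is_snv))),
      n_homozygous = hom$count,
      homozygosity_pct = hom$pct,
      n_transitions = ti,
      n_transversions = tv,
      titv = titv_ratio(ti, tv)
    )
  )
}

#' Homozygosity of one strain's variant calls
#'
#' Counts, among the sites where the strain carries at least one alternate
#' allele, those with a homozygous-variant genotype (a/a, a >= 1). The
#' percentage uses the strain's variant sites as denominator; with zero
#' variant sites it is reported as missing rather than 0/0.
#'
#' @param records variant table.
#' @param strain sample name.
#' @return list with `count` (homozygous-variant sites), `n_variant_sites`,
#'   and `pct` (two decimals, half away from zero).
#' @export
homozygosity <- function(records, strain) {
  gt <- records[[paste0("gt_", strain)]]
  .assert(!is.null(gt), paste0("no genotypes for strain ", strain))
  var_sites <- vapply(gt, gt_is_variant, logical(1))
  hom <- vapply(gt, gt_is_hom_var, logical(1))
  n_var <- sum(var_sites)
  list(count = sum(hom), n_variant_sites = n_var,
       pct = pct(sum(hom), n_var))
}

#' Validate a call set against a truth panel
#'
#' Sensitivity is the fraction of known-polymorphic positions at which the
#' call set has a call; specificity is the fraction of known
#' non-polymorphic positions at which it has none. Both are percentages to
#' two decimals; an empty truth side yields a missing value, not zero.
#'
#' @param called_sites data frame of called positions (`chrom`, `pos`).
#' @param truth truth panel data frame (`chrom`, `pos`, `status` with
#'   values `variant` / `invariant`); a position may not carry both.
#' @return list: `n_truth_variant_sites`, `n_called_at_truth_variant_sites`,
#'   `sensitivity_pct`, `n_truth_invariant_sites`, `n_confirmed_invariant`,
#'   `specificity_pct`.
#' @export
validate_against_truth <- function(called_sites, truth) {
  tv <- truth[truth$status == "variant", , drop = FALSE]
  ti <- truth[truth$status == "invariant", , drop = FALSE]
  both <- intersect(paste(tv$chrom, tv$pos), paste(ti$chrom, ti$pos))
  if (length(both)) {
    stop("positions present in both truth sets: ", both[1])
  }
  called <- unique(paste(called_sites$chrom, called_sites$pos))
  n_hit <- sum(paste(tv$chrom, tv$pos) %in% called)
  n_conf <- sum(!(paste(ti$chrom, ti$pos) %in% called))
  list(
    n_truth_variant_sites = nrow(tv),
    n_called_at_truth_variant_sites = n_hit,
    sensitivity_pct = pct(n_hit, nrow(tv)),
    n_truth_invariant_sites = nrow(ti),
    n_confirmed_invariant = n_conf,
    specificity_pct = pct(n_conf, nrow(ti))
  )
}
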