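# Candidate prioritization: protein-affecting variant selection, strain
# panel consistency filtering, olfactory-receptor gene exclusion, and
# SV/CNV-to-gene interval mapping.

PAV_REASONS <- c("nonsynonymous", "stopgain", "stoploss", "splicing",
                 "frameshift_insertion", "frameshift_deletion",
                 "ncRNA_exonic")

#' Flag protein-affecting variants
#'
#' A variant is protein-affecting (PAV) when its annotation can alter a
#' protein product: nonsynonymous, stopgain, stoploss, splicing, frameshift
#' indels, or exonic ncRNA. Synonymous, UTR, intronic, up/downstream and
#' intergenic variants are not. Unknown vocabulary is an error, never a
#' silent non-PAV.
#'
#' @param annotations annotation data frame (`region_class`,
#'   `exonic_effect`).
#' @return the input with `is_pav` (logical) and `pav_reason` (character,
#'   `NA` for non-PAVs) columns appended.
#' @export
flag_pav <- function(annotations) {
  bad <- setdiff(unique(annotations$region_class), REGION_CLASSES)
  if (length(bad)) stop("unknown region_class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(annotations$exonic_effect), EXONIC_EFFECTS)
  if (length(bad)) stop("unknown exonic_effect: ", paste(bad, collapse = ", "))
  reason <- rep(NA_character_, nrow(annotations))
  reason[annotations$region_class == "splicing"] <- "splicing"
  reason[annotations$region_class == "ncRNA_exonic"] <- "ncRNA_exonic"
  ex <- annotations$region_class == "exonic" &
    annotations$exonic_effect %in% setdiff(PAV_REASONS,
                                           c("splicing", "ncRNA_exonic"))
  reason[ex] <- annotations$exonic_effect[ex]
  annotations$is_pav <- !is.na(reason)
  annotations$pav_reason <- reason
  annotations
}

#' Strain-panel consistency filter for candidate PAVs
#'
#' A PAV survives only if it is homozygous-variant (a/a, a >= 1) in the
#' focal case strain AND homozygous-variant for the same alternate allele
#' in every case-consistent panel strain AND not homozygous-variant for
#' that allele in any control-background strain. A missing panel genotype
#' in a case-consistent strain fails the requirement (homozygosity must be
#' observed); a missing genotype in a background strain does not exclude
#' the variant (absence of evidence cannot demonstrate the background
#' carries it). Sites absent from the panel are dropped. Heterozygous
#' focal PAVs are excluded from candidates but returned in a side list.
#' An empty panel passes everything through with a warning.
#'
#' @param pavs PAV variant table (`chrom`, `pos`, and the focal `gt_`
#'   columns).
#' @param panel a `panel_matrix`.
#' @param case_strain focal case sample name.
#' @param case_consistent_strains,background_strains panel strain names
#'   (default: taken from the panel's strain-group labels).
#' @return list with `surviving` (PAV rows passing the rule),
#'   `heterozygous` (focal-het PAV rows, reported but not candidates), and
#'   `n_dropped`.
#' @export
panel_filter <- function(pavs, panel, case_strain,
                         case_consistent_strains = NULL,
                         background_strains = NULL) {
  if (is.null(case_consistent_strains)) {
    case_consistent_strains <-
      panel$groups$strain[panel$groups$group == "case_consistent"]
  }
  if (is.null(background_strains)) {
    background_strains <-
      panel$groups$strain[panel$groups$group == "control_background"]
  }
  case_consistent_strains <- setdiff(case_consistent_strains, case_strain)
  if (nrow(panel$genotypes) == 0) {
    warning("empty strain panel: all PAVs pass through unfiltered")
    return(list(surviving = pavs,
                heterozygous = pavs[0, , drop = FALSE],
                n_dropped = 0L))
  }
  absent <- setdiff(c(case_consistent_strains, background_strains),
                    colnames(panel$genotypes))
  if (length(absent)) {
    stop("strains named in groups but absent from panel: ",
         paste(absent, collapse = ", "))
  }
  case_gt <- pavs[[paste0("gt_", case_strain)]]
  .assert(!is.null(case_gt), "focal case genotypes missing from PAV table")
  hom <- vapply(case_gt, gt_is_hom_var, logical(1))
  het <- vapply(case_gt, function(g) {
    a <- gt_alleles(g); !is.null(a) && a[1] != a[2] && any(a >= 1L)
  }, logical(1))

  site_idx <- match(paste(pavs$chrom, pavs$pos),
                    rownames(panel$genotypes))
  keep <- hom & !is.na(site_idx)
  for (s in case_consistent_strains) {
    g <- panel$genotypes[site_idx, s]
    keep <- keep & !is.na(g) & g == case_gt  # same hom-var genotype required
  }
  for (s in background_strains) {
    g <- panel$genotypes[site_idx, s]
    keep <- keep & !(!is.na(g) & g == case_gt)  # missing does not exclude
  }
  keep[is.na(keep)] <- FALSE
  list(surviving = pavs[keep, , drop = FALSE],
       heterozygous = pavs[het, , drop = FALSE],
       n_dropped = sum(!keep))
}

#' Exclude olfactory-receptor genes
#'
#' OR genes form a huge, rapidly mutating family whose strain-specific
#' variants are treated as background mutation rather than candidate
#' signal. Genes without a model are kept with a warning (their OR status
#' cannot be confirmed).
#'
#' @param gene_ids candidate gene identifiers.
#' @param genes gene model data frame with `is_olfactory_receptor`.
#' @return list with `kept` (non-OR gene ids), `n_removed`, and
#'   `n_unmodelled`.
#' @export
exclude_or_genes <- function(gene_ids, genes) {
  m <- match(gene_ids, genes$gene_id)
  unmodelled <- is.na(m)
  if (any(unmodelled)) {
    warning(sum(unmodelled), " gene(s) without a model kept: ",
            "olfactory-receptor status unconfirmed")
  }
  is_or <- !unmodelled & genes$is_olfactory_receptor[m]
  list(kept = gene_ids[!is_or], n_removed = sum(is_or),
       n_unmodelled = sum(unmodelled))
}

#' Map interval features onto genes
#'
#' A gene is affected by a feature when their 0-based half-open intervals
#' share at least one base.
#'
#' @param features interval feature data frame (`chrom`, `start`, `end`).
#' @param genes gene model data frame.
#' @return data frame with one row per (gene, feature) overlap: `gene_id`,
#'   `feature_row` (row index into `features`), `feature_kind`.
#' @export
overlap_features_with_genes <- function(features, genes) {
  if (nrow(features) == 0 || nrow(genes) == 0) {
    return(data.frame(gene_id = character(0), feature_row = integer(0),
                      feature_kind = character(0), stringsAsFactors = FALSE))
  }
  fgr <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start + 1L, features$end))
  ggr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(ggr, fgr)
  gi <- S4Vectors::queryHits(ov); fi <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    gene_id = genes$gene_id[gi],
    feature_row = fi,
    feature_kind = features$feature_kind[fi],
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id, out$feature_row), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}
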