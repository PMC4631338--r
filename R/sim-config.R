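# Simulation configuration: the study conditions for the synthetic cohort.

#' Simulation configuration for the synthetic study
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the published study conditions for an inbred diabetic/control rat strain
#' pair: a heavily homozygous case genome, genotype-group mixture matching
#' the published five-group SNV table (3.6% / 92.9% / 3.5% / ~0 / ~0),
#' target Ti/Tv of 2.10, a strain panel with one additional case-consistent
#' strain and eleven control-background strains, and desk-scale genome,
#' gene, PPI and expression dimensions chosen so the whole pipeline runs in
#' seconds while every downstream statistic remains well-powered.
#'
#' @param chromosome_lengths named vector of chromosome lengths in bases.
#'   Two 10-Mb chromosomes by default, so 1-Mb binning yields 20 bins.
#' @param n_variants number of focal SNV sites.
#' @param n_indels number of focal indel sites (about a tenth of the SNVs,
#'   as observed for strain-specific calls).
#' @param target_titv target transition/transversion ratio of simulated
#'   substitutions.
#' @param het_fraction target proportion of heterozygous genotypes among the
#'   case strain's variant genotypes, or `NULL` (default) to take the value
#'   implied by `group_mixture` (groups 1 and 5 are the heterozygous case
#'   genotypes). When larger than the implied value, extra non-specific
#'   heterozygous sites (0/1 in both strains) are appended to reach it.
#' @param group_mixture proportions over the five genotype groups
#'   (case,control) = (0/1,0/0), (1/1,0/0), (1/1,0/1), (1/2,0/0), (1/2,0/1).
#'   Must sum to 1.
#' @param indel_group_mixture same, for indels (published shares 5.0% /
#'   81.9% / 13.1% with the remainder folded into group 2).
#' @param qc_fail_fraction fraction of sites violating each hard-filter QC
#'   rule (drawn independently per rule).
#' @param n_panel_strains number of strains in the panel (including the two
#'   focal strains).
#' @param panel_tree rooted `phylo` tree with branch lengths in expected
#'   substitutions per site, or `NULL` for the default strain tree built by
#'   [default_panel_tree()].
#' @param n_panel_sites number of tree-evolved panel sites (in addition to
#'   the focal variant sites, which are always included in the panel).
#' @param panel_case_consistency probability that a case-consistent panel
#'   strain is homozygous-variant at a case hom-var focal site.
#' @param panel_background_leak probability that a control-background strain
#'   is homozygous-variant at such a site.
#' @param panel_missing_fraction fraction of panel genotypes set to `./.`.
#' @param n_genes number of gene models.
#' @param or_fraction proportion of genes flagged olfactory-receptor.
#' @param ppi_n_edges number of background PPI edges.
#' @param prior_gene_count number of prior (known disease) genes.
#' @param planted_enriched_genes gene ids (or a count, resolved to ids at
#'   generation time) whose partner sets are enriched for prior genes.
#' @param planted_degree number of PPI partners given to each planted gene.
#' @param enrichment_odds_ratio odds ratio by which planted genes' partners
#'   favour prior genes over the background prior fraction.
#' @param expr_n_genes number of genes on the expression matrix.
#' @param expr_samples_per_condition biological replicates per
#'   (strain, tissue, time) cell.
#' @param tissues,time_points expression design levels.
#' @param planted_de_genes number of differentially expressed genes planted
#'   (fold change `de_fold_change`, one designated tissue, all time points).
#' @param de_fold_change linear fold change of planted DE genes.
#' @param expr_sd standard deviation of log2 expression noise.
#' @param planted_dc_genes number of differentially co-expressed genes
#'   planted (correlation `dc_rho_case` with a partner gene in case samples,
#'   `dc_rho_control` in control samples).
#' @param dc_rho_case,dc_rho_control planted correlations.
#' @param truth_n_variant,truth_n_invariant sizes of the truth panel of
#'   known polymorphic / non-polymorphic positions.
#' @param truth_sensitivity,truth_specificity probabilities used to plant
#'   the truth panel's overlap with the call set.
#' @param n_sv,n_cnv numbers of structural-variant and CNV intervals.
#' @param case_strain,control_strain focal sample names.
#' @param seed global random seed; every component derives an independent
#'   substream from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chromosome_lengths = c(chr1 = 10e6, chr2 = 10e6),
                       n_variants = 20000,
                       n_indels = 2000,
                       target_titv = 2.10,
                       het_fraction = NULL,
                       group_mixture = c(0.036, 0.929, 0.035, 0, 0),
                       indel_group_mixture = c(0.050, 0.819, 0.131, 0, 0),
                       qc_fail_fraction = 0.02,
                       n_panel_strains = 14,
                       panel_tree = NULL,
                       n_panel_sites = 2000,
                       panel_case_consistency = 0.90,
                       panel_background_leak = 0.05,
                       panel_missing_fraction = 0.03,
                       n_genes = 400,
                       or_fraction = 0.15,
                       ppi_n_edges = 4000,
                       prior_gene_count = 100,
                       planted_enriched_genes = 3,
                       planted_degree = 40,
                       enrichment_odds_ratio = 10,
                       expr_n_genes = 400,
                       expr_samples_per_condition = 5,
                       tissues = c("liver", "muscle", "adipose"),
                       time_points = 1:5,
                       planted_de_genes = 3,
                       de_fold_change = 4,
                       expr_sd = 0.4,
                       planted_dc_genes = 3,
                       dc_rho_case = 0.9,
                       dc_rho_control = -0.9,
                       truth_n_variant = 800,
                       truth_n_invariant = 400,
                       truth_sensitivity = 0.95,
                       truth_specificity = 0.99,
                       n_sv = 60,
                       n_cnv = 120,
                       case_strain = "GK",
                       control_strain = "WISTAR",
                       seed = 20151103) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  .assert(length(cfg$chromosome_lengths) >= 1 &&
            !is.null(names(cfg$chromosome_lengths)) &&
            all(cfg$chromosome_lengths > 0),
          "chromosome_lengths must be a named vector of positive lengths")
  .assert(abs(sum(cfg$group_mixture) - 1) <= 1e-9,
          "group_mixture must sum to 1")
  .assert(abs(sum(cfg$indel_group_mixture) - 1) <= 1e-9,
          "indel_group_mixture must sum to 1")
  .assert(length(cfg$group_mixture) == 5, "group_mixture needs 5 entries")
  .assert(all(cfg$group_mixture >= 0), "group_mixture must be non-negative")
  .assert(cfg$target_titv > 0, "target_titv must be positive")
  counts <- c(cfg$n_variants, cfg$n_indels, cfg$n_panel_strains,
              cfg$n_genes, cfg$ppi_n_edges, cfg$prior_gene_count,
              cfg$expr_samples_per_condition)
  .assert(all(counts >= 0), "all counts must be non-negative")
  if (!is.null(cfg$het_fraction)) {
    implied <- cfg$group_mixture[1] + cfg$group_mixture[5]
    .assert(cfg$het_fraction >= 0 && cfg$het_fraction <= 1,
            "het_fraction must be in [0, 1]")
    .assert(cfg$het_fraction == 0 || cfg$het_fraction >= implied - 1e-12,
            paste0("het_fraction below the value implied by group_mixture (",
                   signif(implied, 3), "); lower groups 1/5 instead"))
    if (cfg$het_fraction == 0) {
      .assert(implied == 0,
              "het_fraction = 0 requires group_mixture[1] = group_mixture[5] = 0")
    }
  }
  invisible(cfg)
}

#' Default strain-panel tree
#'
#' A rooted tree for the panel strains with a deep split between the case
#' clade (the two case strains, joined by a short branch under a long
#' case-clade stem) and the control-background clade of Wistar-derived
#' strains, plus an outgroup. Branch lengths are per-site substitution
#' probabilities, scaled so that inbred laboratory strains differ at a few
#' percent of panel sites.
#'
#' @param cfg a [sim_config()].
#' @return an `ape` `phylo` object whose tip labels name the panel strains;
#'   attributes `case_consistent` and `control_background` carry the strain
#'   group labels.
#' @export
default_panel_tree <- function(cfg) {
  case_strains <- c(cfg$case_strain, "GK_Ox")
  background <- c("SHR_NHsd", "SHRSP_Gla", "SHR_OlaIpcv", "WKY_NCrl",
                  "WKY_Gla", "WKY_NHsd", "LEW_Crl", "LEW_NcrlBR",
                  "WAG_Rij", "MHS_Gib", "MNS_Gib")
  others <- cfg$control_strain
  n_named <- length(case_strains) + length(background) + length(others)
  extra <- max(0, cfg$n_panel_strains - n_named - 1)  # -1 for outgroup
  others <- c(others, if (extra > 0) sprintf("STRAIN_%02d", seq_len(extra)))

  # case clade: long stem, short within-clade branches
  case_nwk <- sprintf("(%s:0.004,%s:0.004):0.06",
                      case_strains[1], case_strains[2])
  # control clade: control focal strain sits among the Wistar-derived strains
  bg_tips <- paste(sprintf("%s:0.01", c(background, others)), collapse = ",")
  bg_nwk <- sprintf("(%s):0.02", bg_tips)
  nwk <- sprintf("((%s,%s):0.02,OUTGROUP:0.12);", case_nwk, bg_nwk)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "case_consistent") <- setdiff(case_strains, cfg$case_strain)
  attr(tree, "control_background") <- background
  tree
}
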