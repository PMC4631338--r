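# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth. One global seed drives independent per-component substreams
# (see component_seed), so regenerating one component leaves the others'
# draws untouched.

BASES <- c("A", "C", "G", "T")
.TI_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

GROUP_GENOTYPES <- data.frame(
  group = c("Group1", "Group2", "Group3", "Group4", "Group5"),
  case = c("0/1", "1/1", "1/1", "1/2", "1/2"),
  control = c("0/0", "0/0", "0/1", "0/0", "0/1"),
  stringsAsFactors = FALSE
)

# unique random 1-based positions across chromosomes, proportional to length
sample_positions <- function(chrom_lengths, n, exclude_key = character()) {
  chroms <- names(chrom_lengths)
  out_chrom <- character(0); out_pos <- integer(0)
  need <- n
  while (need > 0) {
    ch <- sample(chroms, need, replace = TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    po <- vapply(ch, function(c) sample.int(chrom_lengths[[c]], 1L),
                 integer(1))
    key <- paste(ch, po)
    keep <- !duplicated(key) & !(key %in% exclude_key) &
      !(key %in% paste(out_chrom, out_pos))
    out_chrom <- c(out_chrom, ch[keep]); out_pos <- c(out_pos, po[keep])
    need <- n - length(out_pos)
  }
  ord <- order(match(out_chrom, chroms), out_pos)
  data.frame(chrom = out_chrom[ord], pos = out_pos[ord],
             stringsAsFactors = FALSE)
}

# draw an alternate base given ref, honouring the Ti/Tv target; `taken`
# excludes bases already used at the site
draw_alt <- function(ref, titv, taken = character(0)) {
  cand <- setdiff(BASES, c(ref, taken))
  w <- ifelse(cand == .TI_PARTNER[[ref]], 2 * titv, 1)
  sample(cand, 1L, prob = w)
}

# plant a violating value for one QC rule
qc_violations <- list(
  depth = function(n) sample(0:9, n, replace = TRUE),
  allele_number = function(n) sample(c(1L, 2L, 3L), n, replace = TRUE),
  base_quality = function(n) stats::runif(n, 10, 29.9),
  quality_by_depth = function(n) stats::runif(n, 0, 4.9),
  zero_mapq_count = function(n) sample(5:12, n, replace = TRUE)
)

#' Generate the two-sample focal VCF with ground truth
#'
#' Emits `cfg$n_variants` SNVs and `cfg$n_indels` indels for the focal
#' case/control strain pair. Genotype pairs are drawn from the configured
#' five-group mixture; substitution types are drawn so the realized Ti/Tv
#' matches `cfg$target_titv` within sampling error; per-record QC fields
#' (depth, allele number, base quality, quality by depth, zero-mapq count)
#' are populated, with a `cfg$qc_fail_fraction` of records violating each
#' hard-filter rule. When `cfg$het_fraction` exceeds the heterozygosity
#' implied by the group mixture, non-specific `0/1 , 0/1` sites are added
#' to reach it. Positions are unique within a chromosome.
#'
#' @param cfg a [sim_config()].
#' @param path output VCF path, or `NULL` to skip writing.
#' @return list with `variants` (the variant table), `path`, and `truth`
#'   (data frame with each site's true group and per-rule QC cleanliness).
#' @export
generate_focal_vcf <- function(cfg, path = NULL) {
  validate_sim_config(cfg)
  res <- with_component_seed(cfg$seed, "focal_vcf", {
    n_extra <- 0L
    implied_het <- cfg$group_mixture[1] + cfg$group_mixture[5]
    if (!is.null(cfg$het_fraction) && cfg$het_fraction > implied_het) {
      t <- cfg$het_fraction
      n_extra <- round((t * cfg$n_variants - implied_het * cfg$n_variants) /
                         (1 - t))
    }
    n_snv <- cfg$n_variants + n_extra
    sites <- sample_positions(cfg$chromosome_lengths, n_snv + cfg$n_indels)
    idx_snv <- sample.int(nrow(sites), n_snv)
    snv_sites <- sites[sort(idx_snv), , drop = FALSE]
    indel_sites <- sites[sort(setdiff(seq_len(nrow(sites)), idx_snv)), ,
                         drop = FALSE]

    ## --- SNVs ---
    grp <- sample(GROUP_GENOTYPES$group, cfg$n_variants, replace = TRUE,
                  prob = cfg$group_mixture)
    grp <- c(grp, rep("NotSpecific", n_extra))
    grp <- sample(grp)  # shuffle extras among positions
    case_gt <- ifelse(grp == "NotSpecific", "0/1",
                      GROUP_GENOTYPES$case[match(grp, GROUP_GENOTYPES$group)])
    ctrl_gt <- ifelse(grp == "NotSpecific", "0/1",
                      GROUP_GENOTYPES$control[match(grp, GROUP_GENOTYPES$group)])
    ref <- sample(BASES, n_snv, replace = TRUE)
    alt1 <- vapply(ref, draw_alt, character(1), titv = cfg$target_titv)
    need2 <- grp %in% c("Group4", "Group5")
    alt <- alt1
    if (any(need2)) {
      alt2 <- mapply(function(r, a1) draw_alt(r, cfg$target_titv, a1),
                     ref[need2], alt1[need2])
      alt[need2] <- paste(alt1[need2], alt2, sep = ",")
    }
    snvs <- data.frame(snv_sites, ref = ref, alt = alt, class = "SNV",
                       stringsAsFactors = FALSE)
    snvs <- add_qc_fields(snvs, cfg$qc_fail_fraction, min_depth = 10,
                          rules = names(qc_violations))
    snvs[[paste0("gt_", cfg$case_strain)]] <- case_gt
    snvs[[paste0("gt_", cfg$control_strain)]] <- ctrl_gt

    ## --- indels ---
    igrp <- sample(GROUP_GENOTYPES$group, cfg$n_indels, replace = TRUE,
                   prob = cfg$indel_group_mixture)
    is_del <- stats::runif(cfg$n_indels) < 0.5
    len <- sample(1:5, cfg$n_indels, replace = TRUE)
    anchor <- sample(BASES, cfg$n_indels, replace = TRUE)
    tail_seq <- vapply(len, function(l)
      paste(sample(BASES, l, replace = TRUE), collapse = ""), character(1))
    iref <- ifelse(is_del, paste0(anchor, tail_seq), anchor)
    ialt1 <- ifelse(is_del, anchor, paste0(anchor, tail_seq))
    ineed2 <- igrp %in% c("Group4", "Group5")
    ialt <- ialt1
    if (any(ineed2)) {
      t2 <- vapply(len[ineed2] + 1L, function(l)
        paste(sample(BASES, l, replace = TRUE), collapse = ""), character(1))
      ialt[ineed2] <- paste(ialt1[ineed2],
                            ifelse(is_del[ineed2], anchor[ineed2],
                                   paste0(anchor[ineed2], t2)), sep = ",")
      # ensure distinct second allele for deletions: shorten ref tail
      ialt[ineed2 & is_del] <- paste(ialt1[ineed2 & is_del],
                                     substr(iref[ineed2 & is_del], 1, 2),
                                     sep = ",")
    }
    indels <- data.frame(indel_sites, ref = iref, alt = ialt,
                         class = ifelse(is_del, "deletion", "insertion"),
                         stringsAsFactors = FALSE)
    indels <- add_qc_fields(indels, cfg$qc_fail_fraction, min_depth = 8,
                            rules = c("depth", "allele_number"))
    indels[[paste0("gt_", cfg$case_strain)]] <-
      GROUP_GENOTYPES$case[match(igrp, GROUP_GENOTYPES$group)]
    indels[[paste0("gt_", cfg$control_strain)]] <-
      GROUP_GENOTYPES$control[match(igrp, GROUP_GENOTYPES$group)]

    variants <- rbind(snvs, indels)
    ord <- order(match(variants$chrom, names(cfg$chromosome_lengths)),
                 variants$pos)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    truth <- data.frame(
      chrom = variants$chrom, pos = variants$pos, class = variants$class,
      true_group = c(grp, igrp)[ord],
      qc_clean = c(attr(snvs, "qc_clean_all"),
                   attr(indels, "qc_clean_all"))[ord],
      stringsAsFactors = FALSE
    )
    list(variants = variants, truth = truth)
  })
  if (!is.null(path)) write_vcf(res$variants, path)
  res$path <- path
  res
}

# populate QC fields; a qc_fail_fraction of rows violates each listed rule
add_qc_fields <- function(df, fail_frac, min_depth, rules) {
  n <- nrow(df)
  df$depth <- min_depth + stats::rpois(n, 15)
  df$allele_number <- rep(4L, n)
  df$base_quality <- stats::runif(n, 31, 40)
  df$quality_by_depth <- stats::runif(n, 5.5, 30)
  df$zero_mapq_count <- sample(0:4, n, replace = TRUE)
  if (n == 0) {
    attr(df, "qc_clean_all") <- logical(0)
    return(df)
  }
  clean <- rep(TRUE, n)
  for (rule in rules) {
    bad <- stats::runif(n) < fail_frac
    if (any(bad)) df[[rule]][bad] <- qc_violations[[rule]](sum(bad))
    clean <- clean & !bad
  }
  attr(df, "qc_clean_all") <- clean
  df
}

#' Generate a strain-panel genotype matrix along a known tree
#'
#' Two site classes make up the panel. Tree-evolved sites
#' (`cfg$n_panel_sites` of them) start homozygous-reference at the root and
#' flip between `0/0` and `1/1` along each branch with probability equal to
#' the branch length, giving phylogenetic signal for tree reconstruction.
#' Focal-variant sites (all sites of `focal$variants`) get
#' consistency-driven genotypes: at sites where the focal case strain is
#' homozygous-variant, case-consistent strains repeat that genotype with
#' probability `cfg$panel_case_consistency` and control-background strains
#' with probability `cfg$panel_background_leak`; a
#' `cfg$panel_missing_fraction` of panel genotypes is set missing.
#'
#' @param cfg a [sim_config()].
#' @param tree panel tree (`phylo`); defaults to [default_panel_tree()].
#' @param focal result of [generate_focal_vcf()], or `NULL` to generate
#'   only tree-evolved sites.
#' @return list with `panel` (a `panel_matrix`), `tree`, and `truth`
#'   (per-focal-site logical `survives_panel`).
#' @export
generate_panel <- function(cfg, tree = NULL, focal = NULL) {
  if (is.null(tree)) tree <- default_panel_tree(cfg)
  .assert(all(tree$edge.length >= 0), "branch lengths must be non-negative")
  strains <- tree$tip.label
  case_cons <- attr(tree, "case_consistent")
  backgrnd <- attr(tree, "control_background")
  groups <- data.frame(
    strain = strains,
    group = ifelse(strains %in% c(case_cons, cfg$case_strain),
                   "case_consistent",
                   ifelse(strains %in% backgrnd, "control_background",
                          "other")),
    stringsAsFactors = FALSE
  )
  # the focal case strain itself is genotyped in the VCF, not the panel rule
  groups$group[groups$strain == cfg$case_strain] <- "focal_case"
  groups$group[groups$strain == cfg$control_strain] <- "focal_control"

  with_component_seed(cfg$seed, "panel", {
    ## tree-evolved sites
    exclude <- if (!is.null(focal)) {
      paste(focal$variants$chrom, focal$variants$pos)
    } else character(0)
    ev_sites <- sample_positions(cfg$chromosome_lengths, cfg$n_panel_sites,
                                 exclude_key = exclude)
    states <- evolve_binary(tree, cfg$n_panel_sites)
    ev_geno <- matrix(ifelse(states == 1L, "1/1", "0/0"),
                      nrow = cfg$n_panel_sites,
                      dimnames = list(NULL, strains))

    if (!is.null(focal)) {
      fv <- focal$variants
      case_gt <- fv[[paste0("gt_", cfg$case_strain)]]
      ctrl_gt <- fv[[paste0("gt_", cfg$control_strain)]]
      nf <- nrow(fv)
      fgeno <- matrix("0/0", nrow = nf, ncol = length(strains),
                      dimnames = list(NULL, strains))
      fgeno[, cfg$case_strain] <- case_gt
      fgeno[, cfg$control_strain] <- ctrl_gt
      hom <- vapply(case_gt, gt_is_hom_var, logical(1))
      for (s in setdiff(case_cons, cfg$case_strain)) {
        share <- hom & stats::runif(nf) < cfg$panel_case_consistency
        fgeno[share, s] <- case_gt[share]
        fgeno[hom & !share, s] <- "0/1"
      }
      for (s in setdiff(backgrnd, cfg$control_strain)) {
        leak <- hom & stats::runif(nf) < cfg$panel_background_leak
        fgeno[leak, s] <- case_gt[leak]
      }
      free <- setdiff(strains, c(case_cons, backgrnd, cfg$case_strain,
                                 cfg$control_strain))
      for (s in free) {
        v <- stats::runif(nf) < 0.10
        fgeno[v, s] <- "1/1"
      }
      # missingness, never on the focal pair (their VCF is the call set)
      others <- setdiff(strains, c(cfg$case_strain, cfg$control_strain))
      miss <- matrix(stats::runif(nf * length(others)) <
                       cfg$panel_missing_fraction, nrow = nf)
      fgeno[, others][miss] <- "./."

      sites <- rbind(fv[, c("chrom", "pos")], ev_sites)
      geno <- rbind(fgeno, ev_geno)
      ord <- order(match(sites$chrom, names(cfg$chromosome_lengths)),
                   sites$pos)
      panel <- panel_matrix(sites[ord, , drop = FALSE],
                            geno[ord, , drop = FALSE], groups)
      truth <- data.frame(
        chrom = fv$chrom, pos = fv$pos,
        survives_panel = panel_truth(fgeno, case_gt, cfg, case_cons,
                                     backgrnd),
        stringsAsFactors = FALSE
      )
    } else {
      panel <- panel_matrix(ev_sites, ev_geno, groups)
      truth <- NULL
    }
    list(panel = panel, tree = tree, truth = truth)
  })
}

# per-site 0/1 states at the leaves after Bernoulli flips along each branch
evolve_binary <- function(tree, n_sites) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_nodes <- max(tree$edge)
  states <- matrix(0L, nrow = n_sites, ncol = n_nodes)
  # preorder: parents before children
  ord <- order(tree$edge[, 1])
  for (i in ord) {
    par <- tree$edge[i, 1]; chd <- tree$edge[i, 2]
    p <- min(1, tree$edge.length[i])
    flip <- stats::runif(n_sites) < p
    states[, chd] <- ifelse(flip, 1L - states[, par], states[, par])
  }
  states[, seq_len(n_tip), drop = FALSE] |>
    `colnames<-`(tree$tip.label)
}

# ground-truth survival of the panel-consistency rule, by construction
panel_truth <- function(fgeno, case_gt, cfg, case_cons, backgrnd) {
  nf <- nrow(fgeno)
  hom <- vapply(case_gt, gt_is_hom_var, logical(1))
  ok <- hom
  for (s in setdiff(case_cons, cfg$case_strain)) {
    ok <- ok & fgeno[, s] == case_gt
  }
  for (s in setdiff(backgrnd, cfg$control_strain)) {
    ok <- ok & !(fgeno[, s] == case_gt)
  }
  ok
}

#' Generate gene models with olfactory-receptor flags
#'
#' @param cfg a [sim_config()].
#' @return gene model data frame (0-based half-open intervals), with an
#'   `or_fraction` share flagged as olfactory-receptor genes.
#' @export
generate_gene_models <- function(cfg) {
  with_component_seed(cfg$seed, "genes", {
    chroms <- names(cfg$chromosome_lengths)
    ch <- sample(chroms, cfg$n_genes, replace = TRUE,
                 prob = cfg$chromosome_lengths / sum(cfg$chromosome_lengths))
    width <- sample(5000:50000, cfg$n_genes, replace = TRUE)
    start <- vapply(seq_len(cfg$n_genes), function(i)
      sample.int(cfg$chromosome_lengths[[ch[i]]] - width[i], 1L) - 1L,
      integer(1))
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
      chrom = ch, start = start, end = start + width,
      is_olfactory_receptor = stats::runif(cfg$n_genes) < cfg$or_fraction,
      stringsAsFactors = FALSE
    )
    genes[order(match(genes$chrom, chroms), genes$start), ] |>
      (\(g) {rownames(g) <- NULL; g})()
  })
}

#' Generate functional annotations for the focal variants
#'
#' Variants inside a gene model get gene-linked region classes with
#' realistic proportions (intronic-dominant, a small exonic fraction split
#' between nonsynonymous and synonymous effects); variants outside any gene
#' are intergenic.
#'
#' @param cfg a [sim_config()].
#' @param variants focal variant table.
#' @param genes gene model data frame.
#' @return annotation data frame (`chrom`, `pos`, `gene_id`,
#'   `region_class`, `exonic_effect`, `sift_call`).
#' @export
generate_annotations <- function(cfg, variants, genes) {
  with_component_seed(cfg$seed, "annotations", {
    vgr <- GenomicRanges::GRanges(variants$chrom,
                                  IRanges::IRanges(variants$pos,
                                                   variants$pos))
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1L,
                                                   genes$end))
    hit <- GenomicRanges::findOverlaps(vgr, ggr, select = "first")
    n <- nrow(variants)
    ann <- data.frame(
      chrom = variants$chrom, pos = variants$pos,
      gene_id = ifelse(is.na(hit), ".", genes$gene_id[hit]),
      region_class = "intergenic", exonic_effect = ".", sift_call = ".",
      stringsAsFactors = FALSE
    )
    ing <- !is.na(hit)
    ann$region_class[ing] <- sample(
      c("exonic", "splicing", "ncRNA_exonic", "UTR", "intronic",
        "upstream", "downstream"),
      sum(ing), replace = TRUE,
      prob = c(0.05, 0.002, 0.004, 0.03, 0.80, 0.057, 0.057))
    ex <- ann$region_class == "exonic"
    is_indel <- variants$class != "SNV"
    ann$exonic_effect[ex & !is_indel] <- sample(
      c("nonsynonymous", "synonymous", "stopgain", "stoploss"),
      sum(ex & !is_indel), replace = TRUE, prob = c(0.33, 0.66, 0.008, 0.002))
    ann$exonic_effect[ex & is_indel] <- sample(
      c("frameshift_insertion", "frameshift_deletion"),
      sum(ex & is_indel), replace = TRUE)
    fix_ins <- ann$exonic_effect == "frameshift_insertion" &
      variants$class == "deletion"
    ann$exonic_effect[fix_ins] <- "frameshift_deletion"
    fix_del <- ann$exonic_effect == "frameshift_deletion" &
      variants$class == "insertion"
    ann$exonic_effect[fix_del] <- "frameshift_insertion"
    ns <- ann$exonic_effect == "nonsynonymous"
    ann$sift_call[ns] <- sample(c("deleterious", "tolerated"), sum(ns),
                                replace = TRUE, prob = c(0.2, 0.8))
    ann
  })
}

#' Generate a PPI edge list and prior-gene list with planted enrichment
#'
#' Background edges connect uniformly random gene pairs; each planted gene
#' receives `cfg$planted_degree` partners drawn with prior genes upweighted
#' by `cfg$enrichment_odds_ratio`. Scores are uniform on \[0, 1\]
#' independent of prior status, so thresholding does not bias enrichment.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids universe of gene identifiers (defaults to the ids used
#'   by [generate_gene_models()]).
#' @return list with `edges`, `prior_genes`, and `truth` (the planted
#'   enriched gene ids).
#' @export
generate_ppi_prior <- function(cfg, gene_ids = NULL, planted = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  with_component_seed(cfg$seed, "ppi", {
    if (is.null(planted) && is.character(cfg$planted_enriched_genes)) {
      planted <- cfg$planted_enriched_genes
    }
    if (is.null(planted)) {
      prior <- sort(sample(gene_ids, cfg$prior_gene_count))
      planted <- sort(sample(setdiff(gene_ids, prior),
                             cfg$planted_enriched_genes))
    } else {
      # planted genes model novel candidates: keep them out of the priors
      prior <- sort(sample(setdiff(gene_ids, planted),
                           cfg$prior_gene_count))
    }
    .assert(all(planted %in% gene_ids),
            "planted enriched genes must be in the gene universe")
    a <- sample(gene_ids, cfg$ppi_n_edges, replace = TRUE)
    b <- sample(gene_ids, cfg$ppi_n_edges, replace = TRUE)
    keep <- a != b
    edges <- data.frame(gene_a = a[keep], gene_b = b[keep],
                        stringsAsFactors = FALSE)
    w <- ifelse(gene_ids %in% prior, cfg$enrichment_odds_ratio, 1)
    for (g in planted) {
      cand <- setdiff(gene_ids, g)
      partners <- sample(cand, min(cfg$planted_degree, length(cand)),
                         prob = w[match(cand, gene_ids)])
      edges <- rbind(edges, data.frame(gene_a = g, gene_b = partners,
                                       stringsAsFactors = FALSE))
    }
    key <- paste(pmin(edges$gene_a, edges$gene_b),
                 pmax(edges$gene_a, edges$gene_b))
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$score <- round(stats::runif(nrow(edges)), 4)
    rownames(edges) <- NULL
    list(edges = edges, prior_genes = prior, truth = planted)
  })
}

#' Generate an expression matrix with planted DE and DC genes
#'
#' Log-normal expression over a full strain x tissue x time design.
#' Planted differentially expressed genes get a `cfg$de_fold_change` shift
#' in case samples of one designated tissue at every time point; planted
#' differentially co-expressed genes are generated with correlation
#' `cfg$dc_rho_case` to a partner gene within case samples and
#' `cfg$dc_rho_control` within control samples, in one designated tissue.
#'
#' @param cfg a [sim_config()].
#' @param de_genes,dc_genes,dc_partners optional gene ids at which to plant
#'   the DE and DC signals (defaults: the first gene ids, disjoint sets).
#' @return list with `exprs` (genes x samples, linear intensities), `meta`
#'   (sample metadata), `log_scale = FALSE`, and `truth` (data frames of
#'   planted DE genes with tissue/fold-change and planted DC genes with
#'   tissue/partner).
#' @export
generate_expression <- function(cfg, de_genes = NULL, dc_genes = NULL,
                                dc_partners = NULL) {
  .assert(cfg$expr_samples_per_condition >= 2,
          "need >= 2 samples per condition")
  with_component_seed(cfg$seed, "expression", {
    genes <- sprintf("G%04d", seq_len(cfg$expr_n_genes))
    meta <- expand.grid(
      rep = seq_len(cfg$expr_samples_per_condition),
      time = cfg$time_points, tissue = cfg$tissues,
      strain = c(cfg$case_strain, cfg$control_strain),
      stringsAsFactors = FALSE
    )
    meta$sample_id <- sprintf("%s_%s_t%d_r%d", meta$strain, meta$tissue,
                              meta$time, meta$rep)
    meta <- meta[, c("sample_id", "strain", "tissue", "time")]
    mu <- stats::runif(cfg$expr_n_genes, 6, 12)
    logx <- matrix(stats::rnorm(cfg$expr_n_genes * nrow(meta), mean = mu,
                                sd = cfg$expr_sd),
                   nrow = cfg$expr_n_genes,
                   dimnames = list(genes, meta$sample_id))

    de_ids <- if (is.null(de_genes)) genes[seq_len(cfg$planted_de_genes)]
              else de_genes
    dc_ids <- if (is.null(dc_genes)) {
      genes[cfg$planted_de_genes + seq_len(cfg$planted_dc_genes)]
    } else dc_genes
    if (is.null(dc_partners)) {
      dc_partners <- setdiff(genes, c(de_ids, dc_ids))[seq_along(dc_ids)]
    }
    .assert(all(c(de_ids, dc_ids, dc_partners) %in% genes),
            "planted expression genes must be on the matrix")
    n_de <- length(de_ids)
    n_dc <- length(dc_ids)
    de_tissue <- rep(cfg$tissues, length.out = max(n_de, 1))[seq_len(n_de)]
    dc_tissue <- rep(cfg$tissues, length.out = max(n_dc, 1))[seq_len(n_dc)]

    if (n_de > 0) {
      for (i in seq_len(n_de)) {
        sel <- meta$strain == cfg$case_strain & meta$tissue == de_tissue[i]
        logx[de_ids[i], sel] <- logx[de_ids[i], sel] +
          log2(cfg$de_fold_change)
      }
    }
    if (n_dc > 0) {
      for (i in seq_len(n_dc)) {
        for (strain in c(cfg$case_strain, cfg$control_strain)) {
          rho <- if (strain == cfg$case_strain) cfg$dc_rho_case
                 else cfg$dc_rho_control
          for (tp in cfg$time_points) {
            sel <- meta$strain == strain & meta$tissue == dc_tissue[i] &
              meta$time == tp
            m <- sum(sel)
            ep <- stats::rnorm(m)
            eg <- rho * ep + sqrt(1 - rho^2) * stats::rnorm(m)
            logx[dc_partners[i], sel] <- mu[match(dc_partners[i], genes)] +
              cfg$expr_sd * ep
            logx[dc_ids[i], sel] <- mu[match(dc_ids[i], genes)] +
              cfg$expr_sd * eg
          }
        }
      }
    }
    truth <- list(
      de = data.frame(gene = de_ids, tissue = de_tissue,
                      fold_change = rep(cfg$de_fold_change, n_de),
                      stringsAsFactors = FALSE),
      dc = data.frame(gene = dc_ids, partner = dc_partners,
                      tissue = dc_tissue, stringsAsFactors = FALSE)
    )
    list(exprs = round(2^logx, 3), meta = meta, log_scale = FALSE,
         truth = truth)
  })
}

#' Generate a per-bin coverage track
#'
#' Per-bin counts of bases covered by at least three reads, emulating a
#' deeply sequenced genome where most of each bin is callable.
#'
#' @param cfg a [sim_config()].
#' @param bin_size bin width in bases.
#' @return coverage data frame (`chrom`, `start`, `end`, `covered_bases`).
#' @export
generate_coverage <- function(cfg, bin_size = 1e6) {
  with_component_seed(cfg$seed, "coverage", {
    bins <- tile_bins(cfg$chromosome_lengths, bin_size)
    frac <- stats::rbeta(nrow(bins), 93, 7)  # ~93% of bases callable
    bins$covered_bases <- round((bins$end - bins$start) * frac)
    bins
  })
}

#' Generate a truth panel of known polymorphic / non-polymorphic positions
#'
#' Emulates an external genotyping resource: `truth_n_variant` positions
#' known to be polymorphic in the case strain group, of which a
#' `truth_sensitivity` share coincides with the focal call set, and
#' `truth_n_invariant` known non-polymorphic positions, of which a
#' `truth_specificity` share is absent from the call set.
#'
#' @param cfg a [sim_config()].
#' @param variants focal variant table (the call set).
#' @param qc_clean optional logical vector along `variants`: planted hits
#'   are drawn from QC-clean calls only, so the planted sensitivity refers
#'   to the call set that survives hard filtering.
#' @return truth data frame (`chrom`, `pos`, `status`).
#' @export
generate_truth_panel <- function(cfg, variants, qc_clean = NULL) {
  with_component_seed(cfg$seed, "truth", {
    if (is.null(qc_clean)) qc_clean <- rep(TRUE, nrow(variants))
    case_var <- variants[qc_clean &
                           vapply(variants[[paste0("gt_", cfg$case_strain)]],
                                  gt_is_variant, logical(1)), ]
    called_key <- paste(variants$chrom, variants$pos)
    n_hit <- round(cfg$truth_n_variant * cfg$truth_sensitivity)
    n_hit <- min(n_hit, nrow(case_var))
    hit_idx <- sample.int(nrow(case_var), n_hit)
    miss <- sample_positions(cfg$chromosome_lengths,
                             cfg$truth_n_variant - n_hit,
                             exclude_key = called_key)
    tv <- rbind(case_var[hit_idx, c("chrom", "pos")], miss)
    n_clean <- round(cfg$truth_n_invariant * cfg$truth_specificity)
    clean <- sample_positions(cfg$chromosome_lengths, n_clean,
                              exclude_key = c(called_key,
                                              paste(tv$chrom, tv$pos)))
    n_dirty <- cfg$truth_n_invariant - n_clean
    pool <- setdiff(seq_len(nrow(variants)),
                    match(paste(case_var$chrom[hit_idx],
                                case_var$pos[hit_idx]), called_key))
    dirty_idx <- sample(pool, min(n_dirty, length(pool)))
    ti <- rbind(clean, variants[dirty_idx, c("chrom", "pos")])
    truth <- rbind(
      data.frame(tv, status = "variant", stringsAsFactors = FALSE),
      data.frame(ti, status = "invariant", stringsAsFactors = FALSE)
    )
    rownames(truth) <- NULL
    truth
  })
}

#' Generate SV and differential-CNV interval features
#'
#' Structural variants get kinds among deletion / inversion / tandem
#' duplication / translocation breakpoint. CNVs carry a case/control
#' mapped-read ratio and a raw p-value; about half are planted as
#' differential (ratio beyond 2-fold with a tiny p-value), the rest as
#' non-differential background.
#'
#' @param cfg a [sim_config()].
#' @return list with `features` (data frame) and `truth` (logical
#'   `differential` flag per CNV row).
#' @export
generate_features <- function(cfg) {
  with_component_seed(cfg$seed, "features", {
    mk_intervals <- function(n, min_w, max_w) {
      ch <- sample(names(cfg$chromosome_lengths), n, replace = TRUE)
      w <- sample(min_w:max_w, n, replace = TRUE)
      st <- vapply(seq_len(n), function(i)
        sample.int(cfg$chromosome_lengths[[ch[i]]] - w[i], 1L) - 1L,
        integer(1))
      data.frame(chrom = ch, start = st, end = st + w,
                 stringsAsFactors = FALSE)
    }
    sv <- mk_intervals(cfg$n_sv, 1000, 100000)
    sv$feature_kind <- sample(c("SV-deletion", "SV-inversion",
                                "SV-tandem-duplication",
                                "SV-translocation-breakpoint"),
                              cfg$n_sv, replace = TRUE,
                              prob = c(0.76, 0.05, 0.16, 0.03))
    sv$ratio <- NA_real_; sv$p_value <- NA_real_
    cnv <- mk_intervals(cfg$n_cnv, 5000, 200000)
    cnv$feature_kind <- sample(c("CNV-gain", "CNV-loss"), cfg$n_cnv,
                               replace = TRUE)
    diffl <- stats::runif(cfg$n_cnv) < 0.5
    hi <- stats::runif(cfg$n_cnv, 2.2, 6)
    cnv$ratio <- ifelse(diffl,
                        ifelse(cnv$feature_kind == "CNV-gain", hi, 1 / hi),
                        stats::runif(cfg$n_cnv, 0.8, 1.25))
    cnv$p_value <- ifelse(diffl, stats::runif(cfg$n_cnv, 0, 1e-6),
                          stats::runif(cfg$n_cnv, 0.05, 1))
    feat <- rbind(sv, cnv)
    rownames(feat) <- NULL
    list(features = feat, truth = diffl)
  })
}

#' Generate every pipeline input into one directory
#'
#' Runs all component generators under independent substreams of
#' `cfg$seed`, writes every file the pipeline consumes, and a
#' `ground_truth.json` with the planted truth. Identical configurations
#' yield byte-identical outputs.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return named list of file paths plus `truth` (the ground-truth list)
#'   and `cfg`.
#' @export
generate_all <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  focal <- generate_focal_vcf(cfg, p("focal.vcf"))
  panel <- generate_panel(cfg, focal = focal)
  write_panel(panel$panel, p("panel.tsv"), p("strain_groups.tsv"))
  write_newick(panel$tree, p("panel_truth_tree.nwk"))
  genes <- generate_gene_models(cfg)
  write_gene_bed(genes, p("genes.bed"))
  ann <- generate_annotations(cfg, focal$variants, genes)
  write_annotations(ann, p("annotations.tsv"))

  # ground-truth candidate genes: QC-clean, protein-affecting,
  # panel-surviving variants in non-OR genes — the genes a perfect run of
  # the pipeline should nominate; enrichment and expression signals are
  # planted at these so end-to-end recovery is measurable
  pav <- flag_pav(ann)
  or_ids <- genes$gene_id[genes$is_olfactory_receptor]
  cand_truth <- sort(unique(pav$gene_id[
    pav$is_pav & pav$gene_id != "." & focal$truth$qc_clean &
      panel$truth$survives_panel & !(pav$gene_id %in% or_ids)]))
  n_enr <- if (is.character(cfg$planted_enriched_genes))
    length(cfg$planted_enriched_genes) else cfg$planted_enriched_genes
  planted_enr <- utils::head(cand_truth, n_enr)
  expr_ids <- sprintf("G%04d", seq_len(cfg$expr_n_genes))
  rest <- intersect(setdiff(cand_truth, planted_enr), expr_ids)
  planted_de <- utils::head(rest, cfg$planted_de_genes)
  planted_dc <- utils::head(setdiff(rest, planted_de),
                            cfg$planted_dc_genes)
  # DC partners drawn from the candidate set too, so the correlation flip
  # is visible to a co-expression test over the candidate genes
  planted_dc_partners <- utils::head(
    setdiff(rest, c(planted_de, planted_dc)), length(planted_dc))
  if (length(planted_dc_partners) < length(planted_dc)) {
    planted_dc <- planted_dc[seq_along(planted_dc_partners)]
  }

  ppi <- generate_ppi_prior(cfg, genes$gene_id,
                            planted = if (length(planted_enr))
                              planted_enr else NULL)
  write_edges(ppi$edges, p("ppi_edges.tsv"))
  write_prior_genes(ppi$prior_genes, p("prior_genes.txt"))
  expr <- generate_expression(
    cfg,
    de_genes = if (length(planted_de)) planted_de else NULL,
    dc_genes = if (length(planted_dc)) planted_dc else NULL,
    dc_partners = if (length(planted_dc)) planted_dc_partners else NULL)
  write_expression(expr$exprs, expr$meta, p("expression.tsv"),
                   p("expression_meta.tsv"))
  cov <- generate_coverage(cfg)
  write_coverage_bins(cov, p("coverage_bins.tsv"))
  truth_panel <- generate_truth_panel(cfg, focal$variants,
                                      qc_clean = focal$truth$qc_clean)
  write_truth_panel(truth_panel, p("truth_panel.tsv"))
  feats <- generate_features(cfg)
  write_features(feats$features, p("features.tsv"))

  truth <- list(
    true_group_per_variant = focal$truth,
    survives_panel = panel$truth,
    true_candidate_genes = cand_truth,
    true_tree = ape::write.tree(panel$tree),
    true_enriched_genes = ppi$truth,
    true_de_genes = expr$truth$de,
    true_dc_genes = expr$truth$dc,
    differential_cnv = feats$truth
  )
  write_json_report(truth, p("ground_truth.json"))

  list(
    vcf = p("focal.vcf"), panel = p("panel.tsv"),
    strain_groups = p("strain_groups.tsv"),
    truth_tree = p("panel_truth_tree.nwk"), genes = p("genes.bed"),
    annotations = p("annotations.tsv"), ppi = p("ppi_edges.tsv"),
    prior = p("prior_genes.txt"), expression = p("expression.tsv"),
    expression_meta = p("expression_meta.tsv"),
    coverage = p("coverage_bins.tsv"), truth_panel = p("truth_panel.tsv"),
    features = p("features.tsv"), ground_truth = p("ground_truth.json"),
    truth = truth, cfg = cfg
  )
}
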