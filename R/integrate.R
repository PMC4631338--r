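# Evidence integration into tiered candidate genes, and the end-to-end
# pipeline driver.

#' Merge evidence streams into a tiered candidate-gene table
#'
#' Three evidence flags per candidate gene: (1) membership in the prior
#' gene list, (2) PPI-partner enrichment with prior genes (adjusted
#' p <= 0.05), (3) differential expression or co-expression (annotation
#' only). A gene is `high-confidence` when flag (1) or flag (2) holds;
#' expression support alone never promotes a gene.
#'
#' @param candidates candidate gene ids (post panel filter and OR
#'   exclusion).
#' @param prior_set prior gene ids.
#' @param enrichment enrichment data frame from [enrich_gene_set()].
#' @param expression_flags combined flags from [combine_timepoints()]
#'   (or `NULL`).
#' @param variants optional data frame of each gene's surviving variants
#'   (`gene_id`, `chrom`, `pos`, `ref`, `alt`, `sift_call`).
#' @param alpha enrichment significance threshold on the adjusted p.
#' @return data frame, one row per candidate, sorted by (tier, adjusted
#'   enrichment p, gene): `gene`, `is_prior_gene`, `ppi_enriched`,
#'   `enrichment_adjusted_p`, `expression_support`, `de_tissues`,
#'   `dc_tissues`, `n_variants`, `tier`.
#' @export
integrate_evidence <- function(candidates, prior_set, enrichment,
                               expression_flags = NULL, variants = NULL,
                               alpha = 0.05) {
  extra <- setdiff(enrichment$gene, candidates)
  if (length(extra)) {
    warning("evidence for genes absent from candidates ignored: ",
            paste(utils::head(extra, 3), collapse = ", "))
  }
  em <- match(candidates, enrichment$gene)
  xm <- if (!is.null(expression_flags)) {
    match(candidates, expression_flags$gene)
  } else {
    rep(NA_integer_, length(candidates))
  }
  adj <- enrichment$adjusted_p[em]
  out <- data.frame(
    gene = candidates,
    is_prior_gene = candidates %in% prior_set,
    ppi_enriched = !is.na(adj) & adj <= alpha,
    enrichment_adjusted_p = adj,
    expression_support = if (!is.null(expression_flags)) {
      !is.na(xm) & expression_flags$is_differential[xm]
    } else rep(FALSE, length(candidates)),
    de_tissues = if (!is.null(expression_flags))
      ifelse(is.na(xm), "", expression_flags$de_tissues[xm]) else "",
    dc_tissues = if (!is.null(expression_flags))
      ifelse(is.na(xm), "", expression_flags$dc_tissues[xm]) else "",
    stringsAsFactors = FALSE
  )
  if (!is.null(variants)) {
    out$n_variants <- vapply(out$gene, function(g)
      sum(variants$gene_id == g), integer(1))
  }
  out$tier <- ifelse(out$is_prior_gene | out$ppi_enriched,
                     "high-confidence", "candidate")
  key_adj <- ifelse(is.na(out$enrichment_adjusted_p), 1,
                    out$enrichment_adjusted_p)
  out <- out[order(out$tier != "high-confidence", key_adj, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default pipeline parameters
#' @return named list of stage parameters.
#' @export
default_pipeline_params <- function() {
  list(bin_size = 1e6, extreme_fraction = 0.05, ppi_score_threshold = 0.4,
       adjust_method = "BH", enrichment_alpha = 0.05, de_p = 0.01,
       de_fc = 2, dc_n_perm = 200, dc_alpha = 0.05, expr_log_scale = FALSE,
       seed = 1)
}

#' Run the full prioritization pipeline
#'
#' Executes filter -> compare -> density -> validation -> PAV selection ->
#' panel filter -> OR exclusion -> phylogeny -> enrichment -> expression ->
#' integration over one input directory, and returns (optionally writes)
#' a single run report with every summary statistic and full parameter
#' provenance. The report is deterministic: identical inputs, parameters
#' and seed give byte-identical JSON.
#'
#' @param inputs named list of input paths as produced by
#'   [generate_all()] (fields `vcf`, `panel`, `strain_groups`, `genes`,
#'   `annotations`, `ppi`, `prior`, `expression`, `expression_meta`,
#'   `coverage`, `truth_panel`, `features`).
#' @param case,control focal sample names.
#' @param params stage parameters, see [default_pipeline_params()].
#' @param report_path optional path for the JSON run report.
#' @return the report as a nested list (invisibly also written when
#'   `report_path` is given), with a `tables` attribute carrying the full
#'   candidate table and enrichment results.
#' @export
run_pipeline <- function(inputs, case, control,
                         params = default_pipeline_params(),
                         report_path = NULL) {
  p <- utils::modifyList(default_pipeline_params(), params)

  ## 1. read + hard filters
  variants <- read_vcf(inputs$vcf)
  snvs <- variants[variants$class == "SNV", , drop = FALSE]
  indels <- variants[variants$class != "SNV", , drop = FALSE]
  fs <- filter_snvs(snvs, indels = indels)
  fi <- filter_indels(indels)
  passed <- rbind(fs$passed, fi$passed)

  ## 2. strain comparison
  cmp <- derive_specific(passed, case, control)
  specific <- cmp$specific

  ## 3. density profiling
  coverage <- read_coverage_bins(inputs$coverage)
  chrom_lengths <- tapply(coverage$end, coverage$chrom, max)
  chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                   names(chrom_lengths))
  snv_bins <- profile_density(specific[specific$class == "SNV", ],
                              coverage, chrom_lengths, p$bin_size)
  indel_bins <- profile_density(specific[specific$class != "SNV", ],
                                coverage, chrom_lengths, p$bin_size)
  dens_cor <- correlate_densities(snv_bins, indel_bins)
  extremes <- extreme_bins(snv_bins, p$extreme_fraction)

  ## 4. truth-panel validation
  truth <- read_truth_panel(inputs$truth_panel)
  case_called <- passed[vapply(passed[[paste0("gt_", case)]],
                               gt_is_variant, logical(1)),
                        c("chrom", "pos")]
  validation <- validate_against_truth(case_called, truth)

  ## 5. PAV selection
  ann <- read_annotations(inputs$annotations)
  ann <- flag_pav(ann)
  akey <- paste(ann$chrom, ann$pos)
  skey <- paste(specific$chrom, specific$pos)
  m <- match(skey, akey)
  specific$gene_id <- ann$gene_id[m]
  specific$is_pav <- !is.na(m) & ann$is_pav[m]
  specific$sift_call <- ann$sift_call[m]
  pavs <- specific[specific$is_pav, , drop = FALSE]

  ## 6. strain-panel consistency filter
  panel <- read_panel(inputs$panel, inputs$strain_groups)
  pf <- panel_filter(pavs, panel, case)
  surviving <- pf$surviving

  ## 7. OR-gene exclusion
  genes <- read_gene_bed(inputs$genes)
  cand_genes <- sort(unique(surviving$gene_id[surviving$gene_id != "."]))
  orx <- exclude_or_genes(cand_genes, genes)
  candidates <- orx$kept

  ## 8. SV / CNV overlap
  features <- read_features(inputs$features)
  cnv <- features[grepl("^CNV", features$feature_kind), , drop = FALSE]
  sv <- features[grepl("^SV", features$feature_kind), , drop = FALSE]
  fc <- filter_differential_cnv(cnv)
  feature_hits <- overlap_features_with_genes(rbind(sv, fc$passed), genes)

  ## 9. strain phylogeny (skipped when the panel holds no sites)
  tree <- NULL
  if (nrow(panel$genotypes) > 0) {
    dmat <- distance_matrix(panel)
    tree <- upgma(dmat)
  }

  ## 10. PPI enrichment
  edges <- read_edges(inputs$ppi)
  prior <- read_prior_genes(inputs$prior)
  graph <- build_ppi_graph(edges, p$ppi_score_threshold)
  enr <- if (length(candidates)) {
    enrich_gene_set(graph, candidates, prior, method = p$adjust_method)
  } else {
    data.frame(gene = character(0), p_value = numeric(0),
               adjusted_p = numeric(0))
  }

  ## 11. expression evidence
  ex <- read_expression(inputs$expression, inputs$expression_meta)
  tissues <- sort(unique(ex$meta$tissue))
  times <- sort(unique(ex$meta$time))
  test_genes <- intersect(rownames(ex$exprs), candidates)
  de_all <- list(); dc_all <- list()
  for (ti in tissues) {
    for (tp in times) {
      if (length(test_genes)) {
        de_all[[paste(ti, tp)]] <- differential_expression(
          ex$exprs, ex$meta, ti, tp, case, control, genes = test_genes,
          log_scale = p$expr_log_scale, p_threshold = p$de_p,
          fc_threshold = p$de_fc)
      }
      if (length(test_genes) >= 2) {
        dc_all[[paste(ti, tp)]] <- differential_coexpression(
          ex$exprs, ex$meta, ti, tp, case, control, test_genes,
          n_perm = p$dc_n_perm,
          seed = component_seed(p$seed, "pipeline") + match(ti, tissues) *
            100L + tp,
          alpha = p$dc_alpha)
      }
    }
  }
  de_res <- if (length(de_all)) do.call(rbind, de_all) else NULL
  dc_res <- if (length(dc_all)) do.call(rbind, dc_all) else NULL
  expr_flags <- combine_timepoints(de_res, dc_res)

  ## 12. integrate
  evidence <- integrate_evidence(candidates, prior, enr, expr_flags,
                                 variants = surviving, alpha =
                                   p$enrichment_alpha)

  report <- list(
    parameters = c(p, list(case = case, control = control)),
    filters = list(snv = fs$report, indel = fi$report,
                   differential_cnv = fc$report),
    comparison = cmp$stats,
    density = list(pearson_r = dens_cor$pearson_r,
                   r_squared = dens_cor$r_squared,
                   n_pairs = dens_cor$n_pairs,
                   n_top_bins = nrow(extremes$top),
                   n_bottom_bins = nrow(extremes$bottom)),
    validation = validation,
    prioritization = list(
      n_pavs = nrow(pavs),
      n_pavs_surviving_panel = nrow(surviving),
      n_heterozygous_pavs = nrow(pf$heterozygous),
      n_candidate_genes_pre_or = length(cand_genes),
      n_or_genes_removed = orx$n_removed,
      n_candidate_genes = length(candidates),
      n_feature_affected_genes = length(unique(feature_hits$gene_id))
    ),
    phylogeny = list(newick = if (is.null(tree)) ""
                     else ape::write.tree(tree)),
    enrichment = list(
      n_significant = sum(enr$adjusted_p <= p$enrichment_alpha,
                          na.rm = TRUE),
      adjust_method = p$adjust_method
    ),
    expression = list(
      n_de_genes = sum(expr_flags$is_de),
      n_dc_genes = sum(expr_flags$is_dc),
      n_differential = sum(expr_flags$is_differential)
    ),
    candidates = list(
      n_high_confidence = sum(evidence$tier == "high-confidence"),
      n_candidate_tier = sum(evidence$tier == "candidate"),
      high_confidence_genes = evidence$gene[evidence$tier ==
                                              "high-confidence"]
    )
  )
  if (!is.null(report_path)) write_json_report(report, report_path)
  attr(report, "tables") <- list(evidence = evidence, enrichment = enr,
                                 expression_flags = expr_flags,
                                 tree = tree, snv_bins = snv_bins,
                                 feature_hits = feature_hits,
                                 surviving_pavs = surviving)
  invisible(report)
}
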