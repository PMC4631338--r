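# The synthetic-data generator: planted conditions and determinism.

test_that("a degenerate group mixture forces every genotype pair", {
  cfg <- small_cfg(group_mixture = c(0, 1, 0, 0, 0),
                   indel_group_mixture = c(0, 1, 0, 0, 0))
  res <- generate_focal_vcf(cfg)
  expect_true(all(res$variants$gt_GK %in% "1/1"))
  expect_true(all(res$variants$gt_WISTAR == "0/0"))
})

test_that("het_fraction = 0 yields 100% case homozygosity", {
  cfg <- small_cfg(group_mixture = c(0, 0.96, 0.04, 0, 0),
                   indel_group_mixture = c(0, 1, 0, 0, 0),
                   het_fraction = 0)
  res <- generate_focal_vcf(cfg)
  expect_equal(homozygosity(res$variants, "GK")$pct, 100)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(group_mixture = c(0.5, 0.4, 0, 0, 0)),
               "sum to 1")
  expect_error(sim_config(target_titv = 0), "positive")
  expect_error(sim_config(het_fraction = 0), "het_fraction = 0 requires")
  expect_error(sim_config(het_fraction = 0.01), "below the value implied")
})

test_that("realized Ti/Tv tracks the configured target", {
  cfg <- sim_config(n_variants = 100000, n_indels = 0, target_titv = 2.10,
                    seed = 1)
  res <- generate_focal_vcf(cfg)
  cmp <- derive_specific(res$variants, "GK", "WISTAR")
  expect_lt(abs(cmp$stats$titv - 2.10), 0.05)
})

test_that("realized group proportions follow the mixture (chi-square GOF)", {
  cfg <- sim_config(n_variants = 100000, n_indels = 0,
                    group_mixture = c(0.036, 0.929, 0.035, 0, 0), seed = 1)
  res <- generate_focal_vcf(cfg)
  counts <- table(factor(res$truth$true_group,
                         levels = c("Group1", "Group2", "Group3")))
  gof <- suppressWarnings(
    chisq.test(as.integer(counts), p = c(0.036, 0.929, 0.035)))
  expect_gt(gof$p.value, 0.01)
})

test_that("positions are unique within a chromosome", {
  cfg <- small_cfg()
  res <- generate_focal_vcf(cfg)
  expect_false(anyDuplicated(paste(res$variants$chrom,
                                   res$variants$pos)) > 0)
})

test_that("same seed gives byte-identical outputs; components are independent", {
  cfg <- small_cfg(n_variants = 500, n_indels = 50, n_panel_sites = 100,
                   expr_samples_per_condition = 2)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  generate_all(cfg, d1)
  generate_all(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
  # regenerating the panel does not perturb the VCF substream
  v1 <- generate_focal_vcf(cfg)
  invisible(generate_panel(cfg))
  v2 <- generate_focal_vcf(cfg)
  expect_identical(v1$variants, v2$variants)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ground-truth identifiers exist in the generated files", {
  cfg <- small_cfg()
  dir <- file.path(tempdir(), "simC")
  out <- generate_all(cfg, dir)
  genes <- read_gene_bed(out$genes)
  expect_true(all(out$truth$true_enriched_genes %in% genes$gene_id))
  ex <- read_expression(out$expression, out$expression_meta)
  expect_true(all(out$truth$true_de_genes$gene %in% rownames(ex$exprs)))
  expect_true(all(out$truth$true_dc_genes$partner %in% rownames(ex$exprs)))
  panel <- read_panel(out$panel, out$strain_groups)
  expect_true(all(paste(out$truth$survives_panel$chrom,
                        out$truth$survives_panel$pos) %in%
                    rownames(panel$genotypes)))
  unlink(dir, recursive = TRUE)
})

test_that("a star tree with equal branches gives exchangeable distances", {
  star <- ape::read.tree(text = "(A:0.05,B:0.05,C:0.05,D:0.05);")
  cfg <- sim_config(n_panel_sites = 4000, seed = 3)
  pan <- generate_panel(cfg, tree = star)
  d <- distance_matrix(pan$panel)
  off <- d[upper.tri(d)]
  # all pairwise distances estimate the same quantity; binomial sampling
  # error at 4000 sites keeps them within a few percent of their mean
  expect_lt((max(off) - min(off)) / mean(off), 0.2)
})

test_that("a long internal branch makes UPGMA recover the planted split", {
  tr <- ape::read.tree(text = "((A:0.01,B:0.01):0.2,(C:0.01,D:0.01):0.2);")
  cfg <- sim_config(n_panel_sites = 1500, seed = 9)
  pan <- generate_panel(cfg, tree = tr)
  est <- upgma(distance_matrix(pan$panel))
  # A,B and C,D must be sisters
  co <- ape::cophenetic.phylo(est)
  expect_lt(co["A", "B"], co["A", "C"])
  expect_lt(co["C", "D"], co["A", "C"])
})

test_that("planted QC violations appear at the configured rate", {
  cfg <- sim_config(n_variants = 20000, n_indels = 0,
                    qc_fail_fraction = 0.05, seed = 4)
  res <- generate_focal_vcf(cfg)
  frac_clean <- mean(res$truth$qc_clean)
  # five independent rules at 5% each: clean fraction ~ 0.95^5
  expect_lt(abs(frac_clean - 0.95^5), 0.02)
  expect_gt(sum(res$variants$depth < 10), 0)
})
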