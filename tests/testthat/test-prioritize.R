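# PAV flagging, panel-consistency filtering, OR exclusion, interval overlap.

test_that("PAV flagging partitions the annotation vocabulary exactly", {
  ann <- data.frame(
    chrom = "chr1", pos = 1:10, gene_id = "G1",
    region_class = c("exonic", "exonic", "exonic", "exonic", "splicing",
                     "ncRNA_exonic", "UTR", "intronic", "upstream",
                     "intergenic"),
    exonic_effect = c("nonsynonymous", "synonymous", "stopgain",
                      "frameshift_deletion", ".", ".", ".", ".", ".", "."),
    sift_call = ".",
    stringsAsFactors = FALSE
  )
  out <- flag_pav(ann)
  expect_equal(out$is_pav,
               c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$pav_reason[5], "splicing")
  expect_equal(out$pav_reason[6], "ncRNA_exonic")
  # every vocabulary class is decided: none left NA on is_pav
  expect_false(anyNA(out$is_pav))
})

test_that("unknown annotation classes are an error, not silent non-PAV", {
  bad <- data.frame(region_class = "exotic", exonic_effect = ".",
                    stringsAsFactors = FALSE)
  expect_error(flag_pav(bad), "unknown region_class")
})

.pf_groups <- data.frame(
  strain = c("GK", "WISTAR", "GK_Ox", "BG1", "BG2"),
  group = c("focal_case", "focal_control", "case_consistent",
            "control_background", "control_background"),
  stringsAsFactors = FALSE
)

.pf_panel <- function(gts) {
  geno <- matrix(gts, nrow = 1,
                 dimnames = list(NULL, c("GK", "WISTAR", "GK_Ox",
                                         "BG1", "BG2")))
  make_panel("chr1", 100, geno, .pf_groups)
}

test_that("panel filter demands case-clade homozygosity and background absence", {
  pav <- make_variants("chr1", 100)

  keep <- panel_filter(pav, .pf_panel(c("1/1", "0/0", "1/1", "0/0", "0/0")),
                       "GK")
  expect_equal(nrow(keep$surviving), 1)

  het_ox <- panel_filter(pav, .pf_panel(c("1/1", "0/0", "0/1", "0/0", "0/0")),
                         "GK")
  expect_equal(nrow(het_ox$surviving), 0)

  bg_hom <- panel_filter(pav, .pf_panel(c("1/1", "0/0", "1/1", "1/1", "0/0")),
                         "GK")
  expect_equal(nrow(bg_hom$surviving), 0)

  # missing in background does not exclude; missing in case clade does
  bg_miss <- panel_filter(pav, .pf_panel(c("1/1", "0/0", "1/1", "./.", "0/0")),
                          "GK")
  expect_equal(nrow(bg_miss$surviving), 1)
  ox_miss <- panel_filter(pav, .pf_panel(c("1/1", "0/0", "./.", "0/0", "0/0")),
                          "GK")
  expect_equal(nrow(ox_miss$surviving), 0)
})

test_that("heterozygous focal PAVs are reported but never candidates", {
  pav <- make_variants("chr1", 100, gt_case = "0/1")
  res <- panel_filter(pav, .pf_panel(c("0/1", "0/0", "1/1", "0/0", "0/0")),
                      "GK")
  expect_equal(nrow(res$surviving), 0)
  expect_equal(nrow(res$heterozygous), 1)
})

test_that("panel filter is monotone in the strain groups", {
  set.seed(21)
  n <- 200
  strains <- c("GK", "WISTAR", "GK_Ox", "GK_2", "BG1", "BG2")
  geno <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n * 6,
                        replace = TRUE, prob = c(0.4, 0.1, 0.4, 0.1)),
                 ncol = 6, dimnames = list(NULL, strains))
  geno[, "GK"] <- sample(c("1/1", "0/1"), n, replace = TRUE,
                         prob = c(0.8, 0.2))
  groups <- data.frame(strain = strains,
                       group = c("focal_case", "focal_control",
                                 "case_consistent", "other",
                                 "control_background", "other"),
                       stringsAsFactors = FALSE)
  panel <- make_panel("chr1", seq_len(n) * 10, geno, groups)
  pav <- make_variants("chr1", seq_len(n) * 10,
                       gt_case = geno[, "GK"], gt_control = "0/0")

  base <- panel_filter(pav, panel, "GK",
                       case_consistent_strains = "GK_Ox",
                       background_strains = "BG1")
  more_cc <- panel_filter(pav, panel, "GK",
                          case_consistent_strains = c("GK_Ox", "GK_2"),
                          background_strains = "BG1")
  more_bg <- panel_filter(pav, panel, "GK",
                          case_consistent_strains = "GK_Ox",
                          background_strains = c("BG1", "BG2"))
  base_key <- paste(base$surviving$chrom, base$surviving$pos)
  expect_true(all(paste(more_cc$surviving$chrom, more_cc$surviving$pos)
                  %in% base_key))
  expect_true(all(paste(more_bg$surviving$chrom, more_bg$surviving$pos)
                  %in% base_key))
})

test_that("an empty panel passes PAVs through with a warning", {
  pav <- make_variants("chr1", c(100, 200))
  empty <- make_panel(character(0), integer(0),
                      matrix(character(0), nrow = 0, ncol = 5,
                             dimnames = list(NULL, .pf_groups$strain)),
                      .pf_groups)
  expect_warning(res <- panel_filter(pav, empty, "GK"), "empty")
  expect_equal(nrow(res$surviving), 2)
})

test_that("strains named in groups but missing from the panel are fatal", {
  pav <- make_variants("chr1", 100)
  p <- .pf_panel(c("1/1", "0/0", "1/1", "0/0", "0/0"))
  expect_error(panel_filter(pav, p, "GK",
                            case_consistent_strains = "GK_Missing"),
               "absent from panel")
})

test_that("OR-gene exclusion keeps non-OR genes and warns on unmodelled", {
  genes <- data.frame(gene_id = c("A", "B", "C"), chrom = "chr1",
                      start = c(0, 100, 200), end = c(50, 150, 250),
                      is_olfactory_receptor = c(FALSE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  res <- exclude_or_genes(c("A", "B", "C"), genes)
  expect_equal(res$kept, c("A", "C"))
  expect_equal(res$n_removed, 1)

  none <- exclude_or_genes(c("A", "C"), genes)
  expect_equal(none$kept, c("A", "C"))

  all_or <- exclude_or_genes("B", genes)
  expect_equal(all_or$kept, character(0))

  expect_warning(unk <- exclude_or_genes(c("A", "Z"), genes), "unconfirmed")
  expect_true("Z" %in% unk$kept)
})

test_that("interval overlap is half-open and matches the all-pairs oracle", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(150, 200), end = c(400, 400),
                      is_olfactory_receptor = FALSE,
                      stringsAsFactors = FALSE)
  feat <- data.frame(chrom = "chr1", start = 100, end = 200,
                     feature_kind = "SV-deletion", stringsAsFactors = FALSE)
  hits <- overlap_features_with_genes(feat, genes)
  expect_equal(hits$gene_id, "g1")  # [100,200) touches [150,400) only

  set.seed(33)
  n <- 400
  feats <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(1e6, n), stringsAsFactors = FALSE)
  feats$end <- feats$start + sample.int(5000, n)
  feats$feature_kind <- "CNV-gain"
  gs <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(1e6, n), stringsAsFactors = FALSE)
  gs$end <- gs$start + sample.int(20000, n)
  gs$is_olfactory_receptor <- FALSE
  hits <- overlap_features_with_genes(feats, gs)
  # vectorized all-pairs oracle
  om <- outer(seq_len(n), seq_len(n), function(gi, fi)
    gs$chrom[gi] == feats$chrom[fi] &
      gs$start[gi] < feats$end[fi] & feats$start[fi] < gs$end[gi])
  expect_equal(nrow(hits), sum(om))
  got <- sort(paste(hits$gene_id, hits$feature_row))
  want <- sort(paste(gs$gene_id[row(om)[om]], col(om)[om]))
  expect_equal(got, want)
})
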