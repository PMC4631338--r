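# Format round trips and coordinate conventions.

test_that("VCF genotypes surface verbatim, phased codes normalized", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tGK\tWISTAR",
    "chr1\t100\t.\tA\tG\t.\tPASS\tDP=20\tGT\t0/1\t0/0",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\tDP=15\tGT\t0|1\t./.",
    "chr1\t300\t.\tAT\tA\t.\tPASS\tDP=12\tGT\t1/1\t0/0"
  ), path)
  v <- read_vcf(path)
  expect_equal(v$gt_GK, c("0/1", "0/1", "1/1"))
  expect_equal(v$gt_WISTAR, c("0/0", "./.", "0/0"))
  expect_equal(v$class, c("SNV", "SNV", "deletion"))
  expect_equal(v$alt[2], "T,G")  # multi-allelic record kept whole
  expect_equal(v$depth, c(20, 15, 12))
  expect_true(all(is.na(v$quality_by_depth)))  # absent INFO key -> NA
})

test_that("malformed VCF input is a named fatal error", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "at all"), path)
  expect_error(read_vcf(path), "failed to parse VCF")
})

test_that("VCF write -> read is idempotent on the preserved fields", {
  cfg <- small_cfg(n_variants = 300, n_indels = 30)
  res <- generate_focal_vcf(cfg, tempfile(fileext = ".vcf"))
  v <- read_vcf(res$path)
  expect_equal(v$chrom, res$variants$chrom)
  expect_equal(v$pos, res$variants$pos)
  expect_equal(v$ref, res$variants$ref)
  expect_equal(v$alt, res$variants$alt)
  expect_equal(v$class, res$variants$class)
  expect_equal(v$gt_GK, res$variants$gt_GK)
  expect_equal(v$gt_WISTAR, res$variants$gt_WISTAR)
  expect_equal(v$depth, res$variants$depth)
  expect_equal(v$base_quality, round(res$variants$base_quality, 2))
  # writing the re-read table reproduces the file byte for byte
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(v, p2)
  v2 <- read_vcf(p2)
  expect_equal(v2, v)
})

test_that("panel round trips with groups; bad files are fatal", {
  geno <- matrix(c("0/0", "1/1", "0/1", "./.", "1/2", "0/0"), nrow = 2,
                 dimnames = list(NULL, c("S1", "S2", "S3")))
  groups <- data.frame(strain = c("S1", "S2", "S3"),
                       group = c("case_consistent", "control_background",
                                 "other"),
                       stringsAsFactors = FALSE)
  panel <- make_panel("chr1", c(10, 20), geno, groups)
  pp <- tempfile(); gp <- tempfile()
  write_panel(panel, pp, gp)
  back <- read_panel(pp, gp)
  expect_equal(unname(back$genotypes), unname(geno))
  expect_equal(back$groups, groups)
  expect_equal(length(back$genotypes), 6)

  # duplicate site rows are fatal
  tab <- utils::read.delim(pp, check.names = FALSE)
  utils::write.table(rbind(tab, tab[1, ]), pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_panel(pp, gp), "duplicate")

  # unknown genotype codes are rejected
  tab$S1[1] <- "3/3"
  utils::write.table(tab, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_panel(pp, gp), "unknown panel genotype")
})

test_that("an empty panel reads to an empty matrix", {
  pp <- tempfile()
  writeLines("chrom\tpos\tS1\tS2", pp)
  panel <- read_panel(pp)
  expect_equal(nrow(panel$genotypes), 0)
})

test_that("gene BED round trips with 0-based half-open coordinates", {
  genes <- data.frame(
    gene_id = c("G1", "G2"), chrom = c("chr1", "chr2"),
    start = c(0L, 5000L), end = c(1000L, 9000L),
    is_olfactory_receptor = c(TRUE, FALSE), stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".bed")
  write_gene_bed(genes, path)
  back <- read_gene_bed(path)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$is_olfactory_receptor, genes$is_olfactory_receptor)
  # raw file is 0-based half-open
  raw <- utils::read.delim(path, header = FALSE)
  expect_equal(raw$V2, genes$start)
  expect_equal(raw$V3, genes$end)
})

test_that("annotation vocabulary is validated on read", {
  ann <- data.frame(chrom = "chr1", pos = 1, gene_id = "G1",
                    region_class = "promoter", exonic_effect = ".",
                    sift_call = ".", stringsAsFactors = FALSE)
  path <- tempfile()
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_annotations(path), "unknown region_class")
})

test_that("newick writing handles degenerate and regular trees", {
  p <- tempfile(fileext = ".nwk")
  write_newick("A", p)
  expect_equal(readLines(p), "A;")

  two <- upgma(matrix(c(0, 2, 2, 0), 2, 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  write_newick(two, p)
  expect_equal(readLines(p), "(A:1,B:1);")

  dup <- two; dup$tip.label <- c("A", "A")
  expect_error(write_newick(dup, p), "duplicate")
})

test_that("newick round trip preserves topology and heights", {
  set.seed(23)
  for (i in 1:5) {
    x <- matrix(runif(6 * 3), 6)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(LETTERS[1:6], LETTERS[1:6])
    tr <- upgma(d)
    p <- tempfile(fileext = ".nwk")
    back <- read_newick(write_newick(tr, p))
    expect_equal(ape::cophenetic.phylo(back)[LETTERS[1:6], LETTERS[1:6]],
                 ape::cophenetic.phylo(tr)[LETTERS[1:6], LETTERS[1:6]],
                 tolerance = 1e-9)
  }
})

test_that("expression matrices round trip with metadata validation", {
  cfg <- small_cfg(expr_n_genes = 20, expr_samples_per_condition = 2)
  ex <- generate_expression(cfg)
  mp <- tempfile(); tp <- tempfile()
  write_expression(ex$exprs, ex$meta, mp, tp)
  back <- read_expression(mp, tp)
  expect_equal(back$exprs, ex$exprs)
  expect_equal(back$meta, ex$meta)

  bad_meta <- ex$meta; bad_meta$tissue[1] <- NA
  utils::write.table(bad_meta, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_expression(mp, tp), "incomplete sample metadata")
})

test_that("bedGraph coverage aggregates bases at >= 3 reads per bin", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t100\t5",     # covered
               "chr1\t100\t150\t2",   # below threshold
               "chr1\t150\t250\t3"),  # covered
             bg)
  cov <- read_coverage_bedgraph(bg, c(chr1 = 400), bin_size = 200)
  expect_equal(cov$covered_bases, c(150, 50))
})

test_that("coverage bins reject counts exceeding the bin width", {
  path <- tempfile()
  utils::write.table(
    data.frame(chrom = "chr1", start = 0, end = 100, covered_bases = 200),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_coverage_bins(path), "within the bin width")
})
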