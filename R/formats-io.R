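# Readers and writers for every on-disk format the pipeline touches.
#
# Coordinate conventions (centralized here): VCF positions are 1-based
# inclusive; BED and all internal interval sets are 0-based half-open.
# Variant tables carry 1-based `pos`; interval tables carry 0-based
# `start`/`end`.

QC_FIELDS <- c("depth", "allele_number", "base_quality",
               "quality_by_depth", "zero_mapq_count")
.INFO_KEYS <- c(depth = "DP", allele_number = "AN", base_quality = "BQ",
                quality_by_depth = "QD", zero_mapq_count = "MQ0")

REGION_CLASSES <- c("exonic", "splicing", "ncRNA_exonic", "UTR",
                    "intronic", "upstream", "downstream", "intergenic")
EXONIC_EFFECTS <- c("nonsynonymous", "synonymous", "stopgain", "stoploss",
                    "frameshift_insertion", "frameshift_deletion", ".")

# sample names carried by a variant table
vcf_samples <- function(variants) {
  sub("^gt_", "", grep("^gt_", names(variants), value = TRUE))
}

#' Read a VCF file into the internal variant table
#'
#' Parses a VCF 4.x file (via vcfR) into a data frame with one row per
#' record: `chrom`, `pos` (1-based), `ref`, `alt` (comma-separated),
#' `class` (`SNV`, `insertion` or `deletion`), the site QC fields `depth`,
#' `allele_number`, `base_quality`, `quality_by_depth`, `zero_mapq_count`
#' (from INFO keys DP, AN, BQ, QD, MQ0; `NA` when absent), and one
#' `gt_<sample>` column per sample. Multi-allelic records are preserved
#' whole, never split. Phased genotypes are normalized to unphased codes;
#' genotypes with a missing allele become `./.`.
#'
#' @param path path to a VCF file.
#' @return variant table data frame.
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path,
                                         "': ", conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    stringsAsFactors = FALSE
  )
  out$class <- variant_class(out$ref, out$alt)
  for (f in names(.INFO_KEYS)) {
    out[[f]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = .INFO_KEYS[[f]])))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  for (s in colnames(gt)) out[[paste0("gt_", s)]] <- normalize_gt(gt[, s])
  rownames(out) <- NULL
  out
}

# SNV iff ref and every alt allele are single bases.
variant_class <- function(ref, alt) {
  alt_max <- vapply(strsplit(alt, ",", fixed = TRUE),
                    function(a) max(nchar(a)), integer(1))
  ifelse(nchar(ref) == 1L & alt_max == 1L, "SNV",
         ifelse(nchar(ref) > alt_max, "deletion", "insertion"))
}

#' Write a variant table as a plain-text VCF 4.2 file
#'
#' Inverse of [read_vcf()] for the fields the internal model preserves.
#'
#' @param variants variant table (see [read_vcf()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  samples <- vcf_samples(variants)
  .assert(length(samples) >= 1, "variant table has no gt_ columns")
  contigs <- unique(variants$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=strainprior",
    sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Called allele number\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"RMS base quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Reads with mapping quality zero\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                      scientific = FALSE))
  info <- sprintf("DP=%s;AN=%s;BQ=%s;QD=%s;MQ0=%s",
                  fmt_num(variants$depth), fmt_num(variants$allele_number),
                  fmt_num(round(variants$base_quality, 2)),
                  fmt_num(round(variants$quality_by_depth, 2)),
                  fmt_num(variants$zero_mapq_count))
  gts <- do.call(cbind, lapply(samples, function(s)
    variants[[paste0("gt_", s)]]))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a strain-panel genotype matrix
#'
#' The panel is a TSV with columns `chrom`, `pos` and one genotype column
#' per strain (codes `0/0`, `0/1`, `1/1`, `1/2`, `./.`). A sidecar TSV with
#' columns `strain`, `group` labels each strain `case_consistent`,
#' `control_background` or `other`.
#'
#' @param path panel TSV path.
#' @param groups_path sidecar strain-group TSV path (optional).
#' @return a `panel_matrix`: list with `sites` (data frame `chrom`, `pos`),
#'   `genotypes` (character matrix, rows = sites, columns = strains) and
#'   `groups` (data frame `strain`, `group`).
#' @export
read_panel <- function(path, groups_path = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  .assert(all(c("chrom", "pos") %in% names(tab)),
          "panel must have chrom and pos columns")
  strains <- setdiff(names(tab), c("chrom", "pos"))
  key <- paste(tab$chrom, tab$pos)
  if (anyDuplicated(key)) {
    stop("duplicate panel site rows: ", key[duplicated(key)][1])
  }
  geno <- as.matrix(tab[, strains, drop = FALSE])
  ok <- geno %in% c("0/0", "0/1", "1/1", "1/2", "2/2", "0/2", "./.")
  if (!all(ok)) stop("unknown panel genotype code: ", geno[!ok][1])
  groups <- if (!is.null(groups_path)) {
    utils::read.delim(groups_path, stringsAsFactors = FALSE)
  } else {
    data.frame(strain = strains, group = "other", stringsAsFactors = FALSE)
  }
  panel_matrix(tab[, c("chrom", "pos")], geno, groups)
}

#' Construct a panel matrix object
#'
#' @param sites data frame with `chrom`, `pos` (1-based).
#' @param genotypes character matrix (rows = sites, cols = strains).
#' @param groups data frame with `strain`, `group`.
#' @return a `panel_matrix` list.
#' @export
panel_matrix <- function(sites, genotypes, groups) {
  .assert(nrow(sites) == nrow(genotypes),
          "sites and genotypes disagree on row count")
  rownames(genotypes) <- paste(sites$chrom, sites$pos)
  structure(list(sites = sites, genotypes = genotypes, groups = groups),
            class = "panel_matrix")
}

#' @export
print.panel_matrix <- function(x, ...) {
  cat("panel_matrix:", nrow(x$genotypes), "sites x",
      ncol(x$genotypes), "strains\n")
  invisible(x)
}

#' Write a panel matrix and its strain-group sidecar
#'
#' @param panel a `panel_matrix`.
#' @param path panel TSV path.
#' @param groups_path sidecar TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, groups_path) {
  tab <- cbind(panel$sites, as.data.frame(panel$genotypes,
                                          stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$groups, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6
#'
#' BED columns: chrom, start, end (0-based half-open), name = gene id,
#' score = olfactory-receptor flag (1 = OR gene), strand.
#'
#' @param path BED file path.
#' @return data frame `gene_id`, `chrom`, `start`, `end`,
#'   `is_olfactory_receptor`.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    is_olfactory_receptor = !is.na(gr$score) & gr$score > 0,
    stringsAsFactors = FALSE
  )
}

#' Write gene models as BED6
#'
#' @param genes gene model data frame (see [read_gene_bed()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  .assert(all(genes$start < genes$end), "gene models need start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    name = genes$gene_id,
    score = as.integer(genes$is_olfactory_receptor)
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read per-variant functional annotations
#'
#' TSV dialect mirroring ANNOVAR/SIFT output: columns `chrom`, `pos`,
#' `gene_id`, `region_class`, `exonic_effect`, `sift_call`.
#'
#' @param path TSV path.
#' @return annotation data frame; region classes and exonic effects are
#'   validated against the supported vocabulary.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(ann$region_class), REGION_CLASSES)
  if (length(bad)) stop("unknown region_class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ann$exonic_effect), EXONIC_EFFECTS)
  if (length(bad)) stop("unknown exonic_effect: ", paste(bad, collapse = ", "))
  ann
}

#' @rdname read_annotations
#' @param ann annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a PPI edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `score` (score in \[0, 1\]).
#'
#' @param path TSV path.
#' @return edge data frame.
#' @export
read_edges <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("gene_a", "gene_b", "score") %in% names(e)),
          "edge list needs gene_a, gene_b, score")
  .assert(all(e$score >= 0 & e$score <= 1), "scores must be in [0, 1]")
  e
}

#' @rdname read_edges
#' @param edges edge data frame.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a prior-gene list (one gene id per line)
#'
#' @param path text file path.
#' @return character vector of gene ids.
#' @export
read_prior_genes <- function(path) readLines(path)

#' @rdname read_prior_genes
#' @param genes character vector of gene ids.
#' @export
write_prior_genes <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read / write an expression matrix with sample metadata
#'
#' The matrix TSV has a `gene_id` column followed by one column per sample;
#' the metadata TSV has columns `sample_id`, `strain`, `tissue`, `time`.
#'
#' @param matrix_path,meta_path TSV paths.
#' @return list with `exprs` (numeric matrix, genes x samples) and `meta`
#'   (data frame); every sample must carry all three metadata fields.
#' @export
read_expression <- function(matrix_path, meta_path) {
  tab <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  exprs <- as.matrix(tab[, -1, drop = FALSE])
  rownames(exprs) <- tab$gene_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  .assert(all(c("sample_id", "strain", "tissue", "time") %in% names(meta)),
          "metadata needs sample_id, strain, tissue, time")
  .assert(all(colnames(exprs) %in% meta$sample_id),
          "every expression column must be described in the metadata")
  .assert(!anyNA(meta[, c("strain", "tissue", "time")]),
          "incomplete sample metadata")
  list(exprs = exprs, meta = meta)
}

#' @rdname read_expression
#' @param exprs numeric matrix (genes x samples).
#' @param meta metadata data frame.
#' @export
write_expression <- function(exprs, meta, matrix_path, meta_path) {
  tab <- data.frame(gene_id = rownames(exprs), exprs, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read / write per-bin coverage
#'
#' Per-bin TSV with columns `chrom`, `start`, `end` (0-based half-open) and
#' `covered_bases` (bases in the bin covered by >= 3 reads).
#'
#' @param path TSV path.
#' @return coverage data frame.
#' @export
read_coverage_bins <- function(path) {
  cov <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("chrom", "start", "end", "covered_bases") %in% names(cov)),
          "coverage needs chrom, start, end, covered_bases")
  .assert(all(cov$covered_bases >= 0 &
                cov$covered_bases <= cov$end - cov$start),
          "covered_bases must lie within the bin width")
  cov
}

#' @rdname read_coverage_bins
#' @param cov coverage data frame.
#' @export
write_coverage_bins <- function(cov, path) {
  utils::write.table(cov, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Aggregate a bedGraph depth track into per-bin covered-base counts
#'
#' Counts, per fixed-width bin, the bases whose read depth is at least
#' `min_depth`.
#'
#' @param path bedGraph path (intervals with a depth value).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin_size bin width in bases.
#' @param min_depth minimum depth for a base to count as covered.
#' @return coverage data frame as in [read_coverage_bins()].
#' @export
read_coverage_bedgraph <- function(path, chrom_lengths, bin_size = 1e6,
                                   min_depth = 3) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[gr$score >= min_depth]
  bins <- tile_bins(chrom_lengths, bin_size)
  bgr <- GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start + 1L, end = bins$end))
  ov <- GenomicRanges::findOverlaps(bgr, gr)
  covered <- rep(0, nrow(bins))
  if (length(ov)) {
    inter <- GenomicRanges::pintersect(bgr[S4Vectors::queryHits(ov)],
                                       gr[S4Vectors::subjectHits(ov)])
    w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(w))] <- as.numeric(w)
  }
  bins$covered_bases <- covered
  bins
}

#' Read / write SV and CNV interval features
#'
#' TSV with columns `chrom`, `start`, `end` (0-based half-open),
#' `feature_kind` (one of the SV kinds, `CNV-gain` or `CNV-loss`), `ratio`
#' (case/control mapped-read ratio, CNV only) and `p_value` (CNV only).
#'
#' @param path TSV path.
#' @return feature data frame.
#' @export
read_features <- function(path) {
  feat <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(feat$start < feat$end), "features need start < end")
  .assert(all(is.na(feat$ratio) | feat$ratio > 0),
          "CNV ratios must be positive")
  feat
}

#' @rdname read_features
#' @param feat feature data frame.
#' @export
write_features <- function(feat, path) {
  utils::write.table(feat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a truth panel of known site statuses
#'
#' TSV with columns `chrom`, `pos` (1-based) and `status`
#' (`variant` = polymorphic in all strains of the group,
#' `invariant` = non-polymorphic in all of them).
#'
#' @param path TSV path.
#' @return truth data frame.
#' @export
read_truth_panel <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(tr$status %in% c("variant", "invariant")),
          "truth status must be 'variant' or 'invariant'")
  tr
}

#' @rdname read_truth_panel
#' @param truth truth data frame.
#' @export
write_truth_panel <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree an `ape` `phylo` object (or, for the degenerate single-leaf
#'   case, a length-1 character label).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (is.character(tree) && length(tree) == 1L) {
    writeLines(paste0(tree, ";"), path)
    return(invisible(path))
  }
  .assert(inherits(tree, "phylo"), "tree must be a phylo object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file path.
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write an R object as stable, human-readable JSON
#'
#' Deterministic serialization (fixed precision, no timestamps), so that
#' identical inputs produce byte-identical files.
#'
#' @param x object to serialize.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_json_report
#' @export
read_json_report <- function(path) jsonlite::read_json(path)
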