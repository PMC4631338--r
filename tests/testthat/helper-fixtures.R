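# Shared fixtures, built in code at test time.

# a desk-scale configuration that keeps generation fast
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_variants = 2000, n_indels = 200, n_panel_sites = 300,
         expr_n_genes = 100, n_genes = 150, ppi_n_edges = 1500,
         prior_gene_count = 40, seed = 42),
    list(...))
  do.call(sim_config, args)
}

# build a variant table row by row
make_variants <- function(chrom, pos, ref = "A", alt = "G", class = "SNV",
                          depth = 20, allele_number = 4,
                          base_quality = 35, quality_by_depth = 10,
                          zero_mapq_count = 0,
                          gt_case = "1/1", gt_control = "0/0",
                          case = "GK", control = "WISTAR") {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   class = class, depth = depth,
                   allele_number = allele_number,
                   base_quality = base_quality,
                   quality_by_depth = quality_by_depth,
                   zero_mapq_count = zero_mapq_count,
                   stringsAsFactors = FALSE)
  df[[paste0("gt_", case)]] <- gt_case
  df[[paste0("gt_", control)]] <- gt_control
  df
}

# small panel_matrix from explicit genotype rows
make_panel <- function(chrom, pos, geno, groups) {
  panel_matrix(data.frame(chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE),
               geno, groups)
}

# independent brute-force oracle for the SNV cluster rule: enumerate every
# 10-base window over the position range
cluster_oracle <- function(chrom, pos, window = 10L, min_count = 3L) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- sort(pos[idx])
    starts <- seq(min(p) - window + 1L, max(p))
    n_in <- findInterval(starts + window - 1L, p) -
      findInterval(starts - 1L, p)
    for (s in starts[n_in >= min_count]) {
      out[idx[pos[idx] >= s & pos[idx] <= s + window - 1L]] <- TRUE
    }
  }
  out
}

# direct hypergeometric upper-tail sum via binomial coefficients
hyper_tail_oracle <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
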