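# Differential expression and differential co-expression between case and
# control strains, per tissue and time point, with union combination
# across cells.

# sample ids of one (strain, tissue, time) cell
.cell_samples <- function(meta, strain, tissue, time) {
  meta$sample_id[meta$strain == strain & meta$tissue == tissue &
                   meta$time == time]
}

#' Differential expression in one tissue / time-point cell
#'
#' Welch two-sample t-test per gene between case and control samples of
#' the cell, with a direction-symmetric fold change on linear intensities
#' (or `2^(mean log2 difference)` when the matrix is log2 scale). A gene
#' is differentially expressed when p <= 0.01 and the fold change exceeds
#' 2 in either direction. Degenerate genes (zero variance in both groups)
#' get p = 1 when the means are equal, p = 0 when they differ (the
#' fold-change rule then decides).
#'
#' @param exprs genes x samples matrix.
#' @param meta sample metadata (`sample_id`, `strain`, `tissue`, `time`).
#' @param tissue,time cell selectors.
#' @param case,control strain labels.
#' @param genes genes to test (default: all rows).
#' @param log_scale `TRUE` when the matrix holds log2 intensities.
#' @param p_threshold,fc_threshold decision thresholds.
#' @return data frame `gene`, `tissue`, `time`, `p_value`, `fold_change`
#'   (case over control, linear scale), `is_de`.
#' @export
differential_expression <- function(exprs, meta, tissue, time,
                                    case, control, genes = rownames(exprs),
                                    log_scale = FALSE,
                                    p_threshold = 0.01, fc_threshold = 2) {
  cs <- .cell_samples(meta, case, tissue, time)
  ct <- .cell_samples(meta, control, tissue, time)
  .assert(length(cs) >= 2 && length(ct) >= 2,
          "need >= 2 samples per condition in the cell")
  genes <- intersect(genes, rownames(exprs))
  x <- exprs[genes, cs, drop = FALSE]
  y <- exprs[genes, ct, drop = FALSE]
  res <- lapply(seq_along(genes), function(i) {
    xi <- x[i, ]; yi <- y[i, ]
    if (stats::sd(xi) == 0 && stats::sd(yi) == 0) {
      p <- if (mean(xi) == mean(yi)) 1 else 0
    } else {
      p <- stats::t.test(xi, yi)$p.value
    }
    fc <- if (log_scale) 2^(mean(xi) - mean(yi)) else mean(xi) / mean(yi)
    data.frame(gene = genes[i], tissue = tissue, time = time,
               p_value = p, fold_change = fc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$is_de <- out$p_value <= p_threshold &
    pmax(out$fold_change, 1 / out$fold_change) > fc_threshold
  out
}

# mean |Fisher-z difference| of each gene's correlations to its partners,
# for two correlation matrices at once (diagonal excluded)
.dcz_all <- function(cx, cy) {
  clamp <- function(m) pmin(pmax(m, -0.999999), 0.999999)
  a <- abs(atanh(clamp(cx)) - atanh(clamp(cy)))
  diag(a) <- 0
  rowSums(a) / (ncol(a) - 1)
}

#' Differential co-expression in one tissue / time-point cell
#'
#' For each gene of `gene_set`, computes its Pearson correlation with
#' every other gene of the set within case samples and within control
#' samples; the statistic (`dcz`) is the mean over partners of the
#' absolute difference of Fisher-transformed correlations. Significance
#' comes from permutation of the condition labels (all genes share the
#' permutations of one cell), with Bonferroni correction over the tested
#' genes. Constant genes are skipped with a warning.
#'
#' @param exprs genes x samples matrix.
#' @param meta sample metadata.
#' @param tissue,time cell selectors.
#' @param case,control strain labels.
#' @param gene_set genes whose co-expression structure is compared.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @param alpha Bonferroni-adjusted significance threshold.
#' @return data frame `gene`, `tissue`, `time`, `dc_statistic`, `p_value`,
#'   `adjusted_p`, `is_dc`; empty when fewer than two usable genes.
#' @export
differential_coexpression <- function(exprs, meta, tissue, time,
                                      case, control, gene_set,
                                      n_perm = 1000, seed = 1,
                                      alpha = 0.05) {
  cs <- .cell_samples(meta, case, tissue, time)
  ct <- .cell_samples(meta, control, tissue, time)
  .assert(length(cs) >= 4 && length(ct) >= 4,
          "need >= 4 samples per condition for correlation testing")
  gene_set <- intersect(gene_set, rownames(exprs))
  x <- t(exprs[gene_set, cs, drop = FALSE])
  y <- t(exprs[gene_set, ct, drop = FALSE])
  const <- apply(x, 2, stats::sd) == 0 | apply(y, 2, stats::sd) == 0
  if (any(const)) {
    warning("skipping constant gene(s): ",
            paste(gene_set[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]; y <- y[, !const, drop = FALSE]
    gene_set <- gene_set[!const]
  }
  m <- length(gene_set)
  empty <- data.frame(gene = character(0), tissue = character(0),
                      time = integer(0), dc_statistic = numeric(0),
                      p_value = numeric(0), adjusted_p = numeric(0),
                      is_dc = logical(0), stringsAsFactors = FALSE)
  if (m < 2) return(empty)

  cx <- stats::cor(x); cy <- stats::cor(y)
  obs <- .dcz_all(cx, cy)

  pooled <- rbind(x, y)
  n_case <- nrow(x)
  n_tot <- nrow(pooled)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  count <- integer(m)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_tot, n_case)
    px <- pooled[idx, , drop = FALSE]
    py <- pooled[-idx, , drop = FALSE]
    pcx <- suppressWarnings(stats::cor(px))
    pcy <- suppressWarnings(stats::cor(py))
    pcx[is.na(pcx)] <- 0; pcy[is.na(pcy)] <- 0
    count <- count + (.dcz_all(pcx, pcy) >= obs)
  }
  p <- (1 + count) / (1 + n_perm)
  adj <- pmin(1, p * m)  # Bonferroni over the tested gene set
  data.frame(gene = gene_set, tissue = tissue, time = time,
             dc_statistic = obs, p_value = p, adjusted_p = adj,
             is_dc = adj <= alpha, stringsAsFactors = FALSE)
}

#' Combine per-cell differential calls across time points and tissues
#'
#' Union semantics: a gene is differentially expressed (or co-expressed)
#' in a tissue when flagged at at least one time point, and differential
#' overall when flagged in at least one tissue.
#'
#' @param de_results row-bound [differential_expression()] results (or
#'   `NULL`).
#' @param dc_results row-bound [differential_coexpression()] results (or
#'   `NULL`).
#' @return data frame `gene`, `is_de`, `is_dc`, `de_tissues`,
#'   `dc_tissues` (comma-separated tissue lists), `is_differential`.
#' @export
combine_timepoints <- function(de_results = NULL, dc_results = NULL) {
  tissues_of <- function(res, flag_col) {
    if (is.null(res) || nrow(res) == 0) {
      return(data.frame(gene = character(0), tissues = character(0),
                        stringsAsFactors = FALSE))
    }
    hit <- res[res[[flag_col]], , drop = FALSE]
    if (nrow(hit) == 0) {
      return(data.frame(gene = character(0), tissues = character(0),
                        stringsAsFactors = FALSE))
    }
    agg <- stats::aggregate(tissue ~ gene, data = hit,
                            FUN = function(t) paste(sort(unique(t)),
                                                    collapse = ","))
    names(agg) <- c("gene", "tissues")
    agg
  }
  de <- tissues_of(de_results, "is_de")
  dc <- tissues_of(dc_results, "is_dc")
  genes <- sort(unique(c(
    if (!is.null(de_results)) de_results$gene,
    if (!is.null(dc_results)) dc_results$gene
  )))
  out <- data.frame(
    gene = genes,
    is_de = genes %in% de$gene,
    is_dc = genes %in% dc$gene,
    de_tissues = de$tissues[match(genes, de$gene)],
    dc_tissues = dc$tissues[match(genes, dc$gene)],
    stringsAsFactors = FALSE
  )
  out$de_tissues[is.na(out$de_tissues)] <- ""
  out$dc_tissues[is.na(out$dc_tissues)] <- ""
  out$is_differential <- out$is_de | out$is_dc
  out
}
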