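# PPI partner enrichment of prior genes, and the shared-partner network.

#' Build a PPI graph from a scored edge list
#'
#' Keeps edges whose score is strictly greater than the threshold (an edge
#' scoring exactly at the threshold is excluded), removes self-loops, and
#' collapses duplicate undirected pairs.
#'
#' @param edges edge data frame (`gene_a`, `gene_b`, `score`).
#' @param score_threshold confidence cutoff (default 0.4).
#' @return a `ppi_graph`: list with `edges` (cleaned data frame),
#'   `partners` (named list of partner-gene sets), and `nodes`.
#' @export
build_ppi_graph <- function(edges, score_threshold = 0.4) {
  e <- edges[edges$score > score_threshold & edges$gene_a != edges$gene_b, ,
             drop = FALSE]
  key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  e <- e[!duplicated(key), , drop = FALSE]
  rownames(e) <- NULL
  both <- rbind(
    data.frame(g = e$gene_a, p = e$gene_b, stringsAsFactors = FALSE),
    data.frame(g = e$gene_b, p = e$gene_a, stringsAsFactors = FALSE)
  )
  partners <- lapply(split(both$p, both$g), unique)
  structure(list(edges = e, partners = partners,
                 nodes = sort(unique(c(e$gene_a, e$gene_b)))),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("ppi_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Test one gene's PPI partners for prior-gene enrichment
#'
#' One-sided Fisher exact test (enrichment direction) on the 2x2 table
#' partitioning the universe (excluding the tested gene) by partner /
#' non-partner and prior / non-prior. A gene with no partners gets p = 1.
#'
#' @param graph a `ppi_graph`.
#' @param gene tested gene id.
#' @param prior_set prior gene ids (subset of the universe).
#' @param universe gene universe; defaults to all graph nodes plus the
#'   prior genes, so genes invisible to the PPI data are not counted as
#'   non-partners.
#' @return list: `gene`, `k` (prior partners), `n` (partners), `K` (prior
#'   genes in universe), `N` (universe size), `p_value`.
#' @export
partner_enrichment <- function(graph, gene, prior_set, universe = NULL) {
  if (is.null(universe)) universe <- union(graph$nodes, prior_set)
  .assert(all(prior_set %in% universe), "prior_set must be in the universe")
  uni <- setdiff(universe, gene)
  partners <- intersect(graph$partners[[gene]], uni)
  prior <- intersect(prior_set, uni)
  k <- length(intersect(partners, prior))
  n <- length(partners)
  K <- length(prior)
  N <- length(uni)
  p <- if (n == 0) 1 else {
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), 2, 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }
  list(gene = gene, k = k, n = n, K = K, N = N, p_value = p)
}

#' Partner enrichment over a candidate gene set, with adjustment
#'
#' @param graph a `ppi_graph`.
#' @param genes candidate gene ids.
#' @param prior_set prior gene ids.
#' @param universe see [partner_enrichment()].
#' @param method multiple-testing adjustment passed to
#'   [adjust_pvalues()] (default Benjamini-Hochberg).
#' @return data frame with one row per gene: `gene`, `k`, `n`, `K`, `N`,
#'   `p_value`, `adjusted_p`; the adjustment method is recorded in the
#'   `adjust_method` attribute.
#' @export
enrich_gene_set <- function(graph, genes, prior_set, universe = NULL,
                            method = "BH") {
  rows <- lapply(genes, function(g)
    as.data.frame(partner_enrichment(graph, g, prior_set, universe),
                  stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$adjusted_p <- adjust_pvalues(out$p_value, method = method)
  attr(out, "adjust_method") <- method
  out
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up by default; Bonferroni available. Thin,
#' explicit wrapper over [stats::p.adjust()] so the method used is always
#' recorded by the callers.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values (each >= its raw value).
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  .assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Shared-partner relationship network among a gene set
#'
#' Edge weight between two genes is the size of the intersection of their
#' partner sets; zero-weight pairs are omitted. Genes absent from the
#' graph contribute empty partner sets (isolated nodes).
#'
#' @param graph a `ppi_graph`.
#' @param gene_set gene ids.
#' @return data frame `gene_a`, `gene_b`, `weight` (`gene_a < gene_b`,
#'   sorted for deterministic output).
#' @export
shared_partner_network <- function(graph, gene_set) {
  gene_set <- sort(unique(gene_set))
  psets <- lapply(gene_set, function(g) {
    p <- graph$partners[[g]]
    if (is.null(p)) character(0) else p
  })
  names(psets) <- gene_set
  out <- list()
  n <- length(gene_set)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      w <- length(intersect(psets[[i]], psets[[j]]))
      if (w > 0) {
        out[[length(out) + 1L]] <- data.frame(
          gene_a = gene_set[i], gene_b = gene_set[j], weight = w,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      weight = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
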