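# Fisher enrichment of prior genes among PPI partners.

.graph_from_partners <- function(gene, partners, extra = NULL) {
  e <- data.frame(gene_a = gene, gene_b = partners, score = 0.9,
                  stringsAsFactors = FALSE)
  if (!is.null(extra)) e <- rbind(e, extra)
  build_ppi_graph(e)
}

test_that("score threshold is strict and self-loops/duplicates are cleaned", {
  e <- data.frame(gene_a = c("A", "A", "A", "B", "A"),
                  gene_b = c("B", "C", "A", "A", "D"),
                  score = c(0.4, 0.5, 0.9, 0.8, 0.39),
                  stringsAsFactors = FALSE)
  g <- build_ppi_graph(e)
  # A-B at exactly 0.4 excluded; self-loop excluded; B-A duplicate of A-B
  expect_equal(nrow(g$edges), 2)
  expect_setequal(g$partners$A, c("C", "B"))
})

test_that("degenerate enrichment margins give p = 1", {
  g <- .graph_from_partners("X", c("P1", "P2"))
  # zero partners (gene absent from the graph)
  expect_equal(partner_enrichment(g, "LONER", c("P1"),
                                  universe = c("LONER", "X", "P1", "P2"))
               $p_value, 1)
  # all universe genes are prior: no enrichment possible
  res <- partner_enrichment(g, "X", c("P1", "P2"),
                            universe = c("X", "P1", "P2"))
  expect_equal(res$p_value, 1)
})

test_that("Fisher p equals the direct hypergeometric tail", {
  # fixed worked instance: n = 10 partners, k = 5 prior, N = 1000, K = 50
  others <- sprintf("U%03d", 1:999)
  prior <- others[1:50]
  partners <- c(others[1:5], others[100:104])
  g <- .graph_from_partners("X", partners)
  res <- partner_enrichment(g, "X", prior, universe = c("X", others))
  expect_equal(res$k, 5)
  expect_equal(res$n, 10)
  expect_equal(res$p_value, hyper_tail_oracle(5, 10, 50, 999),
               tolerance = 1e-10)

  # randomized instances at N <= 200
  set.seed(17)
  for (i in 1:20) {
    N <- sample(20:200, 1)
    K <- sample.int(N - 5, 1)
    n <- sample.int(N - 1, 1)
    uni <- sprintf("g%03d", seq_len(N))
    prior <- sample(uni, K)
    partners <- sample(uni, n)
    g <- .graph_from_partners("X", partners)
    res <- partner_enrichment(g, "X", prior, universe = c("X", uni))
    expect_equal(res$p_value,
                 hyper_tail_oracle(res$k, res$n, res$K, res$N),
                 tolerance = 1e-9, info = paste("instance", i))
  }
})

test_that("p-value adjustment matches hand computations", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.5), method = "bonferroni"),
               c(0.02, 1.0))
  expect_true(all(adjust_pvalues(runif(10)) >= sort(runif(10))[0]))
})

test_that("a graph with no retained edges yields p = 1 everywhere", {
  e <- data.frame(gene_a = "A", gene_b = "B", score = 0.1,
                  stringsAsFactors = FALSE)
  g <- build_ppi_graph(e)
  res <- enrich_gene_set(g, c("A", "B"), prior_set = "A",
                         universe = c("A", "B", "C"))
  expect_equal(res$p_value, c(1, 1))
})

test_that("shared-partner weights match the adjacency-matrix oracle", {
  ps <- sprintf("p%d", 1:7)
  e <- rbind(
    data.frame(gene_a = "A", gene_b = ps, score = 0.9,
               stringsAsFactors = FALSE),
    data.frame(gene_a = "B", gene_b = ps, score = 0.9,
               stringsAsFactors = FALSE),
    data.frame(gene_a = "C", gene_b = "q", score = 0.9,
               stringsAsFactors = FALSE)
  )
  g <- build_ppi_graph(e)
  net <- shared_partner_network(g, c("A", "B", "C"))
  expect_equal(net$weight[net$gene_a == "A" & net$gene_b == "B"], 7)
  expect_false(any(net$gene_a == "C" | net$gene_b == "C"))

  # random graph vs A %*% t(A) common-neighbour counts
  set.seed(19)
  nodes <- sprintf("n%02d", 1:30)
  e2 <- data.frame(gene_a = sample(nodes, 200, replace = TRUE),
                   gene_b = sample(nodes, 200, replace = TRUE),
                   score = runif(200), stringsAsFactors = FALSE)
  g2 <- build_ppi_graph(e2)
  adj <- matrix(0L, 30, 30, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(g2$edges))) {
    adj[g2$edges$gene_a[r], g2$edges$gene_b[r]] <- 1L
    adj[g2$edges$gene_b[r], g2$edges$gene_a[r]] <- 1L
  }
  w_oracle <- adj %*% t(adj)
  net2 <- shared_partner_network(g2, nodes)
  for (r in seq_len(nrow(net2))) {
    expect_equal(net2$weight[r],
                 unname(w_oracle[net2$gene_a[r], net2$gene_b[r]]))
  }
  # zero-weight pairs omitted
  zero_pairs <- sum(w_oracle[upper.tri(w_oracle)] == 0)
  expect_equal(nrow(net2), choose(30, 2) - zero_pairs)
})
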