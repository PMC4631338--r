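#!/usr/bin/env Rscript
# Score the candidate genes with the three evidence streams: prior-gene
# membership, prior-gene enrichment among PPI partners, and differential
# (co-)expression; then integrate into the tiered candidate table.

library(strainprior)

cohort <- "results/cohort"
candidates <- readLines("results/candidate_genes.txt")
surviving <- utils::read.delim("results/surviving_pavs.tsv")

prior <- read_prior_genes(file.path(cohort, "prior_genes.txt"))
graph <- build_ppi_graph(read_edges(file.path(cohort, "ppi_edges.tsv")))
enr <- enrich_gene_set(graph, candidates, prior)
cat(sprintf("PPI enrichment: %d of %d candidates at adjusted p <= 0.05\n",
            sum(enr$adjusted_p <= 0.05), nrow(enr)))

ex <- read_expression(file.path(cohort, "expression.tsv"),
                      file.path(cohort, "expression_meta.tsv"))
test_genes <- intersect(rownames(ex$exprs), candidates)
de_all <- list(); dc_all <- list()
for (ti in sort(unique(ex$meta$tissue))) {
  for (tp in sort(unique(ex$meta$time))) {
    de_all[[paste(ti, tp)]] <- differential_expression(
      ex$exprs, ex$meta, ti, tp, "GK", "WISTAR", genes = test_genes)
    dc_all[[paste(ti, tp)]] <- differential_coexpression(
      ex$exprs, ex$meta, ti, tp, "GK", "WISTAR", test_genes,
      n_perm = 200, seed = 1000 + tp)
  }
}
flags <- combine_timepoints(do.call(rbind, de_all),
                            do.call(rbind, dc_all))
cat(sprintf("expression: %d DE, %d DC genes in at least one tissue\n",
            sum(flags$is_de), sum(flags$is_dc)))

evidence <- integrate_evidence(candidates, prior, enr, flags,
                               variants = surviving)
n_hc <- sum(evidence$tier == "high-confidence")
cat(sprintf("%d high-confidence candidates (prior gene or PPI-enriched):\n",
            n_hc))
print(utils::head(evidence[, c("gene", "is_prior_gene", "ppi_enriched",
                               "enrichment_adjusted_p",
                               "expression_support", "tier")], n_hc + 3),
      row.names = FALSE)

net <- shared_partner_network(graph,
                              evidence$gene[evidence$tier ==
                                              "high-confidence"])
utils::write.table(net, "results/shared_partner_network.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(evidence, "results/candidate_evidence.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/candidate_evidence.tsv and shared_partner_network.tsv\n")
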