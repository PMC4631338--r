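#!/usr/bin/env Rscript
# Select protein-affecting variants, apply the strain-panel consistency
# filter and olfactory-receptor exclusion, map SV/CNV features to genes,
# and build the UPGMA strain tree from net nucleotide substitutions.

library(strainprior)

cohort <- "results/cohort"
specific <- utils::read.delim("results/specific_variants.tsv")

ann <- flag_pav(read_annotations(file.path(cohort, "annotations.tsv")))
m <- match(paste(specific$chrom, specific$pos), paste(ann$chrom, ann$pos))
specific$gene_id <- ann$gene_id[m]
specific$is_pav <- !is.na(m) & ann$is_pav[m]
pavs <- specific[specific$is_pav, ]
cat(sprintf("%d protein-affecting variants among %d specific variants\n",
            nrow(pavs), nrow(specific)))

panel <- read_panel(file.path(cohort, "panel.tsv"),
                    file.path(cohort, "strain_groups.tsv"))
pf <- panel_filter(pavs, panel, "GK")
cat(sprintf("panel-consistency filter: %d -> %d PAVs (%d heterozygous set aside)\n",
            nrow(pavs), nrow(pf$surviving), nrow(pf$heterozygous)))

genes <- read_gene_bed(file.path(cohort, "genes.bed"))
cand <- sort(unique(pf$surviving$gene_id[pf$surviving$gene_id != "."]))
orx <- exclude_or_genes(cand, genes)
cat(sprintf("OR exclusion: %d genes - %d OR = %d candidates\n",
            length(cand), orx$n_removed, length(orx$kept)))

feat <- read_features(file.path(cohort, "features.tsv"))
cnv <- feat[grepl("^CNV", feat$feature_kind), ]
fc <- filter_differential_cnv(cnv)
hits <- overlap_features_with_genes(
  rbind(feat[grepl("^SV", feat$feature_kind), ], fc$passed), genes)
cat(sprintf("differential CNVs: %d of %d; SV/CNV-affected genes: %d\n",
            fc$report$n_passed, fc$report$n_input,
            length(unique(hits$gene_id))))

tree <- upgma(distance_matrix(panel))
write_newick(tree, "results/strain_tree.nwk")
cat("case clade joins first:",
    ape::cophenetic.phylo(tree)["GK", "GK_Ox"] <
      min(ape::cophenetic.phylo(tree)["GK", c("WKY_NCrl", "LEW_Crl")]),
    "\n")

writeLines(orx$kept, "results/candidate_genes.txt")
utils::write.table(pf$surviving, "results/surviving_pavs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/candidate_genes.txt, surviving_pavs.tsv, strain_tree.nwk\n")
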