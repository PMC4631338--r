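#!/usr/bin/env Rscript
# Build the synthetic study cohort: a two-strain focal call set with the
# study's genotype-group mixture and Ti/Tv, a 14-strain panel, gene
# models, annotations, PPI + prior genes, an expression design and
# SV/CNV features — all with known planted ground truth.

library(strainprior)

cohort_dir <- "results/cohort"
cfg <- sim_config(seed = 20151103)
out <- generate_all(cfg, cohort_dir)

cat("Synthetic cohort written to", cohort_dir, "\n")
cat(sprintf("  %d SNVs + %d indels on %d chromosomes\n",
            cfg$n_variants, cfg$n_indels, length(cfg$chromosome_lengths)))
cat(sprintf("  panel: %d strains, %d tree-evolved sites\n",
            cfg$n_panel_strains, cfg$n_panel_sites))
cat(sprintf("  planted: %d enriched, %d DE, %d DC genes; truth candidates: %d\n",
            length(out$truth$true_enriched_genes),
            nrow(out$truth$true_de_genes),
            nrow(out$truth$true_dc_genes),
            length(out$truth$true_candidate_genes)))
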