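Package: strainprior
Title: Strain-Specific Variant Prioritization for Inbred Disease Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-genome variant prioritization for inbred
    case/control strain pairs, as used to nominate disease candidate genes
    in rat models. Implements post-calling hard filters for SNVs, indels
    and differential CNV regions; strain-specific variant derivation with
    five-way genotype-group classification and Ti/Tv, homozygosity and
    truth-panel validation statistics; coverage-normalized variant density
    profiling in fixed genomic bins; protein-affecting variant selection
    with multi-strain panel-consistency filtering and olfactory-receptor
    gene exclusion; UPGMA strain phylogenies from net nucleotide
    substitution (Nei's dA) distances; Fisher exact-test enrichment of
    prior genes among protein-protein interaction partners; differential
    expression and differential co-expression evidence; and integration of
    all evidence streams into a tiered candidate-gene table. A synthetic
    data generator with known ground truth emulates every input so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
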