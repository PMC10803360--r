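Package: scatID
Title: Individual Identification and Population Genetics from SNP-Genotyped Scats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for minimally invasive genetic monitoring from faecal
    DNA genotyped on targeted SNP panels. Implements SNP panel selection from
    reduced-representation (DArT-style) locus metadata via a thirteen-step
    filter cascade with an exact Hardy-Weinberg test and LD pruning,
    probability-of-identity panel sizing, cleaning and average-linkage
    clustering of noisy scat genotypes by allelic mismatch with elbow,
    heat-map and binomial misassignment diagnostics, allelic-dropout
    estimation from replicate samples, qPCR-based molecular sexing decision
    rules, consensus genotypes with VCF export, population-genetic summaries
    (heterozygosity, allelic richness, inbreeding, Ritland pairwise
    relatedness), and a truth-known scat-study simulator so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'genotype-matrix.R'
    'io.R'
    'hwe.R'
    'ld.R'
    'pid.R'
    'panel-filter.R'
    'subset-diversity.R'
    'cluster.R'
    'misassign.R'
    'ado.R'
    'sexing.R'
    'popgen.R'
    'simulate.R'
    'workflow.R'
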