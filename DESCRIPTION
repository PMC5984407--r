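Package: kleptopop
Title: Genome-Exchange Inference for Mixed-Ploidy Unisexual Salamander Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting genome exchange in sperm-dependent unisexual
    lineages of the Ambystoma laterale-jeffersonianum complex from co-dominant
    microsatellite genotypes and AFLP band data. Microsatellite loci are
    partitioned into species-specific isoloci (J and L haplomes), ploidy and
    biotype are called from distinct allele counts, and individuals are
    assigned to genetic groups via diagnostic alleles at multimodal loci.
    Genotype dissimilarities follow the Bruvo stepwise-mutation model with
    genome-addition and genome-loss handling of unequal ploidy and
    allele-frequency-weighted imputation of partial heterozygotes.
    Downstream diagnostics include neighbor-joining trees with locus
    bootstrap, extended majority-rule consensus, Mantel tests and
    correlograms, divergent-allele detection, rarefied allelic richness,
    alternative-allele statistics, and centroid-dispersion partitioning of
    genetic variation within and among sites. A forward-time kleptogenesis
    simulator generates datasets with known lineage, ploidy and exchange
    histories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
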