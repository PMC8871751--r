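Package: patrilineR
Title: Y-Chromosomal Haplotype Lineage Tracing for Sire-Line Genealogies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paternal-lineage tracing on the male-specific region of
    the Y chromosome (MSY). Reads haploid sample-by-variant call matrices (VCF
    or delimited), applies depth/quality/call-rate ascertainment filters,
    polarizes alleles against an outgroup, imputes missing calls by haplogroup
    consensus, reconstructs the rooted haplotype tree under the perfect
    phylogeny (infinite sites) assumption, names haplotypes with a hierarchical
    nomenclature grammar, designs reduced marker backbones for consecutive
    panel genotyping with unresolved-node (*) placement, and tests tail-male
    pedigree records for congruence with the molecular haplotypes. A forward
    simulator of non-recombining haploid inheritance with genotyping noise and
    paternity errors provides ground truth for every stage, and a bundled
    machine-encoded panel of occidental Arabian sire lines reproduces the
    reference summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    igraph
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
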