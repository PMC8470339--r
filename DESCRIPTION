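Package: commphylo
Title: Community Phylogenetic Structure with Richness-Preserving Null Models
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the phylogenetic structure of
    presence/absence community data on a rooted phylogeny: Faith's
    phylogenetic diversity (PD), mean pairwise distance (MPD) and mean
    nearest-taxon distance (MNTD) within assemblages; their between-community
    analogues (comdist/comdistnt-style); standardized effect sizes under a
    richness-preserving randomization from a global species pool (PDI, the
    SES of PD, and NTI, the negative SES of MNTD); principal coordinates
    analysis of between-site phylogenetic distance matrices with
    variance-explained accounting; life-form proportion summaries and
    group-level statistics (dominant versus non-dominant, invasive versus
    native species); and a seeded synthetic-data generator (Yule trees,
    neutral/clustered/overdispersed community assembly, species attributes)
    so every stage of the pipeline can be tested against known structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
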