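Package: edamap
Title: Haplotype Fine-Mapping of the Stickleback Eda Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association fine-mapping toolkit for a dense marker panel across
    a short haplotype, modelled on the threespine stickleback Eda region.
    Provides rule-based imputation of missing genotypes from flanking
    markers, classification of individuals into haplotype carrier classes
    (including historical recombinants detected from unphased genotypes),
    per-marker LOD and percent-variance-explained association scans with
    covariate models, stratified permutation significance testing,
    detectable-effect power analysis, two-locus dominance and epistasis
    contrasts, and a synthetic population generator that emulates the
    statistical structure of marine carrier crosses and a polymorphic
    freshwater population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
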