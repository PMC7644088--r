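Package: gxtheta
Title: SNP-by-Ancestry Interaction Mapping in Model Organism Crosses
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Linear mixed model association testing for polygenic epistasis
    in structured mapping populations. Implements a kinship-corrected
    likelihood-ratio test for interaction between each SNP and global
    genetic ancestry proportion (the Gxtheta test), ancestry calling from
    biparental founder genotypes, genetic relationship matrices on genotype
    or ancestry-informative SNP sets, forward simulators for recombinant
    inbred panels, advanced intercross lines and haploid crosses, a power
    and higher-order epistasis simulation framework, and a Wald scan for
    transmission ratio distortion (allelic imbalance) with
    Benjamini-Hochberg control and region clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
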