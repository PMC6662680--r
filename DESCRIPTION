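Package: pooxe
Title: Parent-of-Origin by Environment Interaction Analysis for Case-Parent Triads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide screening for parent-of-origin by environment
    (PoOxE) interactions in case-parent triad and dyad designs, as used in
    family-based studies of orofacial clefts. Provides a synthetic triad
    generator with known truth, SNP-level quality control (exact
    Hardy-Weinberg test, Mendelian-error screening, perfect-LD pruning),
    maximum-likelihood estimation of maternally and paternally inherited
    allele and haplotype relative risks via EM over latent transmissions
    (handling missing fathers and unphased haplotypes), Wald tests of the
    relative-risk-ratio statistics RRR_PoO and RRR_PoOxE, Storey-Tibshirani
    q-values with QQ-plot data, and asymptotic power calculations for the
    PoOxE Wald test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
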