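Package: epitrd
Title: Epistatic Transmission Ratio Distortion Scans from Genotyped Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects two-locus (epistatic) transmission ratio distortion from
    sire-dam-offspring genotyped trios. Implements Bayesian genotypic and
    allelic (gamete-transmission) two-locus distortion models fitted by
    Metropolis-Hastings sampling with Savage-Dickey Bayes factors, likelihood
    ratios and DIC; a simplified artificial-haplotype screen; a recessive
    double-homozygote depletion scan; the genome-scan filtering cascade
    (informative-offspring and heterozygous-parent pre-filters, deviation
    screen, epistatic-to-direct Bayes-factor ratio, coefficient-of-variation
    exclusion, per-category top-fraction selection and linked-SNP collapsing);
    and a seeded synthetic trio simulator with configurable distortion
    mechanisms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
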