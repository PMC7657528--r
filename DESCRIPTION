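Package: fcmsku
Title: Pathway Association Tests for Multiple Correlated Quantitative
    Phenotypes via Maximum Kernel U-Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide pathway (SNP-set) association testing for multiple
    correlated quantitative phenotypes.  For a single phenotype, a
    semi-supervised maximum kernel-based U-statistic (mSKU) test evaluates
    the joint, possibly nonlinear, effect of the SNPs in a pathway: candidate
    kernels (linear, Gaussian, polynomial) each yield a standardized
    degenerate U-statistic, and the maximum over kernels is referred to its
    asymptotic multivariate-normal null.  Marginal pathway p-values across
    phenotypes are then combined by a Fisher statistic whose null is
    moment-matched to a gamma distribution with a dependence adjustment for
    phenotype correlation (Brown's method with the Kost-McDermott
    covariance approximation).  Includes a synthetic-data generator for
    Hardy-Weinberg genotypes with linkage disequilibrium, covariates and
    exchangeably correlated phenotypes, a genome-wide runner over GMT
    pathway sets, PLINK and TSV readers, a simulation-study harness for
    type I error and power, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
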