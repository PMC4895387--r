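Package: methpart
Title: Bayesian Partition Model for Three-Way Differential Methylation Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies each CpG locus measured by bisulfite sequencing as
    equal-, hypo- or hyper-methylated between a case and a control condition
    in a single step, using a full Bayesian partition model: binomial read
    counts with conjugate (truncated, ordered) Beta priors on the methylation
    proportions, a Dirichlet-multinomial prior on the genome-wide three-group
    partition, and Metropolis-Hastings sampling over the latent membership
    vector. Includes the pooled two-proportion z-test and per-locus binomial
    logistic regression comparators with Storey q-value control, a synthetic
    data generator for binomial methylation counts with optional subject
    effects, mixed-directional FDR evaluation metrics, and readers for merged
    count tables and bismark-coverage-style files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
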