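Package: icprofiler
Title: Interphase Chromosome Profiling Simulation and Karyotype Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models multi-color interphase FISH probe panels used to karyotype
    products-of-conception specimens without cell culture. Provides the
    Standard Resolution panel (subtelomere and pericentromeric probes for
    every chromosome) and the Acrocentric panel (one pericentromeric mix for
    chromosomes 13, 14, 15, 21 and 22), a nucleus-level spot simulator with
    chromosome-territory placement and detection noise, single-linkage spot
    clustering into per-cell signal patterns, rule-based per-chromosome
    copy-number and juxtaposition calling with mosaicism thresholds, and
    genome-wide assembly of ploidy, sex complement, Robertsonian and
    reciprocal translocations, terminal deletions and maternal-cell
    admixture into an "icp." molecular karyotype string, which can also be
    parsed and classified. Packaged validation fixtures drive end-to-end
    round-trip checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
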