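Package: polyfp
Title: Polyploid SNP Fingerprinting from Endpoint Fluorescence and Amplicon Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fingerprinting polyploid (tetraploid) germplasm
    collections with biallelic SNP markers. Implements allele-dosage calling
    (0-4) from two-channel endpoint fluorescence of allele-specific PCR assays
    via a constrained five-component Gaussian mixture, marker quality
    statistics (call rate, Shannon-Wiener evenness of dosage classes,
    chip-style selection filters, chromosome coverage), robustness analysis
    across plate-layout analysis units with score combination, duplicate and
    identity analysis over dosage profiles (Chebyshev distances, pair
    classification, identical-profile clustering, marker-number
    combinatorics), and amplicon-haplotype discrimination statistics (read
    filtering, polymorphic-site and haplotype enumeration, haplotype-dosage
    assignment, marker-combination distinguishability, concordance with
    reference calls). A synthetic-data generator emulates plate-structured
    fluorescence with dosage clusters, dropout, injected duplicates and
    mislabels, and multinomial amplicon read counts, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
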