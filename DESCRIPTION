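Package: proteocna
Title: Copy-Number Aberration Analysis from Quantitative Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates SILAC ratio-of-ratios protein quantification with
    SNP-array derived gene copy numbers, detects chromosomal amplifications
    and deletions directly from per-gene protein log-ratios with a
    multi-scale sliding-window algorithm (one-sample t-tests transformed to
    posterior error probabilities and thresholded at a permutation-based
    false discovery rate), and tests annotation categories (GO, KEGG,
    CORUM, chromosomes) for coordinated shifts in the joint copy-number
    change by protein change space with a two-dimensional rank-based test.
    Ships a synthetic-data generator emulating aneuploid tumor genomes and
    dosage-attenuated proteomes so that the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
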