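Package: rgenseq
Title: Simulation and Cut-Site Detection for Amplification-Free CRISPR-Cas9
    Cleavage Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping CRISPR-Cas9 double-strand breaks from the
    read-end pileup signature left in amplification-free sequencing libraries
    (RGEN-seq). Includes a ground-truthed simulator of the library chemistry
    (single-turnover Hill-model cleavage, blunt cuts 3 bp upstream of the PAM,
    asymmetric end degradation, productive-fragment selection), strand-aware
    read 5'-end extraction from SAM/BAM, a window-score cleavage-site caller
    with guide/PAM mismatch matching, per-site quality diagnostics (coverage
    skewness, productive-read fraction, saturation and concentration-response
    curves), and tolerance-based comparison of site sets across replicates and
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    Rsamtools,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
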