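Package: permpanel
Title: Permutation-Based Panel Biomarker Discovery for Case/Control Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering multi-protein biomarker panels from
    label-free case/control plasma proteomics intensity data. Implements
    peptide-to-protein quantification (quantile normalization, log2
    transform, weighted rollup), per-protein two-sample permutation testing
    with per-family error rate (PFER) and nominal false discovery rate
    summaries, panel derivation against reference biomarker sets,
    pathway-protein association and frequency-count matrices, Fisher's
    exact pathway enrichment, and two cross-study biomarker-set similarity
    scores (Jaccard of protein sets and Pearson correlation of pathway
    count profiles). A synthetic-data module generates case/control studies
    with planted differential proteins and known ground truth for power and
    calibration analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
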