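Package: icptrend
Title: Multiparameter Intracranial Pressure Trend Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multiparameter analysis of intracranial pressure (ICP)
    monitoring trend data in neurocritical care. Computes hourly monitoring
    indices from 3-second trend recordings of ICP, mean arterial pressure and
    ICP pulse amplitude: mean ICP, cerebral perfusion pressure (CPP), the
    pressure reactivity index (PRx), the compensatory reserve index (RAP),
    the supra-threshold pressure-time dose (DICP) and the optimal cerebral
    perfusion pressure (CPPopt). Includes a physiologically structured
    synthetic-data generator for two-outcome patient cohorts, group-comparison
    statistics (pooled t, tie-corrected Mann-Whitney U, Pearson chi-square),
    and ROC-based prognosis evaluation with DeLong and Hanley-McNeil
    confidence intervals, plus CSV interchange and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
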