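Package: ethreadsim
Title: Cost and Time Planning for Meta-Threading Workloads on
    Heterogeneous Cloud Instances
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A discrete-event simulator and planner for executing the
    eThread protein meta-threading pipeline (ten threading/fold-recognition
    tools plus BLAST and PSIPRED prerequisites) on a heterogeneous pool of
    cloud virtual-machine instance types.  Builds the per-sequence,
    per-tool task graph of the pipeline, calibrates a sequence-length
    runtime model from benchmark profiles, schedules tasks under serial,
    per-tool static, longest-processing-time and deviation-triggered
    dynamic policies, and reports time-to-solution, billed
    cost-to-solution, core utilization and Pareto-optimal instance
    choices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
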