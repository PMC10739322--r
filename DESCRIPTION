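Package: axotrace
Title: Axonal Direction, Burst Dynamics, and Functional Connectivity from
    Compartmentalized Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for compartmentalized hippocampal cultures
    recorded on multi-electrode arrays with microfluidic tunnels. Infers
    single-axon identity and transmission direction in inter-regional
    tunnels from dual-electrode spike timing (normalized matching index,
    conduction-delay histograms, peak detection), quantifies spiking and
    bursting dynamics with log-log complementary cumulative distribution
    fits and log-normal fits, and builds directed well-to-axon functional
    connectivity graphs from sliding-window spike-rate regressions, with
    degree, centrality and effect-size balance summaries across
    stimulation conditions. A seeded synthetic-recording generator with
    planted ground truth makes every stage verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
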