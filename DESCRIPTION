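Package: meanet
Title: Network-Burst and Functional-Connectivity Analysis for Multielectrode-Array Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for analysing spontaneous bioelectrical activity recorded from
    cultured neuronal networks on multielectrode arrays (MEAs). Detects network
    bursts as windows containing a minimum number of spikes from distinct
    electrodes, classifies them into small and large events, and summarises the
    standard activity parameters (burst rate, spikes per burst, duration,
    amplitude, proportion of spikes in bursts). Builds directed functional-
    connectivity graphs from delay-synchronous spike counts evaluated over
    cumulative 1-50 ms windows, selects the strongest electrode pairs, and
    computes hub and diameter metrics. Includes a synthetic spike-train
    generator with planted connectivity and condition factors emulating
    control, amyloidosis, and chronically stimulated cultures, nonparametric
    group-comparison utilities, a relative qPCR expression helper, and an
    end-to-end reproducible analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
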