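Package: archsched
Title: Architecture-Aware Scheduling of Brute-Force Motif Search on
    Heterogeneous Compute Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions large data-parallel workloads across heterogeneous
    compute architectures (CPU clusters, GPUs, many-core coprocessors) using
    empirically profiled per-task execution times. Implements a
    throughput-proportional, architecture-aware scheduler that admits a
    resource into the hybrid pool only if it can finish a single task before
    the current hybrid pool finishes the whole job, together with the
    speed-based baseline scheduler it improves upon. Ships an exact
    brute-force solver for the planted (l,d) DNA motif-finding problem as the
    benchmark workload, chunked by candidate-index range so that portions of
    the 4^L search space can be dispatched independently, plus generators for
    planted-motif instances and simulated timing trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
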