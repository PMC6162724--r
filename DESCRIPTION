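Package: bcisearch
Title: Closed-Loop Neurofeedback Control of Weighted Heuristic Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A testable closed-loop system coupling a weighted-A* search
    engine to a simulated prefrontal-asymmetry neurofeedback signal. The
    search core implements A*, weighted A* with mid-search dynamic
    re-weighting of the evaluation function f = (1 - omega) * g + omega * h,
    and FOCAL (A*-epsilon) search, all with full per-expansion tracing and
    epsilon-admissibility accounting. Benchmark domains (8-puzzle with an
    exhaustive breadth-first-search oracle, occupancy-grid path planning
    with a Dijkstra oracle), a synthetic 8-channel fNIRS oxy-haemoglobin
    generator with trait/state asymmetry, haemodynamic onset delay and
    block-to-block fatigue, the asymmetry scoring and real-time testing
    chain (one-sided Welch t-test, Cohen's d, bootstrap validation), the
    linear effect-size-to-weight mapping, and a scripted experiment harness
    for speed-accuracy characterisation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
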