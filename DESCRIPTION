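Package: msddm
Title: Reward-Rate Optimality of the Speed-Accuracy Trade-Off in
    Multisensory Diffusion Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how decision makers tune their
    speed-accuracy trade-off in a multisensory (visual-vestibular) heading
    discrimination task. Implements a drift-diffusion model with
    time-varying drift, scaled per-condition decision bounds and
    end-of-stimulus forced choices; maximum-likelihood fitting of choice
    and reaction-time data; reward-rate computation and bound optimization
    by gradient ascent with random restarts; curvature (Hessian)
    diagnostics of incomplete gradient-based bound learning; exact
    Wilcoxon signed-rank tests and bootstrap confidence intervals; and a
    synthetic-subject generator, including prematurely stopped
    ("truncated") gradient-ascent learners, emulating the experiment's
    interleaved design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
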