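Package: hypoburden
Title: Intraoperative Hypotension Burden Metrics and Trial Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intraoperative hypotension burden from mean arterial
    pressure (MAP) time series (episode detection, time below threshold,
    area under threshold, time-weighted average), provides the nonparametric
    statistics used in small two-arm perioperative trials (Mann-Whitney U,
    Hodges-Lehmann median differences with confidence intervals, Spearman
    correlations, chi-square, Lilliefors-type normality testing), analyses
    pre/post surgery biomarker panels against hypotension burden, and
    simulates complete two-arm trials: permuted-block randomization,
    mean-reverting MAP trajectories with hypotensive events, an alert-gated
    proactive treatment policy versus reactive standard care, burden-coupled
    biomarker responses, and Monte-Carlo power estimation for binary
    hypotension incidence.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
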