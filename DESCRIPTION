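Package: promscan
Title: Promoter Motif Profiling with Exact PWM P-Value Calibration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans transcription-start-site anchored promoter windows with
    position weight matrices built from JASPAR-format count matrices, calibrates
    per-matrix score cutoffs to exact motif p-values by dynamic programming over
    the background score distribution, and turns the resulting hit tables into
    regulatory profiles: upstream/downstream binding-site counts at two
    stringency tiers, master-regulator and gene-specific transcription factor
    sets, proximal-window profiles, CArG-box matches and autoregulatory-site
    reports. Also provides RPKM/RPM expression summaries from read-count
    tables, directed regulatory-network topology metrics with configurable
    self-loop handling, and seeded synthetic-data generators (matrix libraries,
    promoters with planted motifs, count matrices) so every stage is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
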