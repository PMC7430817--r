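Package: sdrscan
Title: Sex-Determining Region Discovery from RAD-Seq Markers and Pooled
    Sequencing in XX/XY Populations with Sex Reversal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a sex-determining region (SDR) in species with
    male heterogamety (XX/XY) and environmental female-to-male sex reversal,
    modelled on the goldfish sex-locus workflow. Discovers Y-linked markers
    from per-individual RAD-tag presence/absence matrices, classifies
    phenotypic males into XY carriers and XX neomales, scans two-pool
    (male/female) nucleotide counts in popoolation 'sync' format for
    sex-specific SNP-dense windows, calls contiguous SDR intervals, and
    computes cross-level sex-linkage and sex-reversal statistics (Fisher's
    exact test, chi-square sex-ratio tests, Clopper-Pearson intervals). A
    seeded synthetic-data generator simulates an XX/XY population with a
    planted non-recombining Y-divergent region, RAD-tag dropout and a tunable
    neomale rate, so the whole pipeline is testable against known truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
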