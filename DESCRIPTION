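Package: shipimpact
Title: Ship Emission Scenarios, PM2.5 Health Burden and Aerosol Forcing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Activity-based marine ship emission inventories under fuel-sulphur
    policy scenarios, a steady-state lifetime surrogate for atmospheric
    dispersion of the emitted species, gridded premature-mortality and
    childhood-asthma burden via concentration-response functions, and direct
    plus first-indirect (Twomey) aerosol radiative forcing. A synthetic-world
    generator supplies lane-concentrated vessel traffic, coastal-biased
    population with country partitions, incidence tables and meteorology so
    the whole pipeline runs at desk scale without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    mgcv
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
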