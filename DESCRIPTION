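Package: pengkrill
Title: Penguin Foraging Effort and Krill Acoustic Availability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links chinstrap penguin foraging effort derived from biologging
    (GPS foraging trips, time-depth-recorder dive phases and wiggle-based
    capture effort) to Antarctic krill acoustic availability (echo-integrated
    NASC densities, swarm depth selection and depth-stratified Ripley's K
    aggregation) and to local environmental conditions, and contrasts two
    breeding seasons with a from-scratch one-way PERMANOVA. A synthetic-data
    generator emulates central-place foraging tracks, dive profiles with
    wiggles, clustered krill swarm fields, gridded environmental variables and
    breeding counts under named season scenarios, so every stage of the
    pipeline is verifiable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
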