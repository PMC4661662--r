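Package: catchaccess
Title: Variable-Catchment Floating Catchment Area Accessibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures spatial accessibility of populations to
    capacity-limited facilities (hospital beds, residential care places)
    with floating catchment area (FCA) methods.  Implements an enhanced
    variable two-step FCA (EV2SFCA) in which each facility catchment
    grows on a travel-time grid until the facility-to-population ratio
    falls to a threshold, each population catchment grows until the
    summed facility ratios reach a target provision level, and the final
    accessibility scores admit only facility-population pairs whose
    catchments mutually contain each other.  A variable 2SFCA (V2SFCA)
    baseline, Gaussian and stepwise distance-decay weights, a
    shortest-path travel-time builder for classed road networks, a
    seeded synthetic monocentric city generator, and a command-line
    interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
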