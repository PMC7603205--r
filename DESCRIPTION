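Package: rotoscreen
Title: Combinatorial Design Theory for Rotary Droplet Drug-Combination Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact combinatorics, scheduling and synergy-search simulation for
    rotary microfluidic drug-combination dispensers. Computes the number of
    droplet combinations with and without dilution-redundancy reduction,
    reconstructs the full configuration/screen-time design table for a
    48-drug, 4-dilution instrument, enumerates well-level combinations as a
    brute-force oracle for the closed forms, plans and replays dispensing
    schedules (rotor positions and shuttle passes), and simulates staged
    ring-by-ring synergy searches on synthetic Hill-curve dose-response
    surfaces scored against Bliss independence or Loewe additivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
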