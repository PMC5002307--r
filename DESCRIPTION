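Package: vpcsim
Title: Simulation of Visual Place Cell Generation from Landmark Perception
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the generation of visual place cells (VPCs) in an
    agent exploring a rectangular arena populated with point landmarks.
    At each location-update step the agent perceives the landmarks inside
    a recognition-distance annulus as a place code (identity, saliency,
    bearing from north, distance), evaluates every recruited cell's firing
    rate with a saliency-weighted Gaussian similarity measure over matched
    landmarks, and recruits a new cell whenever the winning rate falls
    below a firing-rate threshold. Includes a random-walk agent with
    specular boundary reflection, rate-map rasterization of firing fields,
    a parameter-sweep harness with replicate trend checks, and a
    command-line interface with reproducible output bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
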