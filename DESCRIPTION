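Package: finsong
Title: Fin Whale Singing and Swimming Behaviour Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles fin whale 20 Hz note detections into songs and singing
    bouts using a biexponential bout-ending criterion estimated from the
    inter-song-interval distribution, derives track-segment swimming speeds and
    trailing 30-minute singing duty-cycles from acoustic localizations,
    classifies slow/fast behavioural regimes, and models the amount of singing
    (duty-cycle and song duration) against swimming speed and season with
    generalized additive models. Ships a synthetic singer simulator with a
    two-state semi-Markov behaviour model and an optional hydrophone-array
    time-difference-of-arrival observation model, so the whole pipeline can be
    exercised and validated without access to restricted acoustic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    graphics,
    grDevices,
    jsonlite,
    mgcv,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
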