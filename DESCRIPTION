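Package: texmod
Title: Modelling Edge- and Region-Based Texture Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how modulated Gabor-micropattern textures are
    detected and discriminated. Synthesizes textures whose orientation,
    contrast, luminance, or orientation/contrast variance is modulated by
    sine, square, or cusp waveforms; simulates two-interval forced-choice
    adaptive staircases against synthetic observers with Weibull psychometric
    functions; and fits a single difference-of-Gaussians (DoG) spatial filter
    simultaneously to sensitivity triplets to estimate the spatial frequency
    at peak filter amplitude and the implied perceptual receptive-field size.
    Includes a synthetic threshold-data generator so the whole analysis
    pipeline can be exercised and validated without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
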