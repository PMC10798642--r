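Package: membranexds
Title: Membrane Bending Moduli from X-Ray Diffuse Scattering of Oriented
    Lipid Multilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for X-ray diffuse scattering from solid-supported
    stacks of lipid bilayers. Reduces 2-D detector images (TIFF) to q-space
    maps, meridional reflectivity profiles and in-plane line cuts, computes
    the Caille smectic structure factor of a finite, thermally fluctuating
    membrane stack (height-height correlation functions, finite-domain-size
    weights, Hankel-transform radial integration, beam convolution), and fits
    line cuts simultaneously to estimate the Caille parameters eta and xi and
    hence the membrane bending modulus kappa and inter-membrane compression
    modulus B. Includes a synthetic-data generator that produces detector
    images and line cuts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
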