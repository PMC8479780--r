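Package: photokin
Title: Spectro-Kinetic Analysis of Bilin Chromophore Assembly and Primary Photochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-resolved optical absorption data of
    bilin-binding photoreceptor proteins (cyanobacteriochromes and
    phytochromes). Provides a synthetic-data generator with known ground
    truth for in vitro chromophore-assembly time series, photostationary
    mixture spectra and picosecond pump-probe matrices; a variable-projection
    global multiexponential fitter returning decay-associated (difference)
    spectra and a non-decaying component; a mechanistic two-step assembly
    model (second-order chromophore uptake followed by first-order covalent
    attachment) with ODE simulation and fitting; iterative decomposition of
    photostationary spectra into dark-state and photoproduct contributions;
    and ground-state-bleach-based estimation of photochemical quantum yields
    with an overlap diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    pracma,
    stats,
    graphics,
    grDevices,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
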