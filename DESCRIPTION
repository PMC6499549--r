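Package: espraydiff
Title: Flash X-Ray Diffraction Analysis for Electrospray-Injected Particles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing single-particle flash X-ray imaging
    experiments with electrosprayed aerosol samples: beam and pnCCD detector
    geometry with reciprocal-space maps, aerosolization arithmetic and a
    Poissonian droplet-occupancy model with cluster-diameter scaling,
    a synthetic diffraction-frame generator (uniform spheres and icosahedra
    with photon noise and detector artifacts), detector preprocessing with
    common-mode correction and lit-pixel hit finding, particle sizing by
    uniform-sphere form-factor fitting, and 2D image reconstruction by
    iterative phase retrieval (HIO/RAAR/ER) validated with phase retrieval
    transfer functions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
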