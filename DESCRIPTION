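Package: barmem
Title: Electrostatics and Curvature Energetics of BAR-Domain Membrane Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models the physics of rod-like, crescent-shaped membrane-binding
    proteins (BAR domains) near charged lipid bilayers. Implements the
    Langevin-Bikerman mean-field theory of the electric double layer, in which
    finite-size ions and orientational ordering of water dipoles give a field-
    and potential-dependent relative permittivity, solved self-consistently in
    planar geometry and around the charged concave arc of a BAR domain in two
    dimensions. Also provides the orientation-dependent bending energetics of
    anisotropic rod-like membrane inclusions (rigid and flexible limits),
    Helfrich bilayer energies with a deviatoric ordering term, membrane-tube
    equilibrium radii, and stylised protein packing scenarios on tubes.
    Results are tibbles or light S3 objects with broom-style tidy() and
    glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
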