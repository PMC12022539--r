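Package: pavotrain
Title: Generative Simulation of the Peacock's Train Eyespot Pattern
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the developmental layout of peafowl train feathers as a
    zigzag lattice of follicle insertion points on the uropygial anchor plate,
    expands the lattice bilaterally into the fan-shaped display, and quantifies
    the resulting point pattern (hexagonal packing via Delaunay neighbour
    degrees, nearest-neighbour spacing uniformity, mirror-symmetry error,
    radial-line counts). Includes an age-accretion model of annual feather-row
    addition with asymptotic train growth, a palindromic follicle-type model of
    the eyespot's concentric colour rings, and a seeded generator of synthetic
    museum-specimen records for testing against published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deldir,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
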