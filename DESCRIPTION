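Package: esphole
Title: Detection and Quantification of Metal-Centered Pi-Holes on
    Electrostatic Potential Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building combinatorial libraries of transition-metal
    tetraazamacrocycle (cyclen) complexes and for locating, validating and
    quantifying pi-holes -- regions of locally enhanced electrostatic
    potential perpendicular to the N4 coordination plane -- on volumetric
    electrostatic potential (ESP) grids.  Includes readers and writers for
    XYZ geometries and Gaussian cube volumetric files, a conformer and
    N-substitution enumerator with steric-clash resolution and RMSD
    deduplication, least-squares N4-plane frame alignment, the tau4
    four-coordinate geometry index, trilinear grid interpolation,
    isodensity-surface extraction, synthetic Coulomb/Gaussian field
    generators for end-to-end testing, an axial cylinder search for pi-hole
    candidates, eight-sector azimuthal background validation with the
    relative descriptors V_hole_mean, V_hole_max, V_hole_min, dV_hole and
    dV_angle, and batch pipeline commands with CSV reporting and
    grid-sensitivity comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
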