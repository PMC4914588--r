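Package: endoperm
Title: Endothelial Mechanotransduction and Permeability Mapping on Vascular Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes time-resolved wall shear stress and pressure fields
    on triangulated vessel surfaces into compound shear indices (TAWSS, OSI,
    HOLMES, RRT), wall rheology under a Carreau-Yasuda shear-thinning model,
    and a three-pore endothelial permeability cascade (endothelial cell shape
    index, mitotic and leaky cell fractions, leaky-junction hydraulic
    conductivity, Kedem-Katchalsky volume and solute fluxes). Thresholded
    permeability maps are scored against reference calcification masks with
    region-level percent-area and percent-match statistics. Includes a seeded
    synthetic-data generator for pulsatile wall fields with engineered shear
    environments and matching ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
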