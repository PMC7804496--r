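Package: radialcontrast
Title: Radially Generalized Contrast Energy and Predictions of Visual Crowding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a radially generalized contrast-energy semi-norm
    based on difference-of-Gaussians (center-surround) receptive fields
    whose size scales with retinal eccentricity, together with a
    single-parameter psychometric mapping from contrast energy to
    proportion of correct target identifications.  Ships deterministic
    rasterizers for four classic crowding stimulus families (flanked
    letters, Landolt C with flanking bars, verniers with flanking lines,
    and Landolt C with concentric flankers) and experiment runners that
    regenerate the flanker-distance, flanker-count and eccentricity
    dependence of crowding predicted by contrast energy alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods
Imports: stats, tools, png, tiff, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'viewgeom.R'
    'dogfield.R'
    'psychmap.R'
    'stimgen.R'
    'io.R'
    'radialcontrast-package.R'
    'runner.R'
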