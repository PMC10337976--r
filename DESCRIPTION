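Package: cortexstack
Title: Cortical Flatmap-Stack Mapping and Mesoscale Tracer Image Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for post-processing serial two-photon tomography (STPT)
    brain image data at the mesoscale: microscope tile shading correction and
    section stitching, fluorescence injection-site localization, anterograde
    tracer density and normalized-intensity mapping, retrograde cell density
    rasterization and laminar labeling, and a 3D "flatmap stack" coordinate
    system that extends cortical flatmaps with a relative-depth axis via
    heat-propagated direction fields and through-cortex trajectories.
    Includes symmetric spherical gradient-direction design for HARDI
    averaging, spherical signal interpolation, streamline selection and
    track-density imaging, and validation statistics (normalized
    cross-correlation, Dice overlap, permutation tests, landmark
    displacement, mapping isotropy). All stages can be exercised on
    synthetic phantoms with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
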