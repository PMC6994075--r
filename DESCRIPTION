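Package: wormetrics
Title: Length, Volume and Surface Area of Nematodes from Single-Worm Micrographs
Version: 0.1.0
Authors@R:
    person("Wormetrics", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures the length, volume and surface area of a nematode
    (e.g. Caenorhabditis elegans) from a calibrated single-worm micrograph.
    The image is binarized and cleaned, skeletonized to a one-pixel "spine
    line", traced end to end with moving perpendicular profile lines,
    extended to the worm's true tips using the one-pixel outline, and the
    diameter is measured normal to the midline at every spine point.  The
    worm body is then modelled as a chain of truncated cones (frusta) whose
    summed volumes and lateral areas give the worm's volume and surface
    area; midline curvature and a straightened silhouette are also
    available.  A synthetic-worm generator renders binary tubes around
    parametric centerlines with analytic length, volume, surface area and
    curvature, providing exact ground truth for validation, plus a batch
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    jpeg,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
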