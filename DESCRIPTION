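Package: crownpheno
Title: Root Crown Phenotyping from Backlit Silhouette Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Batch analysis engine for root crown phenotyping from backlit
    silhouette images. Converts grayscale images of excavated root crowns
    (dark roots on a bright background) into 27 quantitative phenes per
    image: root counts from horizontal line scans, tip counts, total root
    length, spatial extent, network and convex areas, solidity, perimeter,
    diameter statistics from an exact Euclidean distance transform along a
    ridge-based medial axis, volume and surface area, hole statistics, and
    root orientation summaries from windowed principal components. Includes
    contour extraction with Ramer-Douglas-Peucker edge smoothing, skeleton
    topology reconstruction into root segments, a synthetic silhouette
    generator with exact ground truth for validation, a batch driver that
    writes feature and metadata CSV files, and rendering of segmented and
    feature-overlay images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    grDevices,
    stats,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jpeg,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
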