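Package: dearrayr
Title: Tissue Microarray De-Arraying from Digital Slide Thumbnails
Version: 0.1.0
Authors@R:
    person("TMA", "Tools", email = "tma.tools@example.org", role = c("aut", "cre"))
Description: Segments tissue microarray (TMA) cores from whole-slide thumbnail
    images, assigns each core its logical (row, column) grid index with a
    Delaunay-triangulation traveling algorithm that is robust to missing cores,
    grid rotation and non-linear stretching, and maps indices to core names
    recorded in a TMAMap spreadsheet. Includes a pseudo-slide simulator that
    generates binary TMA thumbnails with configurable missing cores, rigid
    rotation and cosine-model stretching together with ground-truth grid
    indices, used as the package's test and benchmark fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    jpeg,
    optparse,
    png,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
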