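Package: sellingr
Title: Selling Reduction and Lattice Distances in the S6 Cone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing and clustering crystallographic unit cells in
    the six-dimensional space S6 of Selling scalars (the pairwise dot products
    of the Bravais tetrahedron vectors) and its complex form C3. Implements
    Selling (Delone) reduction via the twelve edge transforms, the 24-element
    reflection group relating equivalent presentations of a reduced lattice,
    minimal-distance algorithms based on virtual Cartesian points and tunneled
    mirrored boundaries, a Follower validation scan for distance metrics, and
    agglomerative clustering of unit cells for serial-crystallography-style
    data sets, together with a synthetic cell generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
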