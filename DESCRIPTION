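Package: VoronoiClassMap
Title: Voronoi Tessellation Class Maps and Island Discordance Metrics
    for 2-D Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Visualizes two-dimensional data projections as class-colored
    Voronoi tessellations ("political maps"), complementing or replacing
    group confidence ellipses.  Computes the bounded Voronoi tessellation
    of a projection plane, its Delaunay-dual neighbor graph, and a
    visualization-intrinsic discordance metric, the Voronoi island count:
    the number of points whose every tessellation neighbor belongs to a
    different class.  Also provides bivariate normal confidence ellipses,
    minimal PCA and PLS-DA score projections, k-means and single-linkage
    clustering helpers, and seeded synthetic benchmark generators for
    two-class, three-class, label-permuted, and Lsun-style datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
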