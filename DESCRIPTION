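Package: mejpattern
Title: Spatial Pattern Analysis of Myoendothelial Junctions in En Face
    Endothelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the spatial organization of holes in the
    internal elastic lamina (HIEL) and the myoendothelial junctions (MEJs)
    they host, from en face preparations of resistance arteries. Provides a
    synthetic en face field generator with known ground truth (Voronoi cell
    tessellation, hub masks, HIEL and marker puncta), raster ingestion with
    thresholding and particle extraction, Monte Carlo positive/negative/random
    placement envelopes, an exact minimum-distance statistic with robust
    outlier removal and Welch/Brown-Forsythe testing to classify spatial
    patterns, marker-to-MEJ colocalization statistics, a stereology predictor
    linking en face HIEL density to transverse-section counts, and
    pressure-myography vasoreactivity formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    png,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
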