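Package: microcatch
Title: Network Catchment Areas and Gridded-Population Microplanning for
    Health Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds transport-network service areas (catchments) around
    health facilities, overlays them with age/sex-stratified gridded
    population rasters, quantifies covered and underserved populations,
    and produces microplan summary tables and campaign resource
    estimates. Includes a seeded synthetic-data generator (settlement-
    clustered population grids, connected walking networks, facilities,
    case points) so the whole pipeline can be exercised offline, plus
    readers and writers for node/edge CSV networks, Esri ASCII grid
    rasters and GeoJSON point/polygon files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
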