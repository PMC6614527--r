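Package: ecrhubs
Title: Travel-Time Catchments, Coverage and Caseload for Endovascular
    Clot Retrieval Hub Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for siting endovascular clot retrieval (ECR) hubs in a
    metropolitan area. Assigns population units (suburbs) to candidate hub
    hospitals by minimum peak-hour travel time, scores every hub combination
    by the share of each catchment reachable within a time threshold
    (default 30 minutes), projects annual stroke counts from age-banded
    populations and age-specific incidence rates, and derives the expected
    ECR caseload per hub. Includes a deterministic synthetic-city generator
    (centroids, age-banded populations, hub sites, peak-hour travel-time
    matrices) so the full pipeline runs and is testable offline, plus CSV
    and GeoJSON writers for coverage tables, ranked hub models and
    catchment maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
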