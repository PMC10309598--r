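Package: pescarchive
Title: Decadal Marine Biodiversity and Trophic Indicators from Historical Newspaper Archives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning taxon mentions extracted from historical
    newspaper archives into decadal biodiversity and trophic indicators for
    marine historical ecology. Resolves vernacular (folk) animal names
    against a taxon dictionary with genus- and family-level trophic-level
    fallback, applies item inclusion rules and presence-capped occurrence
    counting, aggregates occurrences into decade-by-taxon tables, and
    computes weighted average trophic level (WATL), piscivore/planktivore
    and invertebrate/fish ratios, gear summaries, and the correlation and
    percent-change statistics used to relate these indicators to archive
    size, time, and fishery landings. A seeded synthetic-corpus generator
    with a closed-form expected WATL supports parameter-recovery and
    sampling-bias studies without any archive access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
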