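# Hand-built registry exercising the folk-taxonomy cases: one folk name for
# several taxa ("raia prego"), several folk names for one species (mullet),
# excluded groups, and a missing trophic level.
fixture_registry <- function() {
  taxon_registry(tibble::tibble(
    vernacular_name = c("raia prego", "raia prego", "raia prego", "raia prego",
                        "tainha", "tainhota", "tanhota",
                        "anchova", "sardinha", "garoupa", "badejo",
                        "camarão", "ostra", "ouriço",
                        "baleia", "tartaruga", "traíra", "tilápia"),
    scientific_name = c("Hypanus sp.", "Dasyatis sp.", "Fontitrygon sp.",
                        "Bathytoshia sp.",
                        "Mugil liza", "Mugil liza", "Mugil liza",
                        "Pomatomus saltatrix", "Clupeidae",
                        "Epinephelus marginatus", "Mycteroperca sp.",
                        "Penaeidae", "Crassostrea rhizophorae",
                        "Echinometra lucunter",
                        "Mysticeti", "Chelonioidea", "Hoplias malabaricus",
                        "Oreochromis niloticus"),
    taxonomic_level = c("genus", "genus", "genus", "genus",
                        "species", "species", "species",
                        "species", "family", "species", "genus",
                        "family", "species", "species",
                        "order", "order", "species", "species"),
    group = c(rep("native_marine_fish", 11),
              "crustacean", "mollusc", "echinoderm",
              "sea_mammal", "reptile", "freshwater", "non_native"),
    habitat = c(rep("marine", 4), rep("estuarine", 3), "marine", "marine",
                "marine", "marine", "marine", "estuarine", "marine",
                "marine", "marine", "freshwater", "freshwater"),
    native_status = c(rep("native", 17), "non_native"),
    trophic_level = c(3.5, 3.6, 3.5, 3.8,
                      2.5, 2.5, 2.5,
                      4.5, 2.8, 4.0, NA,
                      2.7, 2.0, 2.2,
                      3.6, 2.8, 3.8, 2.2),
    trophic_guild = c(rep("other", 4),
                      "planktivore", "planktivore", "planktivore",
                      "piscivore", "planktivore", "piscivore", "piscivore",
                      rep("other", 3),
                      rep("unknown", 4))
  ))
}

fixture_item <- function(item_id = "a1", year = 1885, mentions = "tainha",
                         gear = "", newspaper = "O Dia",
                         keyword_source = "pesca", is_duplicate = FALSE,
                         is_advertisement = FALSE, scope_marine = TRUE,
                         has_animal_report = TRUE) {
  tibble::tibble(
    item_id = item_id, newspaper = newspaper, year = year,
    municipality = "Florianopolis", keyword_source = keyword_source,
    is_duplicate = is_duplicate, is_advertisement = is_advertisement,
    scope_marine = scope_marine, has_animal_report = has_animal_report,
    mentions = mentions, gear_mentions = gear
  )
}

fixture_items <- function(...) {
  news_items(dplyr::bind_rows(...))
}

# Brute-force double-loop recount of the decade x key occurrence table,
# independent of the vectorized implementation.
brute_decadal_counts <- function(items, type = "taxon") {
  rows <- list()
  for (i in seq_len(nrow(items))) {
    field <- if (type == "taxon") items$mentions[i] else items$gear_mentions[i]
    raw <- strsplit(field, "|", fixed = TRUE)[[1]]
    raw <- trimws(raw)
    raw <- raw[nzchar(raw)]
    keys <- unique(normalize_name(raw))
    for (k in keys) {
      lab <- paste(items$decade[i], k, sep = "\r")
      rows[[lab]] <- (rows[[lab]] %||% 0L) + 1L
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(decade = integer(0), key = character(0),
                          count = integer(0)))
  }
  parts <- strsplit(names(rows), "\r", fixed = TRUE)
  tibble::tibble(
    decade = as.integer(vapply(parts, `[`, character(1), 1)),
    key = vapply(parts, `[`, character(1), 2),
    count = as.integer(unlist(rows))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sort a counts tibble into a canonical order for comparison
sorted_counts <- function(tbl) {
  tbl <- tbl[order(tbl$decade, tbl$key), c("decade", "key", "count")]
  rownames(tbl) <- NULL
  tibble::as_tibble(tbl)
}

# Registry + corpus engineered so that per-group mention totals and
# vernacular/scientific richness reproduce a prescribed group breakdown:
# group g gets v distinct vernacular names mapped onto s scientific taxa
# (the first s vernaculars one-to-one, the rest reusing the last taxon),
# and n single-mention items spread round-robin over its vernaculars.
engineered_corpus <- function(breakdown, years = 1900) {
  stopifnot(all(c("group", "v", "s", "n") %in% names(breakdown)))
  dict <- list(); items <- list()
  guild_for <- function(group) if (group == "native_marine_fish") "other" else "unknown"
  for (gi in seq_len(nrow(breakdown))) {
    g <- breakdown$group[gi]; v <- breakdown$v[gi]; s <- breakdown$s[gi]
    n <- breakdown$n[gi]
    stopifnot(v >= s, s >= 1)
    vn <- sprintf("%s folk %03d", gsub("_", " ", g), seq_len(v))
    sci <- sprintf("Taxon_%s_%03d", g, pmin(seq_len(v), s))
    dict[[gi]] <- tibble::tibble(
      vernacular_name = vn, scientific_name = sci,
      taxonomic_level = "species", group = g,
      habitat = if (g == "freshwater") "freshwater" else "marine",
      native_status = if (g == "non_native") "non_native" else "native",
      trophic_level = 3.0, trophic_guild = guild_for(g)
    )
    items[[gi]] <- fixture_item(
      item_id = sprintf("%s_%05d", g, seq_len(n)),
      year = years,
      mentions = vn[(seq_len(n) - 1) %% v + 1]
    )
  }
  list(registry = taxon_registry(dplyr::bind_rows(dict)),
       items = fixture_items(dplyr::bind_rows(items)))
}

# The per-group breakdown reported for the 1840-2019 newspaper corpus:
# abundance n, vernacular richness v, scientific richness s.
reported_breakdown <- function() {
  tibble::tribble(
    ~group,               ~v,  ~s,  ~n,
    "native_marine_fish", 192, 143, 1041,
    "crustacean",          17,   9,  181,
    "freshwater",          22,  15,  111,
    "mollusc",             11,   9,   99,
    "sea_mammal",           9,   7,   81,
    "echinoderm",           2,   2,    2,
    "reptile",              1,   1,    7,
    "bird",                 1,   1,    1,
    "non_native",          22,  16,  132
  )
}
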