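#' Default synthetic taxon pool
#'
#' A pool of folk taxa modelled on a southern-Brazil coastal fishery:
#' native marine fish spanning trophic levels from detritivorous mullet
#' (~2.5) to piscivorous sharks (~4.3), shrimp/crab crustaceans, oyster/
#' mussel/squid molluscs, one echinoderm, plus the categories every
#' indicator must exclude (a whale, a turtle, a seabird, freshwater and
#' non-native fish). Several taxa carry multiple vernacular variants, and
#' one folk name ("raia") maps to two ray genera, so name resolution and
#' the presence cap are exercised by default.
#'
#' @return tibble with one row per (vernacular variants, scientific taxon):
#'   columns `vernacular` ("|"-separated variants), `scientific_name`,
#'   `taxonomic_level`, `group`, `habitat`, `native_status`,
#'   `trophic_level`, `trophic_guild`, `base_weight`.
#' @export
default_taxon_pool <- function() {
  tibble::tribble(
    ~vernacular,                 ~scientific_name,          ~taxonomic_level, ~group,               ~habitat,     ~native_status, ~trophic_level, ~trophic_guild, ~base_weight,
    "tainha|tainhota|tanhota",   "Mugil liza",              "species",        "native_marine_fish", "estuarine",  "native",       2.5,            "planktivore",  3.0,
    "parati",                    "Mugil curema",            "species",        "native_marine_fish", "estuarine",  "native",       2.4,            "planktivore",  1.2,
    "anchova",                   "Pomatomus saltatrix",     "species",        "native_marine_fish", "marine",     "native",       4.5,            "piscivore",    1.5,
    "garoupa",                   "Epinephelus marginatus",  "species",        "native_marine_fish", "marine",     "native",       4.0,            "piscivore",    1.0,
    "robalo",                    "Centropomus parallelus",  "species",        "native_marine_fish", "estuarine",  "native",       4.0,            "piscivore",    1.0,
    "corvina",                   "Micropogonias furnieri",  "species",        "native_marine_fish", "estuarine",  "native",       3.5,            "other",        1.5,
    "pescada",                   "Sciaenidae",              "family",         "native_marine_fish", "marine",     "native",       3.7,            "piscivore",    1.0,
    "sardinha",                  "Clupeidae",               "family",         "native_marine_fish", "marine",     "native",       2.8,            "planktivore",  1.5,
    "bagre",                     "Ariidae",                 "family",         "native_marine_fish", "estuarine",  "native",       3.4,            "other",        1.2,
    "cacao|tubarao",             "Elasmobranchii",          "order",          "native_marine_fish", "marine",     "native",       4.3,            "piscivore",    1.2,
    "raia",                      "Hypanus sp.",             "genus",          "native_marine_fish", "marine",     "native",       3.5,            "other",        0.5,
    "raia",                      "Dasyatis sp.",            "genus",          "native_marine_fish", "marine",     "native",       3.6,            "other",        0.5,
    "carapeba",                  "Eucinostomus sp.",        "genus",          "native_marine_fish", "estuarine",  "native",       2.9,            "planktivore",  0.8,
    "camarao|camarao sete barbas", "Penaeidae",             "family",         "crustacean",         "marine",     "native",       2.7,            "other",        2.0,
    "siri",                      "Callinectes sp.",         "genus",          "crustacean",         "estuarine",  "native",       2.6,            "other",        0.8,
    "ostra",                     "Crassostrea rhizophorae", "species",        "mollusc",            "estuarine",  "native",       2.0,            "other",        0.8,
    "marisco",                   "Perna perna",             "species",        "mollusc",            "marine",     "native",       2.1,            "other",        0.6,
    "lula",                      "Loliginidae",             "family",         "mollusc",            "marine",     "native",       3.2,            "other",        0.5,
    "ourico",                    "Echinometra lucunter",    "species",        "echinoderm",         "marine",     "native",       2.2,            "other",        0.2,
    "baleia",                    "Mysticeti",               "order",          "sea_mammal",         "marine",     "native",       3.6,            "unknown",      0.8,
    "tartaruga",                 "Chelonioidea",            "order",          "reptile",            "marine",     "native",       2.8,            "unknown",      0.2,
    "gaivota",                   "Laridae",                 "family",         "bird",               "marine",     "native",       3.9,            "unknown",      0.1,
    "traira",                    "Hoplias malabaricus",     "species",        "freshwater",         "freshwater", "native",       3.8,            "unknown",      0.5,
    "tilapia",                   "Oreochromis niloticus",   "species",        "non_native",         "freshwater", "non_native",   2.2,            "unknown",      0.6,
    "bacalhau",                  "Gadus morhua",            "species",        "non_native",         "marine",     "non_native",   4.1,            "unknown",      0.6
  )
}

#' Configuration for the synthetic-corpus generator
#'
#' The defaults emulate the structure of a 180-year regional newspaper
#' archive: 18 calendar decades (1840s through 2010s), a newspaper count
#' that grows roughly 20% per decade (digitised historical archives hold
#' far more recent than early titles), about one relevant item per two
#' newspapers, and around 2.8 taxon mentions per item. The trophic-decline
#' effect `delta` tilts taxon sampling against high trophic levels as time
#' advances (see [generate_corpus()]); its default of 1 produces an
#' expected WATL decline of roughly half a trophic level across the
#' series, the magnitude reported for long-term fishing-down signals.
#'
#' @param decades integer decade labels.
#' @param newspapers_per_decade newspapers available per decade.
#' @param items_per_decade items generated per decade (exact, not
#'   stochastic); default half the newspaper count, so corpus size tracks
#'   archive size.
#' @param taxon_pool pool table, see [default_taxon_pool()].
#' @param mention_rate expected number of distinct taxa mentioned per item.
#' @param trophic_decline_effect `delta >= 0`; log-weight of taxon i in
#'   standardized decade t is shifted by `-delta * TL_i * t`. `delta = 0`
#'   gives a sampling law exchangeable through time.
#' @param duplicate_rate,advertisement_rate probabilities that an item is
#'   a planted duplicate of an earlier item in its decade, or is flagged
#'   as an advertisement; both exercise the inclusion filter.
#' @param repeat_mention_rate probability that a mentioned taxon's raw
#'   string is repeated in the same item (with different capitalisation),
#'   exercising normalization and the presence cap without changing counts.
#' @param seed master integer seed; per-decade substreams are derived by a
#'   stable hash so adding decades never perturbs earlier ones.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(decades = seq(1840, 2010, by = 10),
                             newspapers_per_decade = round(8 * 1.2^(seq_along(decades) - 1)),
                             items_per_decade = pmax(1L, round(newspapers_per_decade / 2)),
                             taxon_pool = default_taxon_pool(),
                             mention_rate = 2.8,
                             trophic_decline_effect = 1,
                             duplicate_rate = 0.05,
                             advertisement_rate = 0.05,
                             repeat_mention_rate = 0.1,
                             seed = 1L) {
  if (nrow(taxon_pool) == 0) {
    rlang::abort("taxon_pool must not be empty", class = "pesc_invalid_config")
  }
  probs <- c(duplicate_rate, advertisement_rate, repeat_mention_rate)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("rates must be probabilities in [0, 1]",
                 class = "pesc_invalid_config")
  }
  stopifnot(length(newspapers_per_decade) == length(decades),
            length(items_per_decade) == length(decades),
            mention_rate > 0, trophic_decline_effect >= 0)
  structure(list(
    decades = as.integer(decades),
    newspapers_per_decade = as.integer(newspapers_per_decade),
    items_per_decade = as.integer(items_per_decade),
    taxon_pool = taxon_pool,
    mention_rate = mention_rate,
    trophic_decline_effect = trophic_decline_effect,
    duplicate_rate = duplicate_rate,
    advertisement_rate = advertisement_rate,
    repeat_mention_rate = repeat_mention_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# standardized decade index in [0, 1]
.decade_t <- function(config) {
  d <- length(config$decades)
  if (d == 1) 0 else (seq_len(d) - 1) / (d - 1)
}

# taxon sampling weights w_i(t) = base_weight_i * exp(-delta * TL_i * t);
# taxa with unknown TL use the pool mean so they stay trend-neutral
.sampling_weights <- function(config, t) {
  tl <- config$taxon_pool$trophic_level
  tl[is.na(tl)] <- mean(tl, na.rm = TRUE)
  config$taxon_pool$base_weight *
    exp(-config$trophic_decline_effect * tl * t)
}

# per-item inclusion probability of each taxon in standardized decade t:
# p_i(t) = mention_rate * w_i / sum(w), capped below 1
.inclusion_probs <- function(config, t) {
  w <- .sampling_weights(config, t)
  pmin(config$mention_rate * w / sum(w), 0.98)
}

#' Expected WATL under the generating law
#'
#' Closed-form expectation of the weighted average trophic level the
#' pipeline recovers from a synthetic corpus: with items including taxon i
#' independently with probability proportional to `w_i(t) = base_weight_i *
#' exp(-delta * TL_i * t)`, the expected occurrence of i is proportional to
#' `w_i(t)`, so over the WATL-eligible set (native marine fish with known
#' TL) the expectation is `sum(TL_i w_i(t)) / sum(w_i(t))`. This analytic
#' form is the oracle for parameter-recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param decade decade label present in `config$decades`.
#' @return expected WATL (numeric scalar).
#' @export
expected_watl <- function(config, decade) {
  stopifnot(inherits(config, "synthetic_config"))
  idx <- match(decade, config$decades)
  if (is.na(idx)) {
    rlang::abort("decade not in config", class = "pesc_invalid_config")
  }
  t <- .decade_t(config)[idx]
  pool <- config$taxon_pool
  elig <- pool$group == "native_marine_fish" & !is.na(pool$trophic_level)
  w <- .sampling_weights(config, t)[elig]
  tl <- pool$trophic_level[elig]
  sum(tl * w) / sum(w)
}

#' Generate a seeded synthetic newspaper corpus
#'
#' Produces an item table, the matching taxon registry, and a truth record,
#' deterministically from the config seed. Per decade, exactly
#' `items_per_decade` items are generated; each item independently includes
#' taxon i with probability `mention_rate * w_i(t) / sum(w)`, where the
#' weights tilt against high trophic levels at rate
#' `trophic_decline_effect` as the standardized decade index t runs from 0
#' to 1 (a softmax-style law chosen so [expected_watl()] has a closed
#' form). Mentioned taxa appear under a randomly chosen vernacular
#' variant; planted duplicates and advertisements exercise the inclusion
#' filter; occasional repeated mention strings with different
#' capitalisation exercise normalization and the presence cap.
#'
#' @param config a [synthetic_config()].
#' @return list with `items` (a [news_items()] table), `registry` (a
#'   [taxon_registry()]), and `truth` (generating `delta`, per-decade
#'   expected WATL, sampling weights and inclusion probabilities).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pool <- config$taxon_pool
  ts <- .decade_t(config)
  variant_list <- strsplit(pool$vernacular, "|", fixed = TRUE)

  per_decade <- lapply(seq_along(config$decades), function(di) {
    dec <- config$decades[di]
    n <- config$items_per_decade[di]
    set.seed(substream_seed(config$seed, dec))
    p <- .inclusion_probs(config, ts[di])
    k <- nrow(pool)
    inc <- matrix(stats::runif(n * k) < rep(p, each = n), nrow = n)
    mentions <- character(n)
    hits <- which(inc, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      nv <- lengths(variant_list)
      offset <- cumsum(c(0L, nv[-length(nv)]))
      pick <- 1L + as.integer(floor(stats::runif(nrow(hits)) * nv[hits[, 2]]))
      raw <- unlist(variant_list, use.names = FALSE)[offset[hits[, 2]] + pick]
      rep_it <- stats::runif(nrow(hits)) < config$repeat_mention_rate
      raw[rep_it] <- paste(raw[rep_it], toupper(raw[rep_it]), sep = "|")
      mentions <- vapply(split(raw, factor(hits[, 1], levels = seq_len(n))),
                         paste, character(1), collapse = "|")
    }
    gear_pool <- c("rede", "rede de espera", "tarrafa", "espinhel", "arrasto")
    has_gear <- stats::runif(n) < 0.3
    gear <- ifelse(has_gear, gear_pool[sample.int(length(gear_pool), n,
                                                  replace = TRUE)], "")
    items <- tibble::tibble(
      item_id = sprintf("it_%d_%04d", dec, seq_len(n)),
      newspaper = sprintf("paper_%d_%02d",
                          dec, sample.int(config$newspapers_per_decade[di],
                                          n, replace = TRUE)),
      year = dec + sample.int(10, n, replace = TRUE) - 1L,
      municipality = sample(c("Florianopolis", "Laguna", "Itajai",
                              "Sao Francisco do Sul"), n, replace = TRUE),
      keyword_source = sample(c("pesca", "peixe", "both"), n, replace = TRUE,
                              prob = c(0.4, 0.5, 0.1)),
      is_duplicate = FALSE,
      is_advertisement = stats::runif(n) < config$advertisement_rate,
      scope_marine = TRUE,
      has_animal_report = TRUE,
      mentions = mentions,
      gear_mentions = gear
    )
    dup <- which(stats::runif(n) < config$duplicate_rate & seq_len(n) > 1)
    if (length(dup) > 0) {
      src <- vapply(dup, function(i) sample.int(i - 1L, 1), integer(1))
      items[dup, ] <- items[src, ]
      items$is_duplicate[dup] <- TRUE
    }
    items
  })

  items <- news_items(dplyr::bind_rows(per_decade))
  registry <- taxon_registry(tibble::tibble(
    vernacular_name = unlist(variant_list),
    scientific_name = rep(pool$scientific_name, lengths(variant_list)),
    taxonomic_level = rep(pool$taxonomic_level, lengths(variant_list)),
    group = rep(pool$group, lengths(variant_list)),
    habitat = rep(pool$habitat, lengths(variant_list)),
    native_status = rep(pool$native_status, lengths(variant_list)),
    trophic_level = rep(pool$trophic_level, lengths(variant_list)),
    trophic_guild = rep(pool$trophic_guild, lengths(variant_list))
  ))
  truth <- list(
    delta = config$trophic_decline_effect,
    expected_watl = tibble::tibble(
      decade = config$decades,
      expected_watl = vapply(config$decades, function(d)
        expected_watl(config, d), numeric(1))
    ),
    weights = vapply(ts, function(t) .sampling_weights(config, t),
                     numeric(nrow(pool))),
    inclusion_probs = vapply(ts, function(t) .inclusion_probs(config, t),
                             numeric(nrow(pool)))
  )
  list(items = items, registry = registry, truth = truth)
}
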