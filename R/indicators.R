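#' Per-decade trophic and composition indicators
#'
#' Computes the three catch-composition indicators from a vernacular-level
#' occurrence table and a taxon registry, applying the standard exclusion
#' set: non-native and freshwater organisms, reptiles, birds and sea
#' mammals never enter any indicator.
#'
#' * **WATL** — weighted average trophic level of native marine fish:
#'   `sum(TL_i * n_i) / sum(n_i)` over eligible fish keys with known TL.
#'   A folk name mapping to several fish taxa contributes the mean TL of
#'   the mapped taxa; a name mapping to a mix of fish and non-fish taxa is
#'   ineligible and reported.
#' * **Pis/Pla** — occurrences of piscivorous over planktivorous native
#'   marine fish; missing when the planktivore sum is zero.
#' * **Inv/Fis** — occurrences of native marine invertebrates (crustaceans,
#'   molluscs and, by default, echinoderms) over native marine fish;
#'   missing when the fish sum is zero.
#'
#' Decades with an empty eligible set are missing (`NA`), never zero.
#'
#' @param table vernacular-level `decadal_table` from [decadal_abundance()].
#' @param registry a [taxon_registry()].
#' @param include_echinoderms include echinoderms in the invertebrate
#'   numerator (default `TRUE`: they are native marine invertebrates and
#'   are not on the exclusion list).
#' @return object of class `indicator_series`: tibble with one row per
#'   decade and columns `watl`, `pis_pla`, `inv_fis`, plus eligibility
#'   counts; attribute `ineligible_keys` lists keys excluded from WATL for
#'   mapping to a mix of fish and non-fish taxa.
#' @export
indicator_series <- function(table, registry, include_echinoderms = TRUE) {
  stopifnot(inherits(table, "decadal_table"), table$level == "vernacular")
  attrs <- key_attributes(registry)
  counts <- dplyr::left_join(table$counts, attrs,
                             by = c(key = "vernacular_key"))

  inv_groups <- c("crustacean", "mollusc",
                  if (include_echinoderms) "echinoderm")
  is_fish <- !is.na(counts$group) & counts$group == "native_marine_fish"
  is_inv <- !is.na(counts$group) & counts$group %in% inv_groups
  watl_ok <- is_fish & !is.na(counts$trophic_level)
  mixed <- !is.na(counts$group) & counts$group == "mixed"

  decades <- sort(unique(table$margin$decade))
  f <- factor(counts$decade, levels = decades)
  agg <- function(vals) {
    out <- rep(0, length(decades))
    if (length(vals)) {
      r <- rowsum(vals, f, na.rm = TRUE)
      out[match(rownames(r), as.character(decades))] <- r[, 1]
    }
    out
  }
  n <- counts$count
  watl_num <- agg(ifelse(watl_ok, n * counts$trophic_level, 0))
  watl_den <- agg(ifelse(watl_ok, n, 0L))
  pis <- agg(ifelse(is_fish & counts$trophic_guild %in% "piscivore", n, 0L))
  pla <- agg(ifelse(is_fish & counts$trophic_guild %in% "planktivore", n, 0L))
  inv <- agg(ifelse(is_inv, n, 0L))
  fis <- agg(ifelse(is_fish, n, 0L))
  per <- tibble::tibble(
    decade = decades,
    watl = ifelse(watl_den > 0, watl_num / watl_den, NA_real_),
    n_watl_eligible = as.integer(watl_den),
    pis_pla = ifelse(pla > 0, pis / pla, NA_real_),
    inv_fis = ifelse(fis > 0, inv / fis, NA_real_),
    n_pis = as.integer(pis), n_pla = as.integer(pla),
    n_inv = as.integer(inv), n_fis = as.integer(fis)
  )
  attr(per, "ineligible_keys") <- sort(unique(counts$key[mixed]))
  attr(per, "exclusions_applied") <-
    c("non_native", "freshwater", "reptile", "bird", "sea_mammal",
      if (!include_echinoderms) "echinoderm_from_invertebrates")
  class(per) <- c("indicator_series", class(per))
  per
}

#' WATL for one decade
#'
#' Convenience accessor over [indicator_series()].
#'
#' @param table vernacular-level `decadal_table`.
#' @param registry a [taxon_registry()].
#' @param decade decade label (e.g. `1900`).
#' @return WATL (numeric) or `NA` when no eligible taxon occurs.
#' @export
watl <- function(table, registry, decade) {
  s <- indicator_series(table, registry)
  s$watl[match(decade, s$decade)]
}

#' Piscivore/planktivore ratio for one decade
#' @inheritParams watl
#' @return ratio or `NA` when the planktivore sum is zero.
#' @export
pis_pla <- function(table, registry, decade) {
  s <- indicator_series(table, registry)
  s$pis_pla[match(decade, s$decade)]
}

#' Invertebrate/fish ratio for one decade
#' @inheritParams watl
#' @param include_echinoderms see [indicator_series()].
#' @return ratio or `NA` when the fish sum is zero.
#' @export
inv_fis <- function(table, registry, decade, include_echinoderms = TRUE) {
  s <- indicator_series(table, registry,
                        include_echinoderms = include_echinoderms)
  s$inv_fis[match(decade, s$decade)]
}

#' Fishing-gear frequency and diversity
#'
#' Gear mentions are normalized and capped per item exactly like taxa, then
#' rolled up into broad standard categories (e.g. every net variant into
#' "rede") via a two-column mapping. Unmapped gear names are reported under
#' their own normalized key with category `"unmapped"`, never dropped.
#'
#' @param items included [news_items()].
#' @param gear_map optional data frame (`raw_gear`, `standard_category`);
#'   raw names are normalized before matching.
#' @return list with `by_category` (category, frequency, variant richness),
#'   `per_decade` (decade, category, frequency), `overall` (total gear
#'   frequency and variant richness) and `unmapped` (character vector).
#' @export
gear_summary <- function(items, gear_map = NULL) {
  stopifnot(inherits(items, "news_items"))
  occ <- corpus_occurrences(items)
  occ <- occ[occ$type == "gear", , drop = FALSE]
  if (!is.null(gear_map)) {
    gm <- tibble::tibble(
      key = normalize_name(gear_map$raw_gear),
      category = gear_map$standard_category
    )
    occ <- dplyr::left_join(occ, gm, by = "key")
  } else {
    occ$category <- NA_character_
  }
  unmapped <- sort(unique(occ$key[is.na(occ$category)]))
  occ$category[is.na(occ$category)] <- "unmapped"

  by_category <- dplyr::summarise(
    dplyr::group_by(occ, .data$category),
    frequency = dplyr::n(),
    richness = dplyr::n_distinct(.data$key),
    .groups = "drop"
  )
  per_decade <- dplyr::count(occ, .data$decade, .data$category,
                             name = "frequency")
  list(
    by_category = by_category,
    per_decade = per_decade,
    overall = tibble::tibble(frequency = nrow(occ),
                             richness = length(unique(occ$key))),
    unmapped = unmapped
  )
}
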