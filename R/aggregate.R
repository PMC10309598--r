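#' Build a decade-by-taxon occurrence table
#'
#' Cell (d, k) is the number of included items in decade d that mention key
#' k, with repeats inside one item counted once (the presence cap). At the
#' `"vernacular"` level keys are normalized folk names; at the
#' `"scientific"` level an item contributes one occurrence to every
#' scientific taxon that any of its mentioned folk names resolves to, again
#' capped per item, so a scientific cell can never exceed the sum of its
#' contributing vernacular cells. Unresolved keys are dropped from the
#' scientific table (they have no taxon) but kept at the vernacular level.
#'
#' @param items an included [news_items()] table (already filtered).
#' @param registry a [taxon_registry()]; required for `level =
#'   "scientific"`, optional otherwise.
#' @param level `"vernacular"` (default) or `"scientific"`.
#' @return object of class `decadal_table`: list with `counts` (tidy
#'   tibble decade/key/count), `level`, and `margin` (per-decade
#'   included-item counts).
#' @export
decadal_abundance <- function(items, registry = NULL, level = "vernacular") {
  stopifnot(inherits(items, "news_items"),
            level %in% c("vernacular", "scientific"))
  occ <- corpus_occurrences(items)
  occ <- occ[occ$type == "taxon", , drop = FALSE]
  margin <- dplyr::count(tibble::as_tibble(items), .data$decade,
                         name = "n_items")
  if (level == "scientific") {
    if (is.null(registry)) {
      rlang::abort("a registry is required for scientific-level aggregation",
                   class = "pesc_validation_error")
    }
    map <- dplyr::distinct(tibble::as_tibble(registry), .data$vernacular_key,
                           .data$scientific_name)
    # many-to-many is the nature of folk taxonomy: one key may fan out to
    # several taxa and several keys may share a taxon
    occ <- dplyr::inner_join(occ, map, by = c(key = "vernacular_key"),
                             relationship = "many-to-many")
    occ$key <- occ$scientific_name
    # re-apply the per-item cap at the scientific level: two folk names in
    # one item resolving to the same taxon count once
    occ <- dplyr::distinct(occ, .data$item_id, .data$decade, .data$key)
  }
  counts <- dplyr::count(occ, .data$decade, .data$key, name = "count")
  structure(list(counts = counts, level = level, margin = margin),
            class = "decadal_table")
}

#' @export
print.decadal_table <- function(x, ...) {
  cat("Decadal occurrence table (", x$level, " level)\n", sep = "")
  cat("  decades:", nrow(x$margin), " keys:",
      length(unique(x$counts$key)), " total occurrences:",
      sum(x$counts$count), "\n")
  invisible(x)
}

#' Decade-by-taxon matrix view
#'
#' @param table a `decadal_table`.
#' @return integer matrix, rows = decades (sorted), columns = keys.
#' @export
decadal_matrix <- function(table) {
  stopifnot(inherits(table, "decadal_table"))
  wide <- tidyr::pivot_wider(table$counts, names_from = "key",
                             values_from = "count", values_fill = 0L)
  wide <- wide[order(wide$decade), , drop = FALSE]
  m <- as.matrix(wide[, setdiff(names(wide), "decade"), drop = FALSE])
  rownames(m) <- wide$decade
  m
}

#' Taxon richness per decade and overall
#'
#' Richness is the number of distinct taxa (at the table's level) with
#' nonzero occurrence. Overall richness counts a taxon once across all
#' decades.
#'
#' @param table a `decadal_table` built at the requested level.
#' @return list with `per_decade` (tibble decade/richness) and `overall`
#'   (integer).
#' @export
richness <- function(table) {
  stopifnot(inherits(table, "decadal_table"))
  nz <- table$counts[table$counts$count > 0, , drop = FALSE]
  per_decade <- dplyr::summarise(dplyr::group_by(nz, .data$decade),
                                 richness = dplyr::n_distinct(.data$key),
                                 .groups = "drop")
  per_decade <- dplyr::left_join(table$margin["decade"], per_decade,
                                 by = "decade")
  per_decade$richness[is.na(per_decade$richness)] <- 0L
  list(per_decade = per_decade, overall = length(unique(nz$key)))
}

#' Relative abundance as a printed percentage
#'
#' 100 * count / total, rounded half-up to one decimal — the convention
#' used for every percentage this package reports.
#'
#' @param count nonnegative occurrence count.
#' @param total positive grand total (must be >= count).
#' @return percentage rounded half-up to one decimal.
#' @examples
#' relative_abundance(187, 1655)  # 11.3
#' @export
relative_abundance <- function(count, total) {
  if (any(total == 0)) {
    rlang::abort("relative abundance is undefined for total = 0",
                 class = "pesc_undefined_denominator")
  }
  stopifnot(all(count >= 0), all(total >= count))
  round_half_up(100 * count / total, 1)
}

#' Per-group abundance and richness summary
#'
#' Tallies, for each broad taxonomic group, the total number of mentions
#' (abundance n), vernacular richness v, and scientific richness s.
#' Vernacular keys not present in the registry go to an `"unassigned"`
#' bucket: they still count as mentions (they were reported) but carry no
#' scientific identity. Keys mapping to taxa in more than one group are
#' reported under `"mixed"`.
#'
#' @param vern_table vernacular-level `decadal_table`.
#' @param registry a [taxon_registry()].
#' @return list with `by_group` (tibble group/abundance/richness_vernacular/
#'   richness_scientific) and `totals` (one-row tibble of grand totals).
#' @export
group_summary <- function(vern_table, registry) {
  stopifnot(inherits(vern_table, "decadal_table"),
            vern_table$level == "vernacular",
            inherits(registry, "taxon_registry"))
  attrs <- key_attributes(registry)
  per_key <- dplyr::summarise(dplyr::group_by(vern_table$counts, .data$key),
                              n = sum(.data$count), .groups = "drop")
  per_key <- dplyr::left_join(per_key, attrs[c("vernacular_key", "group")],
                              by = c(key = "vernacular_key"))
  per_key$group[is.na(per_key$group)] <- "unassigned"

  by_group_vn <- dplyr::summarise(dplyr::group_by(per_key, .data$group),
                                  abundance = sum(.data$n),
                                  richness_vernacular = dplyr::n(),
                                  .groups = "drop")

  # scientific richness: distinct scientific taxa reachable from observed keys
  map <- dplyr::distinct(tibble::as_tibble(registry), .data$vernacular_key,
                         .data$scientific_name, .data$group)
  sci <- dplyr::inner_join(per_key["key"], map, by = c(key = "vernacular_key"))
  sci <- dplyr::distinct(sci, .data$scientific_name, .data$group)
  by_group_sci <- dplyr::count(sci, .data$group, name = "richness_scientific")

  by_group <- dplyr::full_join(by_group_vn, by_group_sci, by = "group")
  by_group$richness_scientific[is.na(by_group$richness_scientific)] <- 0L
  totals <- tibble::tibble(
    abundance = sum(by_group$abundance),
    richness_vernacular = sum(by_group$richness_vernacular),
    richness_scientific = length(unique(sci$scientific_name))
  )
  list(by_group = by_group, totals = totals)
}
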