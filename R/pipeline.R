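#' Run the full newspaper-to-indicators pipeline
#'
#' Binds every stage together: inclusion filtering with an exclusion
#' ledger, decade-by-taxon tables at vernacular and scientific level,
#' group summary, indicator series (WATL, Pis/Pla, Inv/Fis), gear
#' summary, trend statistics against corpus size and time, optional
#' landings comparison, and an unresolved-name report. When an output
#' directory is given, every table is written as CSV and a single
#' machine-readable JSON summary mirrors them all; re-running on identical
#' inputs produces identical files (no timestamps, no hidden state).
#'
#' @param items a [news_items()] table (raw; filtering happens here).
#' @param registry a [taxon_registry()].
#' @param gear_map optional gear standardisation table
#'   (`raw_gear`, `standard_category`).
#' @param landings optional landings table (`year`, `group`, `tonnes`).
#' @param newspapers_per_decade optional tibble (`decade`, `n_newspapers`)
#'   with archive-wide newspaper counts; falls back to distinct newspapers
#'   observed in the item table.
#' @param include_echinoderms passed to [indicator_series()].
#' @param out_dir optional directory for CSV/JSON outputs (created if
#'   missing).
#' @return (invisibly when writing) a list with all computed components:
#'   `ledger`, `summary` (corpus summary), `vernacular`, `scientific`
#'   (decadal tables), `groups`, `indicators`, `gear`, `trends`,
#'   `landings_comparison`, `unresolved`.
#' @export
run_pipeline <- function(items, registry, gear_map = NULL, landings = NULL,
                         newspapers_per_decade = NULL,
                         include_echinoderms = TRUE, out_dir = NULL) {
  stopifnot(inherits(items, "news_items"), inherits(registry, "taxon_registry"))
  flt <- filter_items(items)
  if (nrow(flt$included) == 0) {
    rlang::warn("no items pass the inclusion rules; all indicators will be missing")
  }
  summary_tbl <- corpus_summary(items, newspapers_per_decade)
  vern <- decadal_abundance(flt$included, registry, level = "vernacular")
  sci <- decadal_abundance(flt$included, registry, level = "scientific")
  groups <- group_summary(vern, registry)
  ind <- indicator_series(vern, registry,
                          include_echinoderms = include_echinoderms)
  gear <- gear_summary(flt$included, gear_map)

  mappings <- name_mappings(registry)
  observed <- unique(vern$counts$key)
  unresolved <- sort(setdiff(observed, registry$vernacular_key))

  rich <- richness(vern)
  effort <- if (!is.null(newspapers_per_decade)) {
    dplyr::left_join(summary_tbl["decade"], newspapers_per_decade,
                     by = "decade")$n_newspapers
  } else summary_tbl$n_newspapers_observed
  abun <- dplyr::left_join(
    summary_tbl["decade"],
    dplyr::summarise(dplyr::group_by(vern$counts, .data$decade),
                     abundance = sum(.data$count), .groups = "drop"),
    by = "decade")$abundance
  rich_aligned <- dplyr::left_join(summary_tbl["decade"], rich$per_decade,
                                   by = "decade")$richness

  safe_trend <- function(x, y) {
    tryCatch(pearson_trend(x, y), error = function(e) NULL)
  }
  ind_aligned <- dplyr::left_join(summary_tbl["decade"],
                                  tibble::as_tibble(ind), by = "decade")
  trends <- list(
    items_vs_newspapers = safe_trend(effort, summary_tbl$matched_once),
    richness_vs_newspapers = safe_trend(effort, rich_aligned),
    abundance_vs_newspapers = safe_trend(effort, abun),
    watl_vs_time = safe_trend(summary_tbl$decade, ind_aligned$watl),
    pis_pla_vs_time = safe_trend(summary_tbl$decade, ind_aligned$pis_pla),
    inv_fis_vs_time = safe_trend(summary_tbl$decade, ind_aligned$inv_fis)
  )
  landings_comparison <- if (!is.null(landings)) {
    compare_with_landings(ind, landings)
  } else NULL

  result <- list(
    ledger = flt$ledger,
    summary = summary_tbl,
    vernacular = vern,
    scientific = sci,
    groups = groups,
    indicators = ind,
    gear = gear,
    trends = trends,
    landings_comparison = landings_comparison,
    unresolved = unresolved,
    name_mappings = mappings
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
    return(invisible(result))
  }
  result
}

trend_as_list <- function(tr) {
  if (is.null(tr)) return(NULL)
  tr[c("r", "r_squared", "p_value", "slope", "intercept", "n_points")]
}

#' Write pipeline outputs to disk
#'
#' CSV for every table plus one JSON summary mirroring them; every number
#' in the JSON is copied from a table cell, never recomputed.
#'
#' @param result return value of [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(out_dir, name)
  readr::write_csv(result$ledger, p("exclusion_ledger.csv"))
  readr::write_csv(result$summary, p("corpus_summary.csv"))
  readr::write_csv(result$vernacular$counts, p("decadal_vernacular.csv"))
  readr::write_csv(result$scientific$counts, p("decadal_scientific.csv"))
  readr::write_csv(result$groups$by_group, p("group_summary.csv"))
  readr::write_csv(tibble::as_tibble(result$indicators), p("indicators.csv"))
  readr::write_csv(result$gear$by_category, p("gear_summary.csv"))
  readr::write_csv(tibble::tibble(vernacular_key = result$unresolved),
                   p("unresolved_names.csv"))
  summary_json <- list(
    ledger = result$ledger,
    corpus_summary = result$summary,
    decadal_vernacular = result$vernacular$counts,
    decadal_scientific = result$scientific$counts,
    group_summary = result$groups$by_group,
    group_totals = result$groups$totals,
    indicators = tibble::as_tibble(result$indicators),
    gear = result$gear$by_category,
    trends = lapply(result$trends, trend_as_list),
    unresolved = result$unresolved
  )
  jsonlite::write_json(summary_json, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list.files(out_dir, full.names = TRUE))
}
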