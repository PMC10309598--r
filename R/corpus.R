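#' Build a news-item table
#'
#' One row per newspaper item, carrying the relevance flags produced by the
#' (human, out-of-scope) reading step and the raw mention lists. Mentions
#' and gear mentions are "|"-separated list fields. The decade label is
#' derived as `floor(year / 10) * 10`, so 1885 falls in decade 1880
#' (1880–1889).
#'
#' @param items data frame with columns `item_id`, `newspaper`, `year`,
#'   `municipality`, `keyword_source` (`"pesca"`, `"peixe"` or `"both"`),
#'   `is_duplicate`, `is_advertisement`, `scope_marine`,
#'   `has_animal_report`, `mentions`, `gear_mentions`.
#' @return tibble of class `news_items` with a derived `decade` column
#'   (`NA` when the year is missing).
#' @export
news_items <- function(items) {
  required <- c("item_id", "newspaper", "year", "municipality",
                "keyword_source", "is_duplicate", "is_advertisement",
                "scope_marine", "has_animal_report", "mentions",
                "gear_mentions")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    rlang::abort(paste0("item table is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "pesc_schema_error")
  }
  it <- tibble::as_tibble(items[required])
  it$year <- suppressWarnings(as.integer(it$year))
  it$decade <- as.integer(floor(it$year / 10) * 10)
  bad_source <- !it$keyword_source %in% c("pesca", "peixe", "both")
  if (any(bad_source)) {
    rlang::abort("keyword_source must be one of pesca, peixe, both",
                 class = "pesc_validation_error")
  }
  # the study window is 1840-2019; out-of-window years are kept but flagged
  it$out_of_window <- !is.na(it$year) & (it$year < 1840 | it$year > 2019)
  class(it) <- c("news_items", class(it))
  it
}

#' Read a news-item table from CSV/TSV
#'
#' @param path delimited UTF-8 file, one record per item; `mentions` and
#'   `gear_mentions` are delimiter-separated list fields.
#' @param delim field delimiter; guessed from the extension when `NULL`.
#' @return a `news_items` tibble.
#' @export
read_news_items <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  it <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(
                            mentions = readr::col_character(),
                            gear_mentions = readr::col_character()
                          ))
  it$mentions[is.na(it$mentions)] <- ""
  it$gear_mentions[is.na(it$gear_mentions)] <- ""
  news_items(it)
}

#' Apply the item inclusion rules
#'
#' An item is included when it is not a duplicate, not an advertisement,
#' focuses on coastal/ocean areas (`scope_marine`) and reports marine
#' animals (`has_animal_report`). Items without a usable date are rejected
#' with reason `"undated"`. Duplicate detection additionally catches exact
#' repeats of an already-seen `item_id`. Exclusions are reported in a
#' ledger, one count per reason, so the cleaning step stays auditable.
#'
#' @param items a [news_items()] table.
#' @return list with `included` (the filtered `news_items`), `excluded`
#'   (excluded rows with a `reason` column) and `ledger` (tibble of
#'   reason/count pairs, including an `included` row). Idempotent:
#'   filtering the `included` set again excludes nothing.
#' @export
filter_items <- function(items) {
  stopifnot(inherits(items, "news_items"))
  reason <- rep(NA_character_, nrow(items))
  seen <- duplicated(items$item_id)
  reason[is.na(items$decade)] <- "undated"
  pick <- function(cond, label) {
    idx <- is.na(reason) & cond
    reason[idx] <<- label
  }
  pick(items$is_duplicate | seen, "duplicate")
  pick(items$is_advertisement, "advertisement")
  pick(!items$scope_marine, "not_marine_scope")
  pick(!items$has_animal_report, "no_animal_report")

  included <- items[is.na(reason), , drop = FALSE]
  excluded <- items[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  counts <- table(factor(excluded$reason,
                         levels = c("undated", "duplicate", "advertisement",
                                    "not_marine_scope", "no_animal_report")))
  ledger <- tibble::tibble(
    reason = c(names(counts), "included"),
    n = c(as.integer(counts), nrow(included))
  )
  list(included = included, excluded = tibble::as_tibble(excluded),
       ledger = ledger)
}

#' Extract capped per-item occurrences
#'
#' Occurrence counting is presence-based: if a taxon is mentioned more than
#' once in a single item its abundance in that item is counted as one. The
#' cap operates on normalized vernacular keys, so two spellings of the same
#' folk name collapse, while genuinely distinct folk names (even for the
#' same species) count separately. Gear mentions are capped the same way.
#'
#' @param item one row of a [news_items()] table.
#' @return list with `taxa` and `gear`, each a character vector of distinct
#'   normalized keys (each implicitly count 1).
#' @export
item_occurrences <- function(item) {
  raw_taxa <- split_list_field(item$mentions)
  raw_gear <- split_list_field(item$gear_mentions)
  list(
    taxa = unique(if (length(raw_taxa)) normalize_name(raw_taxa) else character(0)),
    gear = unique(if (length(raw_gear)) normalize_name(raw_gear) else character(0))
  )
}

# long tibble of capped occurrences for a whole corpus:
# one row per (item, decade, key, type); fully vectorized so replicate
# studies over hundreds of synthetic corpora stay fast
corpus_occurrences <- function(items) {
  stopifnot(inherits(items, "news_items"))
  empty <- tibble::tibble(item_id = character(0), decade = integer(0),
                          key = character(0), type = character(0))
  if (nrow(items) == 0) return(empty)
  explode <- function(field, type) {
    parts <- strsplit(ifelse(is.na(field), "", field), "|", fixed = TRUE)
    lens <- lengths(parts)
    raw <- trimws(unlist(parts, use.names = FALSE))
    out <- tibble::tibble(
      item_id = rep(as.character(items$item_id), lens),
      decade = rep(items$decade, lens),
      key = raw,
      type = type
    )
    out <- out[nzchar(out$key), , drop = FALSE]
    out$key <- normalize_name(out$key)
    out
  }
  occ <- dplyr::bind_rows(explode(items$mentions, "taxon"),
                          explode(items$gear_mentions, "gear"))
  if (nrow(occ) == 0) return(empty)
  # presence cap: each key counts at most once per item
  dplyr::distinct(occ, .data$item_id, .data$decade, .data$key, .data$type)
}

#' Summarise corpus coverage per decade
#'
#' @param items a [news_items()] table (typically the raw, unfiltered set).
#' @param newspapers_per_decade optional tibble (`decade`, `n_newspapers`)
#'   with the archive-wide newspaper counts used as the sampling-effort
#'   covariate; when `NULL` the count of distinct newspapers in the item
#'   table is used.
#' @return tibble with per-decade distinct-newspaper counts, matched items
#'   per keyword (an item matched by both keywords counts under both, and
#'   once under `matched_once`), and included-item counts.
#' @export
corpus_summary <- function(items, newspapers_per_decade = NULL) {
  stopifnot(inherits(items, "news_items"))
  flt <- filter_items(items)
  base <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(items), .data$decade),
    n_newspapers_observed = dplyr::n_distinct(.data$newspaper),
    matched_pesca = sum(.data$keyword_source %in% c("pesca", "both")),
    matched_peixe = sum(.data$keyword_source %in% c("peixe", "both")),
    matched_once = dplyr::n(),
    .groups = "drop"
  )
  inc <- dplyr::count(tibble::as_tibble(flt$included), .data$decade,
                      name = "included")
  out <- dplyr::left_join(base, inc, by = "decade")
  out$included[is.na(out$included)] <- 0L
  if (!is.null(newspapers_per_decade)) {
    out <- dplyr::left_join(out, newspapers_per_decade, by = "decade")
  }
  out
}
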