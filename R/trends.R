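#' Pearson correlation with a least-squares trend line
#'
#' The workhorse statistic for relating an indicator series to time or to
#' corpus size. Missing entries are dropped pairwise (sparse early decades
#' are a documented feature of archive data, not something to impute).
#' Reports Pearson r, R-squared, the two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom, and the OLS slope and
#' intercept of y on x.
#'
#' @param x,y paired numeric series; `NA`s dropped pairwise.
#' @return object of class `trend_result`: list with `r`, `r_squared`,
#'   `p_value`, `slope`, `intercept`, `n_points`.
#' @export
pearson_trend <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    rlang::abort("need at least 3 complete pairs for a trend",
                 class = "pesc_insufficient_data")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation is undefined for a constant series",
                 class = "pesc_undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  structure(list(
    r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_points = length(x)
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("r = %.3f; R^2 = %.3f; p = %.4g; slope = %.4g (n = %d)\n",
              x$r, x$r_squared, x$p_value, x$slope, x$n_points))
  invisible(x)
}

#' Percent change between two values
#'
#' `100 * (v1 - v0) / v0`, as used for historical production and landings
#' comparisons (e.g. national fish byproduct rising from 2112 t to 11208 t
#' is a 431% increase). Returns both the raw value and the value rounded
#' half-up to the nearest integer, the convention for printed percent
#' changes.
#'
#' @param v0 baseline value, must be positive.
#' @param v1 later value, nonnegative.
#' @return list with `raw` and `rounded`.
#' @examples
#' percent_change(2112, 11208)$rounded  # 431
#' @export
percent_change <- function(v0, v1) {
  if (any(v0 <= 0)) {
    rlang::abort("percent change is undefined for a nonpositive baseline",
                 class = "pesc_undefined_baseline")
  }
  stopifnot(all(v1 >= 0))
  raw <- 100 * (v1 - v0) / v0
  list(raw = raw, rounded = round_half_up(raw, 0))
}

#' Catch tonnage from a head count and mean weight
#'
#' Converts a reported number of fish and an average individual weight into
#' tonnes: `count * mean_weight_kg / 1000`. Used to put historical
#' head-count reports (e.g. "more than one million mullets caught every
#' winter") on the same scale as modern landings.
#'
#' @param count number of individuals (nonnegative).
#' @param mean_weight_kg mean individual weight in kg (positive).
#' @return tonnes (numeric).
#' @examples
#' tonnage_estimate(1e6, 2)  # 2000
#' @export
tonnage_estimate <- function(count, mean_weight_kg) {
  if (any(count < 0)) {
    rlang::abort("count must be nonnegative", class = "pesc_invalid_input")
  }
  stopifnot(all(mean_weight_kg > 0))
  count * mean_weight_kg / 1000
}

#' Compare a newspaper Inv/Fis series with landings data
#'
#' Aggregates a landings time series (year, group, tonnes) to decades by
#' summation, computes the landings invertebrate/fish tonnage ratio per
#' decade, aligns it with the newspaper-derived Inv/Fis series on
#' overlapping decades, and (when at least 3 decades overlap with
#' variation) adds a Pearson trend between the two. The correlation is
#' exploratory: occurrence ratios and tonnage ratios measure different
#' things and are compared for direction, not magnitude.
#'
#' @param indicator_series an [indicator_series()] (its `inv_fis` column
#'   is used).
#' @param landings data frame with columns `year`, `group` (`"fish"` or
#'   `"invertebrate"`) and `tonnes`.
#' @return list with `aligned` (decade, inv_fis_newspapers,
#'   inv_fis_landings) and `trend` (a `trend_result` or `NULL` when the
#'   overlap cannot support one).
#' @export
compare_with_landings <- function(indicator_series, landings) {
  required <- c("year", "group", "tonnes")
  if (!all(required %in% names(landings))) {
    rlang::abort("landings needs columns year, group, tonnes",
                 class = "pesc_schema_error")
  }
  if (!all(landings$group %in% c("fish", "invertebrate"))) {
    rlang::abort("landings group must be 'fish' or 'invertebrate'",
                 class = "pesc_validation_error")
  }
  ld <- tibble::as_tibble(landings)
  ld$decade <- as.integer(floor(ld$year / 10) * 10)
  dec <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(ld, .data$decade, .data$group),
                     tonnes = sum(.data$tonnes), .groups = "drop"),
    names_from = "group", values_from = "tonnes", values_fill = 0
  )
  if (!"invertebrate" %in% names(dec)) dec$invertebrate <- 0
  if (!"fish" %in% names(dec)) dec$fish <- 0
  dec$inv_fis_landings <- ifelse(dec$fish > 0,
                                 dec$invertebrate / dec$fish, NA_real_)
  aligned <- dplyr::inner_join(
    tibble::tibble(decade = indicator_series$decade,
                   inv_fis_newspapers = indicator_series$inv_fis),
    dec[c("decade", "inv_fis_landings")],
    by = "decade"
  )
  if (nrow(aligned) == 0) {
    rlang::abort("no overlapping decades between indicators and landings",
                 class = "pesc_insufficient_overlap")
  }
  trend <- tryCatch(
    pearson_trend(aligned$inv_fis_newspapers, aligned$inv_fis_landings),
    error = function(e) NULL
  )
  list(aligned = aligned, trend = trend)
}
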