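#' Normalize a vernacular (folk) taxon name
#'
#' Historical newspapers spell folk names inconsistently ("Tainha-Assú",
#' "tainha-assu", "camarão  sete barbas"). Normalization lowercases,
#' strips diacritics, trims, and collapses internal whitespace to single
#' spaces. Hyphens are preserved because they distinguish compound folk
#' names. The function is idempotent.
#'
#' @param raw character vector of raw names; each must be non-empty after
#'   trimming.
#' @return character vector of normalized keys.
#' @examples
#' normalize_name("Tainha")                  # "tainha"
#' normalize_name("camarão sete  barbas") # "camarao sete barbas"
#' @export
normalize_name <- function(raw) {
  if (!is.character(raw)) {
    rlang::abort("`raw` must be a character vector.", class = "pesc_invalid_name")
  }
  out <- stringi::stri_trans_general(raw, "Latin-ASCII")
  out <- tolower(trimws(out))
  out <- gsub("[[:space:]]+", " ", out)
  if (any(is.na(out)) || any(!nzchar(out))) {
    rlang::abort("vernacular names must be non-empty after trimming",
                 class = "pesc_invalid_name")
  }
  out
}

.taxon_groups <- c("native_marine_fish", "crustacean", "mollusc", "echinoderm",
                   "sea_mammal", "reptile", "bird", "freshwater", "non_native")
.taxon_levels <- c("species", "genus", "family", "order", "unresolved")
.taxon_guilds <- c("piscivore", "planktivore", "other", "unknown")
.taxon_habitats <- c("marine", "estuarine", "freshwater", "mixed")

#' Build a taxon registry from a dictionary table
#'
#' The registry is the taxon dictionary of the study: one row per
#' (vernacular name, scientific taxon) pair, with taxonomic level, broad
#' group, habitat, native status, adult-diet trophic level (TL) and trophic
#' guild. Because folk taxonomy is many-to-many (one folk name for several
#' species, several folk names for one species), the same vernacular may
#' occur on several rows and the same scientific taxon under several
#' vernaculars.
#'
#' @param dictionary data frame with columns `vernacular_name`,
#'   `scientific_name`, `taxonomic_level`, `group`, `habitat`,
#'   `native_status`, `trophic_level`, `trophic_guild`.
#' @return an object of class `taxon_registry`: a tibble with normalized
#'   `vernacular_key` added, validated against the schema.
#' @details Validation rules: `trophic_level` must be in \[2, 5\] or `NA`
#'   (marine consumers only); `piscivore`/`planktivore` guilds are only
#'   meaningful for native marine fish (the guild ratio indicator is
#'   fish-based); enums must match their controlled vocabularies.
#' @export
taxon_registry <- function(dictionary) {
  required <- c("vernacular_name", "scientific_name", "taxonomic_level",
                "group", "habitat", "native_status", "trophic_level",
                "trophic_guild")
  missing_cols <- setdiff(required, names(dictionary))
  if (length(missing_cols)) {
    rlang::abort(paste0("dictionary is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "pesc_schema_error")
  }
  reg <- tibble::as_tibble(dictionary[required])
  reg$trophic_level <- as.numeric(reg$trophic_level)
  bad_tl <- !is.na(reg$trophic_level) &
    (reg$trophic_level < 2 | reg$trophic_level > 5)
  if (any(bad_tl)) {
    rlang::abort(paste0("trophic_level outside [2, 5] in dictionary row(s) ",
                        paste(which(bad_tl), collapse = ", ")),
                 class = "pesc_validation_error")
  }
  check_enum <- function(col, allowed) {
    bad <- !reg[[col]] %in% allowed
    if (any(bad)) {
      rlang::abort(paste0("invalid ", col, " value(s): ",
                          paste(unique(reg[[col]][bad]), collapse = ", ")),
                   class = "pesc_validation_error")
    }
  }
  check_enum("taxonomic_level", .taxon_levels)
  check_enum("group", .taxon_groups)
  check_enum("trophic_guild", .taxon_guilds)
  check_enum("habitat", .taxon_habitats)
  bad_guild <- reg$trophic_guild %in% c("piscivore", "planktivore") &
    reg$group != "native_marine_fish"
  if (any(bad_guild)) {
    rlang::abort("piscivore/planktivore guilds are fish-based and only valid for native_marine_fish",
                 class = "pesc_validation_error")
  }
  reg$vernacular_key <- normalize_name(reg$vernacular_name)
  class(reg) <- c("taxon_registry", class(reg))
  reg
}

#' Read a taxon dictionary from CSV/TSV
#'
#' @param path path to a UTF-8 delimited file with the canonical dictionary
#'   header (see [taxon_registry()]).
#' @param delim field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv` means tab, anything else comma).
#' @return a `taxon_registry`.
#' @export
read_taxon_registry <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  dict <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  taxon_registry(dict)
}

#' Resolve a vernacular key to scientific taxa
#'
#' Looks up a normalized vernacular key in the registry and classifies the
#' folk-to-scientific mapping: `one_to_one` (one name, one taxon, and that
#' taxon has no other names), `one_folk_many_sci` (e.g. "raia prego" used
#' for several stingray genera), `many_folk_one_sci` (e.g. "tainhota", one
#' of several names for *Mugil liza*), or `unresolved` for unknown keys.
#' Unknown names are a data condition, not an error: they return an empty
#' taxon set so the caller can report them.
#'
#' @param key a single normalized vernacular key (see [normalize_name()]).
#' @param registry a [taxon_registry()].
#' @return list with `taxa` (tibble of matching registry rows, deduplicated
#'   by scientific name) and `ambiguity` (character scalar).
#' @export
resolve_name <- function(key, registry) {
  stopifnot(inherits(registry, "taxon_registry"), length(key) == 1)
  rows <- registry[registry$vernacular_key == key, , drop = FALSE]
  taxa <- dplyr::distinct(tibble::as_tibble(rows), .data$scientific_name,
                          .keep_all = TRUE)
  if (nrow(taxa) == 0) {
    ambiguity <- "unresolved"
  } else if (nrow(taxa) > 1) {
    ambiguity <- "one_folk_many_sci"
  } else {
    n_folk <- length(unique(
      registry$vernacular_key[registry$scientific_name == taxa$scientific_name]
    ))
    ambiguity <- if (n_folk > 1) "many_folk_one_sci" else "one_to_one"
  }
  list(taxa = taxa, ambiguity = ambiguity)
}

#' Assign a trophic level with taxonomic-level fallback
#'
#' Species-level taxa take their value straight from the reference diet
#' table. Taxa identified only to genus or family take the arithmetic mean
#' of the trophic levels of the member species listed for that genus or
#' family in the table — the standard fallback when a folk name cannot be
#' pinned to one species. Taxa with no member entries get `NA` and are
#' excluded from WATL downstream.
#'
#' @param scientific_name name of the taxon (species, genus or family).
#' @param taxonomic_level one of `"species"`, `"genus"`, `"family"`;
#'   other levels return `NA`.
#' @param tl_table data frame with columns `species`, `genus`, `family`,
#'   `trophic_level` mapping species-level names to TL values.
#' @return trophic level (numeric scalar) or `NA_real_`.
#' @export
assign_trophic_level <- function(scientific_name, taxonomic_level, tl_table) {
  validate_tl_table(tl_table)
  member <- switch(taxonomic_level,
    species = tl_table$trophic_level[tl_table$species == scientific_name],
    genus   = tl_table$trophic_level[tl_table$genus == scientific_name],
    family  = tl_table$trophic_level[tl_table$family == scientific_name],
    numeric(0)
  )
  member <- member[!is.na(member)]
  if (length(member) == 0) return(NA_real_)
  mean(member)
}

validate_tl_table <- function(tl_table) {
  required <- c("species", "genus", "family", "trophic_level")
  if (!all(required %in% names(tl_table))) {
    rlang::abort("tl_table needs columns species, genus, family, trophic_level",
                 class = "pesc_schema_error")
  }
  tl <- tl_table$trophic_level
  if (any(!is.na(tl) & (tl < 2 | tl > 5))) {
    rlang::abort("tl_table contains trophic levels outside [2, 5]",
                 class = "pesc_validation_error")
  }
  invisible(tl_table)
}

#' Summarise folk-to-scientific name mappings
#'
#' One row per vernacular key with the set of mapped scientific taxa and
#' the ambiguity class (see [resolve_name()]).
#'
#' @param registry a [taxon_registry()].
#' @return tibble with `vernacular_key`, `n_taxa`, `scientific_names`
#'   ("|"-separated) and `ambiguity`.
#' @export
name_mappings <- function(registry) {
  stopifnot(inherits(registry, "taxon_registry"))
  keys <- unique(registry$vernacular_key)
  purrr::map_dfr(keys, function(k) {
    res <- resolve_name(k, registry)
    tibble::tibble(
      vernacular_key = k,
      n_taxa = nrow(res$taxa),
      scientific_names = collapse_list_field(res$taxa$scientific_name),
      ambiguity = res$ambiguity
    )
  })
}

# per-key attributes used by the indicator layer: consensus group, mean TL
# over mapped taxa (the per-mention convention for ambiguous folk names),
# and consensus guild. Keys mapping to a mix of groups get group "mixed".
key_attributes <- function(registry) {
  reg <- tibble::as_tibble(registry)
  reg <- dplyr::distinct(reg, .data$vernacular_key, .data$scientific_name,
                         .keep_all = TRUE)
  dplyr::summarise(
    dplyr::group_by(reg, .data$vernacular_key),
    group = if (dplyr::n_distinct(.data$group) == 1) .data$group[1] else "mixed",
    trophic_level = if (all(is.na(.data$trophic_level))) NA_real_ else
      mean(.data$trophic_level, na.rm = TRUE),
    trophic_guild = if (dplyr::n_distinct(.data$trophic_guild) == 1)
      .data$trophic_guild[1] else "mixed",
    native_status = if (dplyr::n_distinct(.data$native_status) == 1)
      .data$native_status[1] else "mixed",
    .groups = "drop"
  )
}
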