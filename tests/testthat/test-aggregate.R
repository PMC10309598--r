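test_that("decadal abundance counts items mentioning each key", {
  it <- fixture_items(
    fixture_item(item_id = "i1", year = 1901, mentions = "tainha|anchova"),
    fixture_item(item_id = "i2", year = 1905, mentions = "tainha"),
    fixture_item(item_id = "i3", year = 1909, mentions = "camarão")
  )
  tab <- decadal_abundance(it)
  m <- decadal_matrix(tab)
  expect_equal(m["1900", "tainha"], 2)
  expect_equal(m["1900", "anchova"], 1)
  expect_equal(m["1900", "camarao"], 1)

  empty <- decadal_abundance(fixture_items(fixture_item(mentions = "")))
  expect_equal(nrow(empty$counts), 0)
})

test_that("decadal abundance matches a brute-force double loop", {
  for (seed in 1:8) {
    cfg <- synthetic_config(seed = seed,
                            decades = seq(1880, 1940, 10),
                            items_per_decade = rep(25L, 7),
                            newspapers_per_decade = rep(6L, 7))
    inc <- filter_items(generate_corpus(cfg)$items)$included
    tab <- decadal_abundance(inc)
    expect_equal(sorted_counts(tab$counts),
                 sorted_counts(brute_decadal_counts(inc)))
  }
})

test_that("scientific-level cells never exceed their vernacular sources", {
  reg <- fixture_registry()
  it <- fixture_items(
    fixture_item(item_id = "i1", year = 1900,
                 mentions = "tainha|tainhota|anchova"),
    fixture_item(item_id = "i2", year = 1900, mentions = "tanhota"),
    fixture_item(item_id = "i3", year = 1910, mentions = "raia prego")
  )
  vern <- decadal_abundance(it, reg, level = "vernacular")
  sci <- decadal_abundance(it, reg, level = "scientific")
  # two folk names in one item resolving to Mugil liza count once
  msci <- decadal_matrix(sci)
  expect_equal(msci["1900", "Mugil liza"], 2)  # items i1 and i2
  # one ambiguous folk name fans out to each mapped taxon, capped per item
  expect_equal(msci["1910", "Hypanus sp."], 1)
  expect_equal(msci["1910", "Dasyatis sp."], 1)
  # every scientific cell <= sum of contributing vernacular cells
  map <- dplyr::distinct(tibble::as_tibble(reg), vernacular_key,
                         scientific_name)
  for (r in seq_len(nrow(sci$counts))) {
    srcs <- map$vernacular_key[map$scientific_name == sci$counts$key[r]]
    vsum <- sum(vern$counts$count[vern$counts$decade == sci$counts$decade[r] &
                                    vern$counts$key %in% srcs])
    expect_lte(sci$counts$count[r], vsum)
  }
})

test_that("adding an item never decreases any cell", {
  it <- fixture_items(
    fixture_item(item_id = "i1", year = 1900, mentions = "tainha|anchova"),
    fixture_item(item_id = "i2", year = 1910, mentions = "camarão")
  )
  more <- fixture_items(
    tibble::as_tibble(it)[, !(names(it) %in% c("decade", "out_of_window"))],
    fixture_item(item_id = "i3", year = 1900, mentions = "tainha|ostra")
  )
  before <- decadal_matrix(decadal_abundance(it))
  after <- decadal_matrix(decadal_abundance(more))
  for (d in rownames(before)) for (k in colnames(before)) {
    expect_gte(after[d, k], before[d, k])
  }
})

test_that("richness counts distinct nonzero taxa, once overall", {
  it <- fixture_items(
    fixture_item(item_id = "i1", year = 1900, mentions = "tainha|anchova"),
    fixture_item(item_id = "i2", year = 1910, mentions = "tainha")
  )
  r <- richness(decadal_abundance(it))
  expect_equal(r$per_decade$richness, c(2L, 1L))
  expect_equal(r$overall, 2L)
})

test_that("relative abundance uses half-up rounding to one decimal", {
  expect_equal(relative_abundance(187, 1655), 11.3)
  expect_equal(relative_abundance(154, 1655), 9.3)
  expect_equal(relative_abundance(63, 1655), 3.8)
  expect_equal(relative_abundance(47, 1655), 2.8)
  expect_equal(relative_abundance(5, 5), 100.0)
  expect_equal(relative_abundance(1, 800), 0.1)  # 0.125 rounds up
  expect_error(relative_abundance(1, 0), class = "pesc_undefined_denominator")
})

test_that("relative abundances conserve 100% within rounding slack", {
  set.seed(77)
  for (rep in 1:10) {
    counts <- stats::rpois(sample(5:40, 1), lambda = 20) + 1
    shares <- relative_abundance(counts, sum(counts))
    expect_lte(abs(sum(shares) - 100), 0.1 * length(counts))
  }
})

test_that("group summary reconciles abundance and richness totals", {
  reg <- fixture_registry()
  it <- fixture_items(
    fixture_item(item_id = "i1", year = 1900,
                 mentions = "tainha|camarão|baleia"),
    fixture_item(item_id = "i2", year = 1910,
                 mentions = "tainhota|ostra|nomedesconhecido"),
    fixture_item(item_id = "i3", year = 1910, mentions = "raia prego")
  )
  tab <- decadal_abundance(it, reg)
  gs <- group_summary(tab, reg)
  expect_equal(gs$totals$abundance, sum(tab$counts$count))
  expect_equal(gs$totals$richness_vernacular,
               sum(gs$by_group$richness_vernacular))
  # unknown names are mentions but carry no scientific identity
  expect_true("unassigned" %in% gs$by_group$group)
  un <- gs$by_group[gs$by_group$group == "unassigned", ]
  expect_equal(un$abundance, 1L)
  expect_equal(un$richness_scientific, 0L)
})

test_that("group summary matches a brute-force recount on synthetic corpora", {
  for (seed in 1:5) {
    cfg <- synthetic_config(seed = seed, decades = seq(1900, 1930, 10),
                            items_per_decade = rep(30L, 4),
                            newspapers_per_decade = rep(8L, 4))
    g <- generate_corpus(cfg)
    inc <- filter_items(g$items)$included
    tab <- decadal_abundance(inc)
    gs <- group_summary(tab, g$registry)
    expect_equal(gs$totals$abundance, sum(brute_decadal_counts(inc)$count))
  }
})
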