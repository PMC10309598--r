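test_that("WATL is the count-weighted mean trophic level of native fish", {
  reg <- fixture_registry()
  # one eligible species -> its own TL
  it <- fixture_items(fixture_item(year = 1900, mentions = "sardinha"))
  expect_equal(watl(decadal_abundance(it), reg, 1900), 2.8)

  # TL 2.5 with n=1 and TL 4.5 with n=3 -> 4.0
  it <- fixture_items(
    fixture_item(item_id = "i1", year = 1900, mentions = "tainha|anchova"),
    fixture_item(item_id = "i2", year = 1900, mentions = "anchova"),
    fixture_item(item_id = "i3", year = 1900, mentions = "anchova")
  )
  expect_equal(watl(decadal_abundance(it), reg, 1900),
               (2.5 * 1 + 4.5 * 3) / 4)

  # decade with only excluded groups -> missing, never zero
  it <- fixture_items(fixture_item(year = 1900,
                                   mentions = "baleia|tilápia|traíra"))
  expect_true(is.na(watl(decadal_abundance(it), reg, 1900)))
})

test_that("excluded groups never enter any indicator", {
  reg <- fixture_registry()
  base <- fixture_items(
    fixture_item(item_id = "i1", year = 1900, mentions = "anchova|camarão"),
    fixture_item(item_id = "i2", year = 1900, mentions = "sardinha")
  )
  with_excluded <- fixture_items(
    fixture_item(item_id = "i1", year = 1900, mentions = "anchova|camarão"),
    fixture_item(item_id = "i2", year = 1900, mentions = "sardinha"),
    fixture_item(item_id = "i3", year = 1900,
                 mentions = "baleia|tartaruga|traíra|tilápia")
  )
  s1 <- indicator_series(decadal_abundance(base), reg)
  s2 <- indicator_series(decadal_abundance(with_excluded), reg)
  expect_equal(s1$watl, s2$watl)
  expect_equal(s1$pis_pla, s2$pis_pla)
  expect_equal(s1$inv_fis, s2$inv_fis)
})

test_that("WATL equals the plain mean when counts are equal and is scale invariant", {
  reg <- fixture_registry()
  one_each <- fixture_items(fixture_item(
    year = 1900, mentions = "tainha|anchova|sardinha|garoupa"))
  s <- indicator_series(decadal_abundance(one_each), reg)
  expect_equal(s$watl, mean(c(2.5, 4.5, 2.8, 4.0)))

  # tripling every count (three identical items) leaves WATL unchanged
  tripled <- fixture_items(fixture_item(
    item_id = c("i1", "i2", "i3"), year = 1900,
    mentions = "tainha|anchova|sardinha|garoupa"))
  s3 <- indicator_series(decadal_abundance(tripled), reg)
  expect_equal(s3$watl, s$watl)
})

test_that("WATL stays within the TL range of taxa present", {
  for (seed in 1:5) {
    cfg <- synthetic_config(seed = seed, decades = seq(1880, 1960, 10),
                            items_per_decade = rep(40L, 9),
                            newspapers_per_decade = rep(10L, 9))
    g <- generate_corpus(cfg)
    inc <- filter_items(g$items)$included
    s <- indicator_series(decadal_abundance(inc), g$registry)
    tls <- g$registry$trophic_level[g$registry$group == "native_marine_fish"]
    ok <- !is.na(s$watl)
    expect_true(all(s$watl[ok] >= min(tls, na.rm = TRUE)))
    expect_true(all(s$watl[ok] <= max(tls, na.rm = TRUE)))
    expect_true(all(s$pis_pla[!is.na(s$pis_pla)] >= 0))
    expect_true(all(s$inv_fis[!is.na(s$inv_fis)] >= 0))
  }
})

test_that("guild and composition ratios follow their definitions", {
  reg <- fixture_registry()
  mk <- function(n_pis, n_pla, n_inv = 0) {
    rows <- list()
    for (i in seq_len(n_pis)) rows[[length(rows) + 1]] <-
      fixture_item(item_id = paste0("p", i), year = 1900, mentions = "anchova")
    for (i in seq_len(n_pla)) rows[[length(rows) + 1]] <-
      fixture_item(item_id = paste0("q", i), year = 1900, mentions = "sardinha")
    for (i in seq_len(n_inv)) rows[[length(rows) + 1]] <-
      fixture_item(item_id = paste0("v", i), year = 1900, mentions = "camarão")
    fixture_items(dplyr::bind_rows(rows))
  }
  tab <- decadal_abundance(mk(5, 5))
  expect_equal(pis_pla(tab, reg, 1900), 1.0)
  tab <- decadal_abundance(mk(4, 2))
  expect_equal(pis_pla(tab, reg, 1900), 2.0)
  tab <- decadal_abundance(mk(3, 0))
  expect_true(is.na(pis_pla(tab, reg, 1900)))

  tab <- decadal_abundance(mk(10, 10, 10))
  expect_equal(inv_fis(tab, reg, 1900), 0.5)
  tab <- decadal_abundance(mk(10, 10, 0))
  expect_equal(inv_fis(tab, reg, 1900), 0.0)
  only_inv <- fixture_items(fixture_item(year = 1900, mentions = "camarão"))
  expect_true(is.na(inv_fis(decadal_abundance(only_inv), reg, 1900)))
})

test_that("the echinoderm switch moves echinoderms out of the numerator", {
  reg <- fixture_registry()
  it <- fixture_items(
    fixture_item(item_id = "i1", year = 1900, mentions = "camarão|ouriço"),
    fixture_item(item_id = "i2", year = 1900, mentions = "anchova")
  )
  tab <- decadal_abundance(it)
  expect_equal(inv_fis(tab, reg, 1900, include_echinoderms = TRUE), 2.0)
  expect_equal(inv_fis(tab, reg, 1900, include_echinoderms = FALSE), 1.0)
})

test_that("gear rolls up to standard categories with the per-item cap", {
  gm <- tibble::tibble(
    raw_gear = c("rede de espera", "rede alta", "rede de fundo", "tarrafa"),
    standard_category = c("rede", "rede", "rede", "tarrafa")
  )
  it <- fixture_items(
    fixture_item(item_id = "i1", year = 1900, gear = "Rede de Espera"),
    fixture_item(item_id = "i2", year = 1900, gear = "rede alta|rede alta"),
    fixture_item(item_id = "i3", year = 1910, gear = "rede de fundo"),
    fixture_item(item_id = "i4", year = 1910, gear = "zangarilho")
  )
  gs <- gear_summary(it, gm)
  rede <- gs$by_category[gs$by_category$category == "rede", ]
  expect_equal(rede$frequency, 3L)
  expect_equal(rede$richness, 3L)
  expect_equal(gs$unmapped, "zangarilho")
  expect_equal(gs$overall$frequency, 4L)

  none <- gear_summary(fixture_items(fixture_item(gear = "")), gm)
  expect_equal(none$overall$frequency, 0L)
})

test_that("gear summary matches a brute-force recount", {
  for (seed in 1:5) {
    cfg <- synthetic_config(seed = seed, decades = seq(1900, 1930, 10),
                            items_per_decade = rep(30L, 4),
                            newspapers_per_decade = rep(8L, 4))
    inc <- filter_items(generate_corpus(cfg)$items)$included
    gs <- gear_summary(inc)
    brute <- brute_decadal_counts(inc, type = "gear")
    expect_equal(gs$overall$frequency, sum(brute$count))
    expect_equal(gs$overall$richness, length(unique(brute$key)))
  }
})
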