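test_that("sampled parameters stay inside their printed ranges", {
  for (seed in 1:200) {
    p <- sample_params(seed = seed)
    expect_true(p$supply_rate >= 0.1 && p$supply_rate <= 1.0)
    expect_true(p$resource_diversity >= 1 && p$resource_diversity <= 10)
    expect_true(all(p$lock_key_prob >= 0.01 & p$lock_key_prob <= 1.0))
    expect_true(p$necromass_value >= 1 && p$necromass_value <= 100)
    expect_true(p$immigration_rate >= 0.01 && p$immigration_rate <= 0.1)
    expect_true(p$logseries_alpha >= 0.95 && p$logseries_alpha <= 0.99)
  }
})

test_that("space-time equivalency constants are fixed", {
  p <- sample_params(seed = 1)
  expect_equal(p$domain_length, 36 * 1200)
  expect_equal(p$domain_length, 43200)
  expect_equal(p$seconds_per_step, 1200)
  expect_equal(p$quota_max_diameter, 1.25)
  expect_equal(p$chemotaxis_cost_mult, 2)
})

test_that("parameter sampling is reproducible and overridable", {
  expect_identical(sample_params(seed = 7), sample_params(seed = 7))
  p <- sample_params(seed = 7, overrides = list(immigration_rate = 0))
  expect_equal(p$immigration_rate, 0)
  expect_error(sample_params(seed = 7, overrides = list(bogus = 1)),
               "unknown parameter")
})

test_that("flat text configuration files override sampled parameters", {
  cfgfile <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("seed: 12", "regime: 5", "supply_rate: 0.4",
               "immigration_rate: 0"), cfgfile)
  cfg <- read_config(cfgfile)
  expect_equal(cfg$seed, 12)
  expect_equal(cfg$regime, regime_from_index(5))
  p <- sample_params(seed = cfg$seed, overrides = cfg$overrides)
  expect_equal(p$supply_rate, 0.4)
  expect_equal(p$immigration_rate, 0)
  # four-token regime spelling and bad keys
  writeLines("regime: scavenging/lock_and_key/chemotaxis/structured", cfgfile)
  expect_equal(read_config(cfgfile)$regime$trophic, "scavenging")
  writeLines("supplyrate: 1", cfgfile)
  expect_error(read_config(cfgfile), "unknown configuration key")
})

test_that("species traits are sampled inside Table ranges, reproducibly", {
  su <- tiny_setup(seed = 3, S = 150)
  tab <- su$traits$table
  expect_equal(nrow(tab), 150)
  expect_true(all(tab$maintenance >= 0.001 & tab$maintenance <= 0.01))
  expect_true(all(tab$dispersal_frac >= 0.01 & tab$dispersal_frac <= 1.0))
  expect_true(all(tab$growth_rate >= 0.1 & tab$growth_rate <= 1.0))
  expect_true(all(tab$resuscitation >= 0.001 & tab$resuscitation <= 0.01))
  expect_true(all(tab$maint_reduction >= 10 & tab$maint_reduction <= 100))
  expect_true(all(tab$consumption_rate >= 0.1 & tab$consumption_rate <= 1.0))
  again <- sample_species_traits(150, su$regime, su$params, seed = 1003L)
  expect_identical(su$traits, again)
  expect_error(sample_species_traits(0, su$regime, su$params), ">= 1")
})

test_that("resource use reflects the regime: monoculture, polyculture, scavenging", {
  p <- sample_params(seed = 5)
  mono <- sample_species_traits(40, regime(resource = "monoculture_labile"),
                                p, seed = 9)
  expect_true(all(mono$consumable[, 1]))
  expect_true(all(!mono$consumable[, 2:11]))

  poly <- sample_species_traits(
    40, regime(resource = "polyculture_labile"), p, seed = 9)
  types <- supplied_types(regime(resource = "polyculture_labile"), p)
  expect_gte(length(types), 2)
  # each species specializes on exactly one supplied type
  expect_true(all(rowSums(poly$consumable[, types, drop = FALSE]) == 1))
  expect_true(all(!poly$consumable[, 11]))

  scav <- sample_species_traits(
    40, regime(trophic = "scavenging"), p, seed = 9)
  expect_true(all(scav$consumable[, 11]))
})

test_that("cross-feeding assigns products outside a species' own diet", {
  p <- sample_params(seed = 11)
  for (troph in c("crossfeed_oneway", "crossfeed_twoway")) {
    tr <- sample_species_traits(
      60, regime(trophic = troph, resource = "polyculture_labile"),
      p, seed = 13)
    prod <- tr$product
    has <- !is.na(prod)
    expect_true(any(has))
    # no species produces a metabolite it can itself consume
    expect_true(all(!tr$consumable[cbind(which(has), prod[has])]))
  }
  # one-way avoids reciprocal producer-consumer loops
  tr1 <- sample_species_traits(
    60, regime(trophic = "crossfeed_oneway", resource = "polyculture_labile"),
    p, seed = 13)
  mutual <- 0L
  for (s in which(!is.na(tr1$product))) {
    eaters <- which(tr1$consumable[, tr1$product[s]])
    back <- eaters[!is.na(tr1$product[eaters])]
    mutual <- mutual +
      sum(tr1$consumable[s, tr1$product[back]], na.rm = TRUE)
  }
  expect_equal(mutual, 0L)
})

test_that("dormancy presets set the printed trait values and nothing else", {
  su <- tiny_setup(seed = 2)
  strong <- scenario_presets(su$traits, "strong_dormancy")
  expect_true(all(strong$table$maint_reduction == 100))
  expect_true(all(strong$table$resuscitation == 0.001))
  weak <- scenario_presets(su$traits, "weak_dormancy")
  expect_true(all(weak$table$maint_reduction == 10))
  expect_true(all(weak$table$resuscitation == 0.1))
  # untouched columns identical
  for (col in c("maintenance", "dispersal_frac", "growth_rate",
                "consumption_rate")) {
    expect_identical(strong$table[[col]], su$traits$table[[col]])
    expect_identical(weak$table[[col]], su$traits$table[[col]])
  }
  expect_identical(strong$consumable, su$traits$consumable)
  expect_error(scenario_presets(su$traits, "medium"), "arg")
})
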