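# Expansion engine: closed-form toys, determinism, caps, saturation,
# monotonicity under rule addition.

test_that("chain-growth toy matches its closed form across caps", {
  for (cap in c(60L, 100L, 130L, 200L)) {
    toy <- make_toy_system("chain_growth", cap = cap)
    net <- expand(toy$config)
    sp <- net$species[!net$species$ubiquitous, ]
    expect_identical(nrow(sp), toy$expected$n_species)
    expect_identical(sort(sp$mass), toy$expected$species_masses)
    expect_identical(length(net$events), as.integer(toy$expected$n_events))
    expect_identical(saturation_generation(net), toy$expected$saturation)
  }
})

test_that("novelty counts partition the network", {
  toy <- make_toy_system("chain_growth", cap = 100L)
  net <- expand(toy$config)
  nc <- novel_counts(net)
  expect_identical(nc$new_species, c(1L, 1L, 0L))
  expect_identical(nc$new_events, c(1L, 1L, 0L))
  # totals: new species + seeds = species table; new events = event list
  expect_identical(sum(nc$new_species) +
                     sum(net$species$first_generation == 0L &
                           !net$species$ubiquitous),
                   sum(!net$species$ubiquitous))
  expect_identical(sum(nc$new_events), length(net$events))
})

test_that("empty rule lists give a seeds-only network", {
  cfg <- expansion_config(c("C=O", "O"), list(), max_generations = 3L,
                          mass_cap = 100L)
  net <- expand(cfg)
  expect_length(net$events, 0L)
  expect_identical(nrow(net$species), 2L)
  expect_true(all(net$species$first_generation == 0L))
})

test_that("a cap below a seed is a configuration error", {
  expect_error(expansion_config("OCC(O)C(O)C(O)C(O)C=O", list(),
                                max_generations = 1L, mass_cap = 100L),
               "config error.*exceeds mass cap")
})

test_that("expansion is deterministic and seed-order invariant", {
  toy <- cached_toy("iron_shortcut")
  n1 <- expand(toy$config_iron)
  n2 <- expand(toy$config_iron)
  expect_identical(n1$species, n2$species)
  expect_identical(n1$events, n2$events)
  seeds_rev <- rev(toy$config_iron$seeds)
  n3 <- expand(expansion_config(seeds_rev, toy$config_iron$rules,
                                toy$config_iron$max_generations,
                                toy$config_iron$mass_cap))
  expect_true(isTRUE(networks_equal(n1, n3)))
  expect_identical(novel_counts(n1)[, c("new_species", "new_events")],
                   novel_counts(n3)[, c("new_species", "new_events")])
})

test_that("re-expanding past saturation is a no-op", {
  toy <- make_toy_system("chain_growth", cap = 100L)
  net <- expand(toy$config)
  cfg_more <- expansion_config(toy$config$seeds, toy$config$rules,
                               toy$config$max_generations + 5L,
                               toy$config$mass_cap)
  net_more <- expand(cfg_more)
  expect_true(isTRUE(networks_equal(net, net_more)))
  expect_identical(saturation_generation(net_more), 3L)
})

test_that("a network stopped before novelty ceases has no saturation generation", {
  toy <- make_toy_system("chain_growth", cap = 100L, generations = 2L)
  expect_true(is.na(saturation_generation(expand(toy$config))))
})

test_that("rule and ionic-seed addition only ever grows the network", {
  for (p in names(preset_run_scales)) {
    nf <- cached_net(p, FALSE)
    ni <- cached_net(p, TRUE)
    m <- match(nf$species$id, ni$species$id)
    expect_false(anyNA(m))  # species(free) subset of species(iron)
    expect_true(all(ni$species$first_generation[m] <=
                      nf$species$first_generation))
    keys_f <- vapply(nf$events, feronet:::event_key, "")
    keys_i <- vapply(ni$events, feronet:::event_key, "")
    expect_true(all(keys_f %in% keys_i))
  }
})

test_that("per-generation novelty is non-decreasing over the computed range", {
  for (p in names(preset_run_scales)) {
    for (iron in c(FALSE, TRUE)) {
      nc <- novel_counts(cached_net(p, iron))
      expect_true(all(diff(nc$new_species) >= 0))
      expect_true(all(diff(nc$new_events) >= 0))
    }
  }
})

test_that("every product in every preset run respects the mass cap", {
  for (p in names(preset_run_scales)) {
    net <- cached_net(p, TRUE)
    expect_lte(max(net$species$mass), net$config$mass_cap)
  }
})

test_that("the species guard aborts runaway expansions cleanly", {
  cfg <- preset_config("formose", TRUE, generations = 4L, mass_cap = 100L)
  cfg$max_species <- 20
  expect_error(expand(cfg), class = "crn_abort")
  expect_error(expand(cfg), "species limit exceeded")
})
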