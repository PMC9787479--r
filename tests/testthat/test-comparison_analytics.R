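# Comparison analytics: catalysis definition, frequencies, degrees, growth.

fake_net <- function(ids, gens, events = list(), ubiq = NULL,
                     rules = character(0)) {
  if (is.null(ubiq)) ubiq <- rep(FALSE, length(ids))
  structure(list(
    species = data.frame(id = ids, formula = ids, mass = 1L, charge = 0L,
                         ubiquitous = ubiq, first_generation = gens,
                         stringsAsFactors = FALSE),
    events = events,
    per_generation = data.frame(generation = integer(0),
                                new_species = integer(0),
                                new_events = integer(0)),
    saturated_at = NA_integer_,
    config = list(rules = stats::setNames(vector("list", length(rules)),
                                          rules))
  ), class = "crn_network")
}

test_that("catalyzed species are exactly the strictly-earlier overlap", {
  free <- fake_net(c("A", "B", "C"), c(0L, 4L, 2L))
  iron <- fake_net(c("A", "B", "C", "D"), c(0L, 2L, 2L, 1L))
  tab <- catalyzed_species(free, iron)
  expect_identical(tab$id, "B")          # equal generations and iron-only
  expect_identical(tab$gen_free, 4L)     # species are excluded
  expect_identical(tab$gen_iron, 2L)
  expect_identical(nrow(catalyzed_species(free, free)), 0L)
  expect_equal(percent_catalysis(free, iron), 100 / 3)
})

test_that("catalysis percentages reproduce the published derived values", {
  tab <- reported_table("catalysis")
  prod <- reported_table("products")
  stopifnot(identical(tab$network, prod$network))
  raw <- 100 * tab$catalyzed / prod$iron_free
  # printed at mixed precision (7%, 8.4%, 3%, 1.1%)
  expect_true(all(abs(raw - tab$printed_percent) <= 0.5))
  expect_identical(format_percent_catalysis(raw[tab$network == "formose"]),
                   "7%")
  expect_identical(format_percent_catalysis(raw[tab$network == "maillard"]),
                   "1.1%")
  expect_identical(format_percent_catalysis(0), "0.0%")
})

test_that("frequency change follows the printed convention, not the caption formula", {
  expect_identical(frequency_change(12, 54), 350L)
  expect_identical(frequency_change(242, 417), 72L)
  expect_identical(frequency_change(0, 187), "-")
  # spot-check every published formose row at integer rounding
  tab <- reported_table("formose_rules")
  for (i in which(tab$iron_free > 0)) {
    expect_identical(frequency_change(tab$iron_free[i], tab$iron_containing[i]),
                     as.integer(tab$printed_percent_change[i]))
  }
})

test_that("degree metrics count event slots with multiplicity", {
  ev <- list(rule = "r", iron = FALSE, generation = 1L,
             reactants = c("A", "B"), products = "C")
  net <- fake_net(c("A", "B", "C"), c(0L, 0L, 1L), events = list(ev),
                  rules = "r")
  d <- degree_metrics(net)
  rownames(d) <- d$id
  expect_identical(d["A", "out_degree"], 1L)
  expect_identical(d["B", "out_degree"], 1L)
  expect_identical(d["C", "in_degree"], 1L)
  expect_identical(sum(d$in_degree), 1L)
  expect_identical(sum(d$out_degree), 2L)

  # catalytic participant gains one in- and one out-edge
  toy <- cached_toy("iron_shortcut")
  di <- degree_metrics(expand(toy$config_iron))
  fe3 <- di[di$id == "[Fe+3]", ]
  expect_identical(fe3$in_degree, 1L)
  expect_identical(fe3$out_degree, 1L)
})

test_that("degree and frequency sums are conserved across preset runs", {
  for (p in c("formose", "pyruvic")) {
    for (iron in c(FALSE, TRUE)) {
      net <- cached_net(p, iron)
      d <- degree_metrics(net)
      expect_identical(sum(d$in_degree),
                       sum(lengths(lapply(net$events, `[[`, "products"))))
      expect_identical(sum(d$out_degree),
                       sum(lengths(lapply(net$events, `[[`, "reactants"))))
      rf <- rule_frequency(net)
      expect_identical(sum(rf$events), length(net$events))
    }
  }
})

test_that("rule frequencies are zero on a seeds-only network and total on a one-rule network", {
  cfg <- expansion_config(c("C=O", "O"), list(), 2L, 100L)
  net <- expand(cfg)
  expect_identical(sum(rule_frequency(net)$events), 0L)
  toy <- make_toy_system("chain_growth", cap = 100L)
  net2 <- expand(toy$config)
  rf <- rule_frequency(net2)
  expect_identical(rf$events[rf$rule == "Aldose Chain Extension"],
                   length(net2$events))
})

test_that("growth fitting recovers exact geometric series and flags extrapolation bias", {
  fit <- growth_fit(c(10, 100, 1000))
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$fold_per_generation, 10, tolerance = 1e-10)
  flat <- growth_fit(c(7, 7, 7), project = 10L)
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_equal(flat$projection$projected, 7, tolerance = 1e-10)
  expect_error(growth_fit(c(5)), "at least two")
  expect_error(growth_fit(c(0, 10)), "positive")

  # projecting the saturating chain toy beyond its cap overestimates truth
  toy <- make_toy_system("chain_growth", cap = 100L)
  cs <- cumulative_species(expand(toy$config))
  cs <- cs[cs$species > 0 & cs$generation <= 2, ]
  proj <- growth_fit(cs, project = 5L)$projection$projected
  expect_gt(proj, 3)   # the true saturated count
})

test_that("compare_networks assembles a coherent report", {
  toy <- cached_toy("iron_shortcut")
  cmp <- compare_networks(expand(toy$config), expand(toy$config_iron))
  expect_s3_class(cmp, "crn_comparison")
  expect_identical(nrow(cmp$catalyzed), 1L)
  expect_identical(cmp$percent_catalysis_printed, "20%")
  rfc <- cmp$rule_frequencies
  iron_only <- rfc$rule == "Glyceraldehyde to Lactic Acid (Fe3+ catalytic)"
  expect_identical(rfc$percent_change[iron_only], "-")
  expect_identical(rfc$events_free[iron_only], 0L)
})
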