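# Shipped preset libraries and seed sets.

test_that("library sizes match the modeled rule counts", {
  expect_length(get_rule_set("formose", with_iron = FALSE), 32L)
  expect_length(get_rule_set("formose", with_iron = TRUE), 39L)
  expect_length(get_rule_set("pyruvic", with_iron = FALSE), 31L)
  expect_length(get_rule_set("pyruvic", with_iron = TRUE), 38L)
  expect_length(get_rule_set("glucose_degradation", with_iron = TRUE), 38L)
  expect_length(get_rule_set("maillard", with_iron = FALSE), 37L)
})

test_that("seed sets match the modeled input reactants", {
  ids <- function(x) sort(vapply(x, function(s) s$canonical_id, ""))
  can <- function(v) sort(vapply(v, function(s)
    parse_and_canonicalize(s)$canonical_id, "", USE.NAMES = FALSE))
  ions <- c("[Fe+2]", "[Fe+3]", "[H+]", "[OH-]")
  expect_identical(ids(get_seed_set("formose")), can(c("C=O", "O")))
  expect_identical(ids(get_seed_set("formose", TRUE)),
                   can(c("C=O", "O", ions)))
  expect_identical(ids(get_seed_set("pyruvic")),
                   can(c("CC(=O)C(=O)O", "O")))
  expect_identical(ids(get_seed_set("maillard")),
                   can(c("NCC(=O)O", "OCC(O)C(O)C(O)C(O)C=O", "O")))
  expect_identical(ids(get_seed_set("glucose_degradation", TRUE)),
                   can(c("OCC(O)C(O)C(O)C(O)C=O", "O", ions)))
})

test_that("iron variants differ only by added ionic seeds and iron rules", {
  for (p in preset_names()) {
    expect_true(check_preset_containment(p))
    extra <- setdiff(names(get_rule_set(p, TRUE)), names(get_rule_set(p, FALSE)))
    expect_length(extra, 7L)   # the seven iron-induced mechanisms
  }
})

test_that("shipped formose library covers every published rule name", {
  tab <- reported_table("formose_rules")
  lib <- get_rule_set("formose", with_iron = TRUE)
  expect_true(all(tab$rule %in% names(lib)))
  iron_named <- tab$rule[tab$iron_free == 0]
  expect_length(iron_named, 7L)
  expect_true(all(vapply(lib[iron_named], function(r) r$iron_dependent, TRUE)))
})

test_that("unknown presets fail naming the alternatives", {
  expect_error(get_seed_set("formosa"), "unknown preset.*formose")
})
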