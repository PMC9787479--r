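# Rule engine: library loading and validation, embedding enumeration,
# application, conservation.

rule_doc_minimal <- function(name = "Test Hydration") {
  list(
    name = name,
    iron_dependent = FALSE,
    reactants = list(
      list(atoms = list(list(id = "c1", elem = "C"),
                        list(id = "o1", elem = "O")),
           bonds = list(list("c1", "o1", 2))),
      list(exact = "O", ids = list("ow"))
    ),
    transform = list(
      bonds = list(list("c1", "o1", 1), list("c1", "ow", 1)),
      hydrogens = list(list("o1", 1), list("ow", -1))
    )
  )
}

test_that("rule libraries load, validate and round-trip through YAML", {
  lib <- get_rule_set("formose", with_iron = TRUE)
  expect_length(lib, 39L)
  expect_true(all(vapply(lib, inherits, TRUE, "crn_rule")))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rule_library(lib, path)
  lib2 <- load_rule_library(path)
  expect_identical(names(lib2), names(lib))
  for (nm in names(lib)) {
    expect_identical(lib2[[nm]]$bond_edits, lib[[nm]]$bond_edits)
    expect_identical(lib2[[nm]]$h_edits, lib[[nm]]$h_edits)
    expect_identical(lib2[[nm]]$iron_dependent, lib[[nm]]$iron_dependent)
  }
})

test_that("malformed libraries are rejected at load", {
  d <- rule_doc_minimal()
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(rules = list(d, d)), path)
  expect_error(load_rule_library(path), "duplicate rule name")

  bad_h <- d
  bad_h$transform$hydrogens <- list(list("o1", 1))  # net +1 H from nowhere
  expect_error(feronet:::load_rule(bad_h), "hydrogen not conserved")

  bad_q <- d
  bad_q$coagents <- list(consumed = list("[H+]" = 1))
  bad_q$transform$hydrogens <- list(list("o1", 2), list("ow", -1))
  expect_error(feronet:::load_rule(bad_q), "charge not conserved")

  bad_ref <- d
  bad_ref$transform$bonds <- list(list("c1", "zz", 1))
  expect_error(feronet:::load_rule(bad_ref), "unknown atom id")

  bad_del <- d
  bad_del$transform$bonds <- list(list("c1", "ow", 0))
  expect_error(feronet:::load_rule(bad_del), "absent from L")
})

test_that("aldol embeddings over glycolaldehyde + formaldehyde yield glyceraldehyde", {
  lib <- get_rule_set("formose")
  pool <- lapply(c("OCC=O", "C=O"), parse_and_canonicalize)
  embs <- find_embeddings(lib[["Aldol Condensation"]], pool)
  expect_gt(length(embs), 0L)
  prods <- unlist(lapply(embs, function(e) {
    ev <- apply_rule(lib[["Aldol Condensation"]], e, pool)
    if (is.null(ev)) character(0) else ev$products
  }))
  expect_true(parse_and_canonicalize("OCC(O)C=O")$canonical_id %in% prods)
})

test_that("iron rules find no embeddings without their iron co-agent", {
  lib <- get_rule_set("formose", with_iron = TRUE)
  rule <- lib[["Fe+3 to Fe+2, Aldehyde to acid"]]
  pool_no_fe <- lapply(c("C=O", "O"), parse_and_canonicalize)
  expect_length(find_embeddings(rule, pool_no_fe), 0L)
  pool_fe <- lapply(c("C=O", "O", "[Fe+3]"), parse_and_canonicalize)
  expect_gt(length(find_embeddings(rule, pool_fe)), 0L)
})

test_that("embeddings are deduplicated up to rule automorphisms", {
  # symmetric two-aldehyde coupling whose edit set is swap-invariant
  sym <- feronet:::load_rule(list(
    name = "Symmetric Coupling",
    reactants = list(
      list(atoms = list(list(id = "c1", elem = "C", minH = 1),
                        list(id = "o1", elem = "O")),
           bonds = list(list("c1", "o1", 2))),
      list(atoms = list(list(id = "c2", elem = "C", minH = 1),
                        list(id = "o2", elem = "O")),
           bonds = list(list("c2", "o2", 2)))
    ),
    transform = list(
      bonds = list(list("c1", "c2", 1), list("c1", "o1", 1),
                   list("c2", "o2", 1)),
      hydrogens = list(list("c1", -1), list("o1", 1),
                       list("c2", -1), list("o2", 1))
    )
  ))
  expect_gte(length(sym$autos), 2L)
  pool1 <- list(parse_and_canonicalize("C=O"))
  embs <- find_embeddings(sym, pool1)
  expect_length(embs, 1L)   # the two ordered assignments are one embedding
  # ordered slot assignments over two aldehydes: HH, HA, AH, AA; the swap
  # symmetry folds HA/AH together
  pool2 <- lapply(c("C=O", "CC=O"), parse_and_canonicalize)
  expect_length(find_embeddings(sym, pool2), 3L)

  # an asymmetric rule keeps both orders: Cannizzaro on two different
  # aldehydes gives two chemically distinct events
  lib <- get_rule_set("formose")
  pool3 <- lapply(c("C=O", "CC=O", "O"), parse_and_canonicalize)
  evs <- Filter(Negate(is.null), lapply(
    find_embeddings(lib[["Canizzaro"]], pool3),
    function(e) apply_rule(lib[["Canizzaro"]], e, pool3)))
  keys <- unique(vapply(evs, feronet:::event_key, ""))
  expect_gte(length(keys), 2L)
})

test_that("iron redox application: aldehyde oxidation by two Fe(III)", {
  lib <- get_rule_set("formose", with_iron = TRUE)
  rule <- lib[["Fe+3 to Fe+2, Aldehyde to acid"]]
  pool <- lapply(c("C=O", "O", "[Fe+3]"), parse_and_canonicalize)
  embs <- find_embeddings(rule, pool)
  expect_length(embs, 1L)
  ev <- apply_rule(rule, embs[[1]], pool)
  formic <- parse_and_canonicalize("OC=O")$canonical_id
  expect_identical(sort(ev$reactants),
                   sort(c("C=O", "O", "[Fe+3]", "[Fe+3]")))
  expect_identical(sort(ev$products),
                   sort(c(formic, "[Fe+2]", "[Fe+2]", "[H+]", "[H+]")))
  expect_true(ev$iron)
})

test_that("catalytic Fe(III) appears unchanged on both sides", {
  toy <- cached_toy("iron_shortcut")
  rule <- toy$config_iron$rules[["Glyceraldehyde to Lactic Acid (Fe3+ catalytic)"]]
  pool <- lapply(c("OCC(O)C=O", "[Fe+3]"), parse_and_canonicalize)
  embs <- find_embeddings(rule, pool)
  expect_length(embs, 1L)
  ev <- apply_rule(rule, embs[[1]], pool)
  lactic <- parse_and_canonicalize("CC(O)C(=O)O")$canonical_id
  expect_true(lactic %in% ev$products)
  expect_true("[Fe+3]" %in% ev$reactants && "[Fe+3]" %in% ev$products)
})

test_that("Cannizzaro disproportionates two formaldehydes into methanol and formic acid", {
  lib <- get_rule_set("formose")
  pool <- lapply(c("C=O", "O"), parse_and_canonicalize)
  evs <- Filter(Negate(is.null), lapply(
    find_embeddings(lib[["Canizzaro"]], pool),
    function(e) apply_rule(lib[["Canizzaro"]], e, pool)))
  expect_length(evs, 1L)
  methanol <- parse_and_canonicalize("CO")$canonical_id
  formic <- parse_and_canonicalize("OC=O")$canonical_id
  expect_true(all(c(methanol, formic) %in% evs[[1]]$products))
})

test_that("valence-impossible edits are rejected as non-matches", {
  over <- feronet:::load_rule(list(
    name = "Protonation (impossible on methane)",
    reactants = list(
      list(atoms = list(list(id = "c1", elem = "C")), bonds = list())
    ),
    coagents = list(consumed = list("[H+]" = 1)),
    transform = list(hydrogens = list(list("c1", 1)),
                     charges = list(list("c1", 1)))
  ))
  pool <- lapply(c("C", "[H+]"), parse_and_canonicalize)  # methane is full
  embs <- find_embeddings(over, pool)
  expect_length(embs, 1L)
  expect_null(apply_rule(over, embs[[1]], pool))
})
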