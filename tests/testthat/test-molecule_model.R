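# Molecule model: parsing, canonical identity, formulas, nominal masses.

test_that("canonicalization maps equivalent notations to one id and is idempotent", {
  cases <- list(
    c("C=O", "O=C"),                                  # formaldehyde
    c("OCC(O)C=O", "O=CC(O)CO", "C(C=O)(O)CO"),       # glyceraldehyde
    c("CC(=O)C(=O)O", "OC(=O)C(C)=O"),                # pyruvic acid
    c("NCC(=O)O", "C(N)C(=O)O"),                      # glycine
    c("OC1OCCC1", "C1(O)OCCC1")                       # cyclic hemiacetal
  )
  for (grp in cases) {
    ids <- vapply(grp, function(s) parse_and_canonicalize(s)$canonical_id, "")
    expect_length(unique(ids), 1L)
    # idempotent: re-canonicalizing the canonical id is a fixed point
    expect_identical(parse_and_canonicalize(ids[[1]])$canonical_id, ids[[1]])
  }
  expect_false(parse_and_canonicalize("C=O")$canonical_id ==
                 parse_and_canonicalize("CO")$canonical_id)
})

test_that("formulas, nominal masses and charges are correct", {
  gly <- parse_and_canonicalize("OCC(O)C=O")
  expect_identical(gly$formula[["C"]], 3L)
  expect_identical(gly$formula[["H"]], 6L)
  expect_identical(gly$formula[["O"]], 3L)
  expect_identical(nominal_mass(gly), 90L)

  expect_identical(nominal_mass(parse_and_canonicalize("O")), 18L)
  expect_identical(nominal_mass(parse_and_canonicalize("OCC(O)C(O)C(O)C(O)C=O")),
                   180L)
  expect_identical(nominal_mass(parse_and_canonicalize("CC(=O)C(=O)O")), 88L)

  fe2 <- parse_and_canonicalize("[Fe+2]")
  fe3 <- parse_and_canonicalize("[Fe+3]")
  expect_identical(fe2$net_charge, 2L)
  expect_identical(fe3$net_charge, 3L)
  expect_false(fe2$canonical_id == fe3$canonical_id)
  expect_true(fe2$is_ubiquitous && fe3$is_ubiquitous)
  expect_identical(parse_and_canonicalize("[OH-]")$net_charge, -1L)
  expect_false(parse_and_canonicalize("NCC(=O)O")$is_ubiquitous)
})

test_that("mass cap predicate follows nominal mass", {
  glucose <- parse_and_canonicalize("OCC(O)C(O)C(O)C(O)C=O")
  expect_true(within_mass_cap(glucose, 200))
  expect_false(within_mass_cap(glucose, 100))
  for (p in preset_names()) {
    for (s in get_seed_set(p, with_iron = TRUE))
      expect_true(within_mass_cap(s, 200))
  }
})

test_that("malformed and unsupported inputs fail with informative errors", {
  expect_error(parse_and_canonicalize("C(("), "malformed")
  expect_error(parse_and_canonicalize("C1CC"), "ring")
  expect_error(parse_and_canonicalize("CS"), "unsupported element")
  expect_error(parse_and_canonicalize("[Na+]"), "unsupported element")
  expect_error(parse_and_canonicalize("C(C)(C)(C)(C)C"), "valence")
  expect_error(parse_and_canonicalize("CC.O"), "malformed|unexpected")
})

test_that("every species of a generated network round-trips through its id", {
  toy <- cached_toy("iron_shortcut")
  net <- expand(toy$config_iron)
  for (id in net$species$id) {
    expect_identical(parse_and_canonicalize(id)$canonical_id, id)
  }
})

test_that("canonical equivalence classes agree with OpenBabel", {
  smiles <- c("C=O", "O=C", "OCC(O)C=O", "C(C=O)(O)CO", "CC(=O)C(=O)O",
              "OC(=O)C(C)=O", "CO", "OC", "C(O)C=O", "OCC=O",
              "OC1OCCC1", "C1(O)OCCC1", "CC=O", "C=CO")
  mine <- vapply(smiles, function(s)
    parse_and_canonicalize(s)$canonical_id, "")
  theirs <- vapply(smiles, function(s)
    trimws(ChemmineOB::convertFormat("SMI", "CAN", source = s)), "")
  # same partition of the input set into identity classes
  expect_identical(outer(mine, mine, "=="), outer(theirs, theirs, "=="))
})
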