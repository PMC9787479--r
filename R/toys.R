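# Toy systems with analytically known networks.
#
# Three parameterized fixtures exercise the full engine (real molecules, so
# the whole canonicalization path is used) while keeping expected results in
# closed form:
#
# * chain_growth: formaldehyde inserts into an aldose terminus
#   (R-CHO + HCHO -> R-CH(OH)-CHO), so the reachable species are exactly the
#   linear aldoses of mass 30*n <= cap: floor(cap/30) species, one new
#   species and one new event per generation, saturation at generation
#   floor(cap/30).
# * reversible_pair: acetaldehyde <-> vinyl alcohol via explicit
#   enolization/ketonization rules; 2 species, 2 events, saturation at 3.
# * iron_shortcut: glyceraldehyde reaches lactic acid in 3 iron-free steps
#   (dehydration to pyruvaldehyde, aldehyde hydration, intramolecular hydride
#   shift) or in 1 step with catalytic Fe3+ (the classic iron(III)-mediated
#   glyceraldehyde -> lactic acid conversion), so lactic acid is "catalyzed":
#   first generation 3 without iron, 1 with iron.

.toy_rule_docs <- list(
  chain_extension = list(
    name = "Aldose Chain Extension",
    iron_dependent = FALSE,
    reactants = list(
      list(atoms = list(list(id = "c1", elem = "C", minH = 1),
                        list(id = "o1", elem = "O")),
           bonds = list(list("c1", "o1", 2))),
      list(exact = "C=O", ids = list("c2", "o2"))
    ),
    transform = list(
      bonds = list(list("c1", "c2", 1), list("c1", "o1", 1)),
      hydrogens = list(list("o1", 1), list("c2", -1))
    ),
    combine_slack = 0
  ),
  enolization = list(
    name = "Enolization",
    iron_dependent = FALSE,
    reactants = list(
      list(atoms = list(list(id = "c1", elem = "C", minH = 1),
                        list(id = "c2", elem = "C"),
                        list(id = "o2", elem = "O")),
           bonds = list(list("c1", "c2", 1), list("c2", "o2", 2)))
    ),
    transform = list(
      bonds = list(list("c1", "c2", 2), list("c2", "o2", 1)),
      hydrogens = list(list("c1", -1), list("o2", 1))
    )
  ),
  ketonization = list(
    name = "Ketonization",
    iron_dependent = FALSE,
    reactants = list(
      list(atoms = list(list(id = "c1", elem = "C"),
                        list(id = "c2", elem = "C"),
                        list(id = "o2", elem = "O", minH = 1)),
           bonds = list(list("c1", "c2", 2), list("c2", "o2", 1)))
    ),
    transform = list(
      bonds = list(list("c1", "c2", 1), list("c2", "o2", 2)),
      hydrogens = list(list("c1", 1), list("o2", -1))
    ),
    inverse_of = "Enolization"
  ),
  dehydration = list(
    name = "Dehydration to Carbonyl",
    iron_dependent = FALSE,
    reactants = list(
      list(atoms = list(list(id = "c1", elem = "C", minH = 1),
                        list(id = "o1", elem = "O", minH = 1),
                        list(id = "c2", elem = "C"),
                        list(id = "o2", elem = "O", minH = 1)),
           bonds = list(list("c1", "o1", 1), list("c1", "c2", 1),
                        list("c2", "o2", 1)))
    ),
    transform = list(
      bonds = list(list("c2", "o2", 0), list("c1", "o1", 2)),
      hydrogens = list(list("o2", 1), list("o1", -1),
                       list("c1", -1), list("c2", 1))
    )
  ),
  ketoaldehyde_hydration = list(
    name = "Ketoaldehyde Hydration",
    iron_dependent = FALSE,
    reactants = list(
      list(atoms = list(list(id = "c3", elem = "C"),
                        list(id = "o3", elem = "O"),
                        list(id = "c1", elem = "C", minH = 1),
                        list(id = "o1", elem = "O")),
           bonds = list(list("c3", "o3", 2), list("c3", "c1", 1),
                        list("c1", "o1", 2))),
      list(exact = "O", ids = list("ow"))
    ),
    transform = list(
      bonds = list(list("c1", "ow", 1), list("c1", "o1", 1)),
      hydrogens = list(list("ow", -1), list("o1", 1))
    )
  ),
  hydride_shift = list(
    name = "Dicarbonyl Hydride Shift",
    iron_dependent = FALSE,
    reactants = list(
      list(atoms = list(list(id = "c3", elem = "C"),
                        list(id = "o3", elem = "O"),
                        list(id = "c1", elem = "C", minH = 1),
                        list(id = "o1", elem = "O", minH = 1),
                        list(id = "o2", elem = "O", minH = 1)),
           bonds = list(list("c3", "o3", 2), list("c3", "c1", 1),
                        list("c1", "o1", 1), list("c1", "o2", 1)))
    ),
    transform = list(
      bonds = list(list("c1", "o1", 2), list("c3", "o3", 1)),
      hydrogens = list(list("c1", -1), list("c3", 1),
                       list("o1", -1), list("o3", 1))
    )
  ),
  fe_glyceraldehyde_lactate = list(
    name = "Glyceraldehyde to Lactic Acid (Fe3+ catalytic)",
    iron_dependent = TRUE,
    reactants = list(
      list(atoms = list(list(id = "c1", elem = "C", minH = 2),
                        list(id = "o1", elem = "O", minH = 1),
                        list(id = "c2", elem = "C", minH = 1),
                        list(id = "o2", elem = "O", minH = 1),
                        list(id = "c3", elem = "C", minH = 1),
                        list(id = "o3", elem = "O")),
           bonds = list(list("c1", "o1", 1), list("c1", "c2", 1),
                        list("c2", "o2", 1), list("c2", "c3", 1),
                        list("c3", "o3", 2)))
    ),
    coagents = list(catalytic = list("[Fe+3]" = 1)),
    transform = list(
      bonds = list(list("c1", "o1", 0), list("c3", "o1", 1)),
      hydrogens = list(list("c1", 1), list("c3", -1))
    )
  )
)

.IRON_SEEDS <- c("[Fe+2]", "[Fe+3]", "[H+]", "[OH-]")

#' Construct a toy reaction system with known expected results
#'
#' @param kind one of `"chain_growth"`, `"reversible_pair"`, `"iron_shortcut"`
#' @param cap mass cap in AMU (chain_growth only; default 100)
#' @param generations generations to run (defaults chosen to reach saturation)
#' @return list with `config` (iron-free [expansion_config()]), `config_iron`
#'   (same system with ionic seeds and any iron rules added) and `expected`,
#'   a list of closed-form expectations for the system
#' @export
make_toy_system <- function(kind = c("chain_growth", "reversible_pair",
                                     "iron_shortcut"),
                            cap = 100L, generations = NULL) {
  kind <- match.arg(kind)
  mk <- function(key) load_rule(.toy_rule_docs[[key]])
  if (kind == "chain_growth") {
    monomer_mass <- 30L
    if (cap < monomer_mass)
      stop("config error: cap below the 30 AMU monomer", call. = FALSE)
    n_expected <- cap %/% monomer_mass
    if (is.null(generations)) generations <- n_expected + 1L
    rules <- list(`Aldose Chain Extension` = mk("chain_extension"))
    seeds <- c("C=O", "O")
    list(
      kind = kind,
      config = expansion_config(seeds, rules, generations, cap),
      config_iron = expansion_config(c(seeds, .IRON_SEEDS), rules,
                                     generations, cap),
      expected = list(
        n_species = n_expected,
        species_masses = monomer_mass * seq_len(n_expected),
        n_events = n_expected - 1L,
        saturation = if (generations >= n_expected) n_expected else NA_integer_
      )
    )
  } else if (kind == "reversible_pair") {
    if (is.null(generations)) generations <- 3L
    rules <- list(Enolization = mk("enolization"),
                  Ketonization = mk("ketonization"))
    seeds <- c("CC=O", "O")
    list(
      kind = kind,
      config = expansion_config(seeds, rules, generations, cap),
      config_iron = expansion_config(c(seeds, .IRON_SEEDS), rules,
                                     generations, cap),
      expected = list(n_species = 2L, n_events = 2L,
                      saturation = if (generations >= 3L) 3L else NA_integer_)
    )
  } else {
    if (is.null(generations)) generations <- 5L
    free_rules <- list(
      `Dehydration to Carbonyl` = mk("dehydration"),
      `Ketoaldehyde Hydration` = mk("ketoaldehyde_hydration"),
      `Dicarbonyl Hydride Shift` = mk("hydride_shift")
    )
    iron_rules <- c(free_rules,
                    list(`Glyceraldehyde to Lactic Acid (Fe3+ catalytic)` =
                           mk("fe_glyceraldehyde_lactate")))
    seeds <- c("OCC(O)C=O", "O")
    lactic <- parse_and_canonicalize("CC(O)C(=O)O")$canonical_id
    list(
      kind = kind,
      config = expansion_config(seeds, free_rules, generations, mass_cap = 200L),
      config_iron = expansion_config(c(seeds, .IRON_SEEDS), iron_rules,
                                     generations, mass_cap = 200L),
      expected = list(
        catalyzed_id = lactic,
        gen_free = 3L, gen_iron = 1L,
        n_species_free = 5L,           # glyceraldehyde, pyruvaldehyde,
                                       # malonaldehyde, hydrate, lactic acid
        percent_catalysis = 20
      )
    )
  }
}

#' Write the toy systems out as ordinary seed and rule files
#'
#' Materializes each toy as a seed list (`.smi`) and rule library (`.yaml`)
#' under `dir`, so the fixtures can be run through the same file-based
#' entry points as the shipped presets.
#' @param dir output directory
#' @export
write_toy_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- list(
    chain_growth = list(seeds = c("C=O", "O"), rules = "chain_extension"),
    reversible_pair = list(seeds = c("CC=O", "O"),
                           rules = c("enolization", "ketonization")),
    iron_shortcut = list(seeds = c("OCC(O)C=O", "O"),
                         rules = c("dehydration", "ketoaldehyde_hydration",
                                   "hydride_shift",
                                   "fe_glyceraldehyde_lactate"))
  )
  for (nm in names(sets)) {
    writeLines(c(sprintf("# %s toy seeds", nm), sets[[nm]]$seeds),
               file.path(dir, paste0(nm, ".smi")))
    yaml::write_yaml(list(rules = unname(.toy_rule_docs[sets[[nm]]$rules])),
                     file.path(dir, paste0(nm, ".yaml")))
  }
  invisible(dir)
}
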