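# Canonical ids of the "ubiquitous" background species: water, the proton,
# hydroxide and the two iron ions. These are available as co-reactants in
# every generation and are excluded from product-diversity counts.
.UBIQUITOUS_SMILES <- c("O", "[H+]", "[OH-]", "[Fe+2]", "[Fe+3]")

ubiquitous_ids <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- vapply(.UBIQUITOUS_SMILES,
                       function(s) canonical_smiles(smiles_parse(s)), "")
    cache
  }
})

#' Parse and canonicalize a species
#'
#' Parses a line-notation (restricted SMILES) string, normalizes implicit
#' hydrogens and returns a canonical species record. Chemically identical
#' inputs (any atom ordering of the same labeled graph) map to the same
#' `canonical_id`, which is what deduplicates products across a network.
#'
#' @param notation SMILES string; elements restricted to C, H, N, O, Fe,
#'   charges explicit in brackets (e.g. `"[Fe+3]"`).
#' @return an object of class `crn_species`: a list with `canonical_id`,
#'   `formula` (named integer vector), `nominal_mass` (integer AMU),
#'   `net_charge`, `is_ubiquitous` and the canonical `mol` graph.
#' @examples
#' sp <- parse_and_canonicalize("OCC(O)C=O")  # glyceraldehyde
#' sp$nominal_mass                            # 90
#' @export
parse_and_canonicalize <- function(notation) {
  m <- canonicalize_mol(smiles_parse(notation))
  id <- smiles_write(m)
  structure(
    list(
      canonical_id = id,
      formula = mol_formula(m),
      nominal_mass = mol_mass(m),
      net_charge = mol_charge(m),
      is_ubiquitous = id %in% ubiquitous_ids(),
      mol = m
    ),
    class = "crn_species"
  )
}

#' @export
print.crn_species <- function(x, ...) {
  cat(sprintf("<species %s  %s  mass %d  charge %+d%s>\n",
              x$canonical_id, formula_string(x$formula), x$nominal_mass,
              x$net_charge, if (x$is_ubiquitous) "  [ubiquitous]" else ""))
  invisible(x)
}

#' Nominal mass of a species in integer AMU
#'
#' Sum of most-abundant-isotope integer masses (H=1, C=12, N=14, O=16, Fe=56).
#' This is the currency of the expansion mass cap.
#' @param s a `crn_species`
#' @return integer AMU (>= 1)
#' @export
nominal_mass <- function(s) {
  stopifnot(inherits(s, "crn_species"))
  s$nominal_mass
}

#' Is a species within the product mass cap?
#' @param s a `crn_species`
#' @param cap positive integer AMU
#' @export
within_mass_cap <- function(s, cap) {
  stopifnot(cap > 0)
  nominal_mass(s) <= cap
}
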