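# Experiment presets: the four modeled networks (formose, concentrated
# pyruvic acid, glucose degradation, glucose-glycine Maillard), each in an
# iron-free and an iron-containing variant. The iron variant differs from the
# iron-free one only by the added ionic seeds (Fe2+, Fe3+, H+, OH-) and the
# added iron rule library; this containment is asserted at load.

preset_file <- function(...) {
  system.file("extdata", ..., package = "feronet", mustWork = TRUE)
}

#' Names of the shipped experiment presets
#' @export
preset_names <- function() names(load_preset_registry())

load_preset_registry <- function() {
  yaml::read_yaml(preset_file("presets.yaml"))
}

get_preset <- function(name) {
  reg <- load_preset_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  reg[[name]]
}

#' Read a seed species file (one SMILES per line, `#` comments)
#' @param path file path
#' @return list of `crn_species`
#' @export
read_seed_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_and_canonicalize)
}

#' Seed species of a preset
#'
#' @param name preset name (see [preset_names()])
#' @param with_iron add the ionic seeds (Fe2+, Fe3+, H+, OH-)?
#' @return list of `crn_species`
#' @export
get_seed_set <- function(name, with_iron = FALSE) {
  p <- get_preset(name)
  seeds <- read_seed_file(preset_file(p$seeds))
  if (with_iron)
    seeds <- c(seeds, read_seed_file(preset_file("seeds", "iron_ions.smi")))
  seeds
}

#' Rule set of a preset
#'
#' @param name preset name
#' @param with_iron append the iron rule library?
#' @return named list of `crn_rule`
#' @export
get_rule_set <- function(name, with_iron = FALSE) {
  p <- get_preset(name)
  rules <- list()
  for (f in p$rules) rules <- c(rules, load_rule_library(preset_file(f)))
  if (with_iron)
    for (f in p$iron_rules) rules <- c(rules, load_rule_library(preset_file(f)))
  if (anyDuplicated(names(rules)))
    stop(sprintf("preset '%s': duplicate rule names across files", name),
         call. = FALSE)
  # containment: the iron variant only ever adds rules
  rules
}

#' Expansion configuration for a preset
#'
#' @param name preset name
#' @param with_iron iron-containing variant?
#' @param generations override the preset's default generation count
#' @param mass_cap override the preset's default mass cap (AMU)
#' @return an [expansion_config()]
#' @export
preset_config <- function(name, with_iron = FALSE, generations = NULL,
                          mass_cap = NULL) {
  p <- get_preset(name)
  if (is.null(generations)) generations <- p$generations
  if (is.null(mass_cap)) mass_cap <- p$mass_cap
  expansion_config(get_seed_set(name, with_iron),
                   get_rule_set(name, with_iron),
                   max_generations = generations, mass_cap = mass_cap)
}

#' Structural containment check for a preset's iron/iron-free pair
#'
#' Asserts that the iron-containing variant differs from the iron-free one
#' only by added ionic seeds and added iron-dependent rules.
#' @param name preset name
#' @export
check_preset_containment <- function(name) {
  sf <- vapply(get_seed_set(name, FALSE), function(s) s$canonical_id, "")
  si <- vapply(get_seed_set(name, TRUE), function(s) s$canonical_id, "")
  if (!all(sf %in% si))
    stop(sprintf("preset '%s': iron seed set does not contain iron-free seeds",
                 name), call. = FALSE)
  extra_seeds <- setdiff(si, sf)
  ubiq <- ubiquitous_ids()
  if (!all(extra_seeds %in% ubiq))
    stop(sprintf("preset '%s': iron variant adds non-ionic seeds", name),
         call. = FALSE)
  rf <- get_rule_set(name, FALSE)
  ri <- get_rule_set(name, TRUE)
  if (!all(names(rf) %in% names(ri)))
    stop(sprintf("preset '%s': iron rule set does not contain iron-free rules",
                 name), call. = FALSE)
  extra <- setdiff(names(ri), names(rf))
  if (!all(vapply(ri[extra], function(r) r$iron_dependent, TRUE)))
    stop(sprintf("preset '%s': iron variant adds non-iron rules", name),
         call. = FALSE)
  if (any(vapply(rf, function(r) r$iron_dependent, TRUE)))
    stop(sprintf("preset '%s': iron-free set contains iron rules", name),
         call. = FALSE)
  invisible(TRUE)
}

#' Published summary tables shipped with the package
#'
#' Returns one of the source study's printed summary tables as a data frame:
#' `"products"` (total product counts per network), `"edges"` (total
#' rule-application counts), `"formose_rules"` (per-rule frequencies in the
#' formose pair) or `"catalysis"` (catalyzed compound counts). These are
#' inputs for the derived-statistic reproduction, not outputs of this
#' package.
#' @param table table name
#' @export
reported_table <- function(table = c("products", "edges", "formose_rules",
                                     "catalysis")) {
  table <- match.arg(table)
  utils::read.csv(preset_file("reported", paste0(table, ".csv")),
                  check.names = FALSE, stringsAsFactors = FALSE)
}
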