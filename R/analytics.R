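# Comparison analytics between an iron-free and an iron-containing network:
# catalysis detection, degree metrics, rule-application frequencies with
# percent change, and log-linear growth fitting with extrapolation.

#' Species catalyzed by iron
#'
#' A compound counts as catalyzed when it appears in both networks but at a
#' strictly earlier generation in the iron-containing one (it needs fewer
#' reaction steps when iron chemistry is available). Ubiquitous background
#' species are excluded.
#'
#' @param free,iron `crn_network` objects for the iron-free and
#'   iron-containing variants of the same system
#' @return data.frame with columns `id`, `gen_free`, `gen_iron`
#' @export
catalyzed_species <- function(free, iron) {
  sf <- free$species[!free$species$ubiquitous, ]
  si <- iron$species[!iron$species$ubiquitous, ]
  m <- match(sf$id, si$id)
  keep <- !is.na(m) & si$first_generation[m] < sf$first_generation
  data.frame(id = sf$id[keep],
             gen_free = sf$first_generation[keep],
             gen_iron = si$first_generation[m][keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage of iron-free compounds that iron catalyzes
#'
#' 100 * |catalyzed| / |compounds in the iron-free network| (ubiquitous ions
#' excluded from both numerator and denominator). Returns the raw percentage;
#' see [format_percent_catalysis()] for report rounding.
#'
#' @inheritParams catalyzed_species
#' @return numeric percentage in [0, 100], `NA` if the iron-free network has
#'   no compounds
#' @export
percent_catalysis <- function(free, iron) {
  n_free <- sum(!free$species$ubiquitous)
  if (n_free == 0L) return(NA_real_)
  100 * nrow(catalyzed_species(free, iron)) / n_free
}

#' Report rounding for catalysis percentages
#'
#' One decimal below 2 percent, nearest integer otherwise.
#' @param p raw percentage
#' @return character
#' @export
format_percent_catalysis <- function(p) {
  if (is.na(p)) return("n/a")
  if (p < 2) sprintf("%.1f%%", p) else sprintf("%d%%", as.integer(round(p)))
}

#' Per-species degree metrics
#'
#' Out-degree counts the reactant slots a species fills over all events,
#' in-degree the product slots; multiplicity counts (a species consumed twice
#' in one event contributes 2), and catalytic participants gain both an in-
#' and an out-edge per event, since they sit on both sides.
#'
#' @param net a `crn_network`
#' @return data.frame `id`, `in_degree`, `out_degree`, `total_degree`, sorted
#'   by decreasing total degree
#' @export
degree_metrics <- function(net) {
  stopifnot(inherits(net, "crn_network"))
  ids <- net$species$id
  ind <- stats::setNames(integer(length(ids)), ids)
  outd <- stats::setNames(integer(length(ids)), ids)
  for (ev in net$events) {
    rt <- table(ev$reactants)
    outd[names(rt)] <- outd[names(rt)] + as.integer(rt)
    pt <- table(ev$products)
    ind[names(pt)] <- ind[names(pt)] + as.integer(pt)
  }
  out <- data.frame(id = ids, in_degree = as.integer(ind),
                    out_degree = as.integer(outd),
                    total_degree = as.integer(ind + outd),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$total_degree, out$id), ]
}

#' Rule application frequencies
#'
#' @param net a `crn_network`
#' @return data.frame `rule`, `events`; includes zero rows for library rules
#'   that never fired; frequencies sum to the total event count
#' @export
rule_frequency <- function(net) {
  stopifnot(inherits(net, "crn_network"))
  lib <- names(net$config$rules)
  counts <- stats::setNames(integer(length(lib)), lib)
  for (ev in net$events) counts[[ev$rule]] <- counts[[ev$rule]] + 1L
  data.frame(rule = names(counts), events = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent change of a rule frequency under iron
#'
#' Computed as 100 * (f_iron - f_free) / f_free, rounded to the nearest
#' integer (the convention every printed row of the source tables follows,
#' unlike their caption's ratio formula). A zero iron-free frequency yields
#' the sentinel `"-"`, as printed for iron-only rules.
#'
#' @param f_free,f_iron non-negative event counts
#' @return integer percentage, or the character `"-"` when `f_free` is zero
#' @export
frequency_change <- function(f_free, f_iron) {
  stopifnot(f_free >= 0, f_iron >= 0)
  if (f_free == 0) return("-")
  as.integer(round(100 * (f_iron - f_free) / f_free))
}

#' Rule-frequency comparison table for a network pair
#'
#' @inheritParams catalyzed_species
#' @return data.frame `rule`, `events_free`, `events_iron`, `percent_change`
#'   (character; `"-"` for iron-only rules)
#' @export
rule_frequency_comparison <- function(free, iron) {
  ff <- rule_frequency(free)
  fi <- rule_frequency(iron)
  m <- match(fi$rule, ff$rule)
  ef <- ifelse(is.na(m), 0L, ff$events[m])
  data.frame(
    rule = fi$rule,
    events_free = ef,
    events_iron = fi$events,
    percent_change = vapply(seq_along(ef), function(i)
      as.character(frequency_change(ef[i], fi$events[i])), ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fit exponential growth to cumulative product counts
#'
#' Least-squares line on log10(count) versus generation, the curve family
#' used to extrapolate product counts beyond what is computed. Projections
#' are back-transformed fitted values; they ignore saturation and so act as
#' upper bounds once the mass cap begins to bite.
#'
#' @param counts data.frame with columns `generation` and `species` (e.g.
#'   from [cumulative_species()]), or a numeric vector of counts at
#'   generations `0:(length-1)`
#' @param project generations to project to (default: the fitted range)
#' @return list with `slope` (log10 units per generation), `intercept`,
#'   `fold_per_generation` (10^slope) and `projection` data.frame
#' @export
growth_fit <- function(counts, project = NULL) {
  if (is.numeric(counts))
    counts <- data.frame(generation = seq_along(counts) - 1L,
                         species = counts)
  counts <- counts[is.finite(counts$species), ]
  if (nrow(counts) < 2L)
    stop("growth fit needs at least two counts", call. = FALSE)
  if (any(counts$species <= 0))
    stop("growth fit needs strictly positive counts", call. = FALSE)
  fit <- stats::lm(log10(species) ~ generation, data = counts)
  co <- stats::coef(fit)
  if (is.null(project)) project <- counts$generation
  pred <- 10^(co[[1]] + co[[2]] * project)
  list(slope = co[[2]], intercept = co[[1]],
       fold_per_generation = 10^co[[2]],
       projection = data.frame(generation = project, projected = pred))
}

#' Full comparison report for an iron-free / iron-containing pair
#'
#' @inheritParams catalyzed_species
#' @return object of class `crn_comparison`: catalyzed species table, percent
#'   catalysis (raw and formatted), degree tables, rule-frequency comparison
#'   and growth fits for both networks
#' @export
compare_networks <- function(free, iron) {
  cat_tab <- catalyzed_species(free, iron)
  pc <- percent_catalysis(free, iron)
  growth <- function(net) {
    cs <- cumulative_species(net)
    cs <- cs[cs$species > 0, ]
    if (nrow(cs) >= 2) growth_fit(cs) else NULL
  }
  structure(list(
    catalyzed = cat_tab,
    percent_catalysis = pc,
    percent_catalysis_printed = format_percent_catalysis(pc),
    degrees_free = degree_metrics(free),
    degrees_iron = degree_metrics(iron),
    rule_frequencies = rule_frequency_comparison(free, iron),
    growth_free = growth(free),
    growth_iron = growth(iron),
    totals = data.frame(
      network = c("iron_free", "iron_containing"),
      species = c(sum(!free$species$ubiquitous),
                  sum(!iron$species$ubiquitous)),
      events = c(length(free$events), length(iron$events))
    )
  ), class = "crn_comparison")
}

#' @export
print.crn_comparison <- function(x, ...) {
  cat("<network comparison>\n")
  cat(sprintf("  species: %d (iron-free) vs %d (iron)\n",
              x$totals$species[1], x$totals$species[2]))
  cat(sprintf("  events:  %d vs %d\n", x$totals$events[1], x$totals$events[2]))
  cat(sprintf("  catalyzed compounds: %d (%s of the iron-free network)\n",
              nrow(x$catalyzed), x$percent_catalysis_printed))
  invisible(x)
}
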