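# Generation-wise reaction network expansion.
#
# Generation 0 is the seed set. At generation g every rule is applied to all
# reactant tuples drawn from the cumulative pool whose newest member first
# appeared at g-1 (so each tuple is processed exactly once, and an event's
# generation label is max(reactant first generation) + 1, independent of
# enumeration order). Events whose products all fit the mass cap are kept;
# an event with any over-cap product is discarded whole. Expansion stops at
# the generation limit or at saturation (a generation with no new species and
# no new events), whichever comes first. The procedure is purely
# combinatorial: there is no randomness anywhere.

#' Build an expansion configuration
#'
#' @param seeds character vector of SMILES strings, or list of `crn_species`
#' @param rules list of `crn_rule` (possibly empty)
#' @param max_generations iterations to run (>= 1)
#' @param mass_cap product nominal-mass cap in AMU (default 200)
#' @param max_species hard safety limit on total species; exceeding it aborts
#'   with an error of class `crn_abort`
#' @return an `expansion_config`
#' @export
expansion_config <- function(seeds, rules, max_generations,
                             mass_cap = 200L, max_species = 1e6) {
  if (is.character(seeds)) seeds <- lapply(seeds, parse_and_canonicalize)
  stopifnot(length(seeds) >= 1L, max_generations >= 1L, mass_cap > 0L)
  for (s in seeds) {
    if (!within_mass_cap(s, mass_cap))
      stop(sprintf("config error: seed %s (mass %d) exceeds mass cap %d",
                   s$canonical_id, s$nominal_mass, mass_cap), call. = FALSE)
  }
  ids <- vapply(seeds, function(s) s$canonical_id, "")
  seeds <- seeds[!duplicated(ids)]
  structure(list(seeds = seeds, rules = rules,
                 max_generations = as.integer(max_generations),
                 mass_cap = as.integer(mass_cap),
                 max_species = max_species),
            class = "expansion_config")
}

#' Expand a reaction network from seeds and rules
#'
#' @param config an [expansion_config()]
#' @return a `crn_network`: species table with first-appearance generations,
#'   event list, per-generation novelty counts and (if reached) the
#'   saturation generation
#' @export
expand <- function(config) {
  stopifnot(inherits(config, "expansion_config"))
  rules <- config$rules
  cap <- config$mass_cap

  reg <- new.env(parent = emptyenv())   # id -> species record
  ids <- character(0)
  gens <- integer(0)
  add_species <- function(sp, gen) {
    id <- sp$canonical_id
    if (!is.null(reg[[id]])) return(FALSE)
    reg[[id]] <- list(species = sp, gen = gen)
    ids[length(ids) + 1L] <<- id
    gens[length(gens) + 1L] <<- gen
    if (length(ids) > config$max_species) {
      cond <- structure(
        class = c("crn_abort", "error", "condition"),
        list(message = sprintf(
          "species limit exceeded (%d > %g) at generation %d; raise max_species or lower the mass cap",
          length(ids), config$max_species, gen), call = NULL))
      stop(cond)
    }
    TRUE
  }
  for (s in config$seeds) add_species(s, 0L)

  canon_memo <- new.env(parent = emptyenv())
  match_cache <- new.env(parent = emptyenv())
  cached_matches <- function(ri, si, id) {
    key <- paste(ri, si, id, sep = "\r")
    hit <- match_cache[[key]]
    if (is.null(hit)) {
      hit <- match_pattern(rules[[ri]]$slots[[si]]$pattern, reg[[id]]$species$mol)
      match_cache[[key]] <- hit
    }
    hit
  }

  events <- list()
  event_seen <- new.env(parent = emptyenv())
  per_gen <- list()
  saturated_at <- NA_integer_

  for (g in seq_len(config$max_generations)) {
    pool_ids <- ids[gens <= g - 1L]
    pool_gens <- gens[gens <= g - 1L]
    new_species_ct <- 0L
    new_event_ct <- 0L

    for (ri in seq_along(rules)) {
      rule <- rules[[ri]]
      ns <- length(rule$slots)
      # candidate species ids (with cached matches) per slot
      slot_ids <- vector("list", ns)
      slot_gen <- vector("list", ns)
      viable <- TRUE
      for (si in seq_len(ns)) {
        s <- rule$slots[[si]]
        if (s$kind == "exact") {
          eid <- s$species$canonical_id
          if (!eid %in% pool_ids) { viable <- FALSE; break }
          slot_ids[[si]] <- eid
          slot_gen[[si]] <- pool_gens[match(eid, pool_ids)]
        } else {
          ok <- vapply(pool_ids, function(id)
            length(cached_matches(ri, si, id)) > 0L, TRUE)
          if (!any(ok)) { viable <- FALSE; break }
          slot_ids[[si]] <- pool_ids[ok]
          slot_gen[[si]] <- pool_gens[ok]
        }
      }
      if (!viable) next
      # each co-agent (consumed or catalytic) must be in the pool
      coag_need <- c(names(rule$coag_consumed), names(rule$coag_catalytic))
      if (length(coag_need) && !all(coag_need %in% pool_ids)) next

      slack <- rule$combine_slack
      masses <- lapply(slot_ids, function(v)
        vapply(v, function(id) reg[[id]]$species$nominal_mass, 0L))

      emb_seen <- new.env(parent = emptyenv())
      tuple <- character(ns); tgen <- integer(ns); tmass <- integer(ns)
      choose <- function(si) {
        if (si > ns) {
          if (max(tgen) != g - 1L) return(invisible())
          if (!is.na(slack) && sum(tmass) - slack > cap) return(invisible())
          slot_species <- lapply(tuple, function(id) reg[[id]]$species)
          mapsets <- lapply(seq_len(ns), function(k) {
            if (rule$slots[[k]]$kind == "exact")
              list(seq_len(rule$slots[[k]]$natoms))
            else cached_matches(ri, k, tuple[k])
          })
          maps <- vector("list", ns)
          emb <- function(k) {
            if (k > ns) {
              sig <- embedding_signature(rule, tuple, maps)
              if (!is.null(emb_seen[[sig]])) return(invisible())
              emb_seen[[sig]] <- TRUE
              prods <- apply_embedding_raw(rule, slot_species, maps, canon_memo)
              if (is.null(prods)) return(invisible())
              if (any(vapply(prods, function(p) p$mass, 0L) > cap))
                return(invisible())
              ev <- build_event(rule, slot_species, prods, g)
              k2 <- event_key(ev)
              if (!is.null(event_seen[[k2]])) return(invisible())
              event_seen[[k2]] <- TRUE
              events[[length(events) + 1L]] <<- ev
              new_event_ct <<- new_event_ct + 1L
              for (p in prods) {
                if (is.null(reg[[p$id]])) {
                  sp <- structure(
                    list(canonical_id = p$id, formula = p$formula,
                         nominal_mass = p$mass, net_charge = p$charge,
                         is_ubiquitous = p$id %in% ubiquitous_ids(),
                         mol = p$mol),
                    class = "crn_species")
                  add_species(sp, g)
                  if (!sp$is_ubiquitous)
                    new_species_ct <<- new_species_ct + 1L
                }
              }
              return(invisible())
            }
            for (m in mapsets[[k]]) {
              maps[[k]] <<- m
              emb(k + 1L)
            }
          }
          emb(1L)
          return(invisible())
        }
        cands <- slot_ids[[si]]
        cgens <- slot_gen[[si]]
        for (ci in seq_along(cands)) {
          tuple[si] <<- cands[ci]
          tgen[si] <<- cgens[ci]
          tmass[si] <<- masses[[si]][ci]
          if (!is.na(slack) && sum(tmass[seq_len(si)]) - slack > cap) next
          choose(si + 1L)
        }
      }
      choose(1L)
    }

    per_gen[[g]] <- c(generation = g, new_species = new_species_ct,
                      new_events = new_event_ct)
    if (new_species_ct == 0L && new_event_ct == 0L) {
      saturated_at <- g
      break
    }
  }

  species_df <- data.frame(
    id = ids,
    formula = vapply(ids, function(i) formula_string(reg[[i]]$species$formula), ""),
    mass = vapply(ids, function(i) reg[[i]]$species$nominal_mass, 0L),
    charge = vapply(ids, function(i) reg[[i]]$species$net_charge, 0L),
    ubiquitous = vapply(ids, function(i) reg[[i]]$species$is_ubiquitous, TRUE),
    first_generation = gens,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    species = species_df,
    mols = stats::setNames(lapply(ids, function(i) reg[[i]]$species$mol), ids),
    events = events,
    per_generation = do.call(rbind.data.frame,
                             c(lapply(per_gen, as.list),
                               list(stringsAsFactors = FALSE))),
    saturated_at = saturated_at,
    config = config
  ), class = "crn_network")
}

#' @export
print.crn_network <- function(x, ...) {
  ns <- sum(!x$species$ubiquitous)
  cat(sprintf(
    "<reaction network: %d species (%d molecular), %d events, %d generation(s)%s, cap %d AMU>\n",
    nrow(x$species), ns, length(x$events), max(0L, x$per_generation$generation),
    if (!is.na(x$saturated_at)) sprintf(", saturated at G%d", x$saturated_at)
    else "", x$config$mass_cap))
  invisible(x)
}

#' Per-generation novelty counts
#'
#' New (non-ubiquitous) species and new reaction events discovered at each
#' generation. The sum of new-species counts plus the number of seeds equals
#' the total species count; the sum of new-event counts equals the total
#' event count.
#'
#' @param net a `crn_network`
#' @return data.frame with columns `generation`, `new_species`, `new_events`
#' @export
novel_counts <- function(net) {
  stopifnot(inherits(net, "crn_network"))
  net$per_generation
}

#' Cumulative molecular species count per generation
#'
#' Counts non-ubiquitous species present at or before each generation
#' (generation 0 = molecular seeds). This is the "product count" growth curve.
#' @param net a `crn_network`
#' @return data.frame with columns `generation`, `species`
#' @export
cumulative_species <- function(net) {
  gmax <- if (nrow(net$per_generation)) max(net$per_generation$generation) else 0L
  gen <- 0:gmax
  sp <- net$species[!net$species$ubiquitous, ]
  data.frame(generation = gen,
             species = vapply(gen, function(g)
               sum(sp$first_generation <= g), 0L))
}

#' Saturation generation of an expanded network
#'
#' The first generation at which no new species and no new events arise (the
#' pool is then a fixed point: later generations cannot differ). `NA` if the
#' run hit its generation limit while still producing novelty.
#'
#' @param net a `crn_network`
#' @return integer generation, or `NA`
#' @export
saturation_generation <- function(net) {
  stopifnot(inherits(net, "crn_network"))
  net$saturated_at
}

#' Reaction events as a data frame
#'
#' @param net a `crn_network`
#' @return data.frame with one row per event: `rule`, `generation`, `iron`,
#'   and `;`-joined reactant and product canonical ids
#' @export
events_df <- function(net) {
  stopifnot(inherits(net, "crn_network"))
  if (!length(net$events))
    return(data.frame(rule = character(0), generation = integer(0),
                      iron = logical(0), reactants = character(0),
                      products = character(0), stringsAsFactors = FALSE))
  data.frame(
    rule = vapply(net$events, `[[`, "", "rule"),
    generation = vapply(net$events, `[[`, 0L, "generation"),
    iron = vapply(net$events, `[[`, TRUE, "iron"),
    reactants = vapply(net$events, function(e)
      paste(e$reactants, collapse = ";"), ""),
    products = vapply(net$events, function(e)
      paste(e$products, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
}

#' Check atom and charge conservation of every event in a network
#'
#' Independent audit: sums element formulas and net charges of the reactant
#' and product multisets of each event (catalytic co-agents appear on both
#' sides and cancel). Returns TRUE invisibly or stops with the offending
#' event.
#' @param net a `crn_network`
#' @export
check_conservation <- function(net) {
  stopifnot(inherits(net, "crn_network"))
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(net$species))) {
    id <- net$species$id[i]
    m <- net$mols[[id]]
    lookup[[id]] <- list(f = mol_formula(m), q = mol_charge(m))
  }
  side_sum <- function(idvec) {
    f <- integer(length(.ELEMENTS)); names(f) <- .ELEMENTS; q <- 0L
    for (id in idvec) {
      rec <- lookup[[id]]
      if (is.null(rec)) {  # co-agent not otherwise in the network table
        sp <- parse_and_canonicalize(id)
        rec <- list(f = sp$formula, q = sp$net_charge)
        lookup[[id]] <- rec
      }
      for (e in names(rec$f)) f[e] <- f[e] + rec$f[[e]]
      q <- q + rec$q
    }
    list(f = f, q = q)
  }
  for (ev in net$events) {
    l <- side_sum(ev$reactants); r <- side_sum(ev$products)
    if (!identical(l$f, r$f) || l$q != r$q)
      stop(sprintf("event not conserved: %s", event_key(ev)), call. = FALSE)
  }
  invisible(TRUE)
}
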