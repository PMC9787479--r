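# Brute-force reference expansion.
#
# An exhaustive, unoptimized re-derivation of the expansion semantics used to
# verify the main engine on small systems. It shares only the molecule
# representation and canonicalization with the engine; matching (all
# injective maps, checked at the end), rewriting (dense adjacency-matrix
# edits) and the generation loop (re-enumerate everything over the cumulative
# pool each generation, no caching, no pruning) are written independently.

# all injective maps of pattern atoms onto mol atoms; constraints and bonds
# verified exhaustively on complete maps only
naive_matches <- function(pat, mol) {
  np <- length(pat$ids)
  nm <- n_atoms(mol)
  if (np > nm) return(list())
  ord_full <- function(i, j) {
    if (!nrow(mol$bonds)) return(0L)
    hit <- (mol$bonds[, 1] == min(i, j)) & (mol$bonds[, 2] == max(i, j))
    if (any(hit)) mol$bonds[hit, 3][1] else 0L
  }
  res <- list()
  pick <- function(k, map) {
    if (k > np) {
      for (i in seq_len(np)) {
        if (!pattern_atom_compatible(pat, i, mol, map[i])) return(invisible())
      }
      if (nrow(pat$bonds)) {
        for (r in seq_len(nrow(pat$bonds))) {
          if (ord_full(map[pat$bonds[r, 1]], map[pat$bonds[r, 2]]) !=
              pat$bonds[r, 3]) return(invisible())
        }
      }
      res[[length(res) + 1L]] <<- map
      return(invisible())
    }
    for (mi in seq_len(nm)) {
      if (mi %in% map[seq_len(k - 1L)]) next
      map[k] <- mi
      pick(k + 1L, map)
    }
  }
  pick(1L, integer(np))
  res
}

# dense-matrix rewrite of one embedding; NULL on chemical rejection
naive_apply <- function(rule, slot_species, maps) {
  mols <- lapply(slot_species, `[[`, "mol")
  sizes <- vapply(mols, n_atoms, 0L)
  off <- cumsum(c(0L, sizes[-length(sizes)]))
  n <- sum(sizes)
  A <- matrix(0L, n, n)
  elem <- character(n); charge <- integer(n); hyd <- integer(n)
  for (si in seq_along(mols)) {
    m <- mols[[si]]
    idx <- off[si] + seq_len(sizes[si])
    elem[idx] <- m$elem; charge[idx] <- m$charge; hyd[idx] <- m$hyd
    if (nrow(m$bonds)) {
      for (k in seq_len(nrow(m$bonds))) {
        i <- off[si] + m$bonds[k, 1]; j <- off[si] + m$bonds[k, 2]
        A[i, j] <- A[j, i] <- m$bonds[k, 3]
      }
    }
  }
  gat <- function(gi) {
    si <- rule$gslot[gi]
    off[si] + maps[[si]][rule$gwithin[gi]]
  }
  if (nrow(rule$bond_edits)) {
    for (k in seq_len(nrow(rule$bond_edits))) {
      a <- gat(rule$bond_edits[k, 1]); b <- gat(rule$bond_edits[k, 2])
      to <- rule$bond_edits[k, 3]
      in_L <- rule_bond_order(rule, rule$bond_edits[k, 1],
                              rule$bond_edits[k, 2])
      if (in_L == 0L && A[a, b] != 0L) return(NULL)
      A[a, b] <- A[b, a] <- to
    }
  }
  if (nrow(rule$h_edits)) {
    for (k in seq_len(nrow(rule$h_edits))) {
      a <- gat(rule$h_edits[k, 1])
      hyd[a] <- hyd[a] + rule$h_edits[k, 2]
      if (hyd[a] < 0L) return(NULL)
    }
  }
  if (nrow(rule$charge_edits)) {
    for (k in seq_len(nrow(rule$charge_edits))) {
      a <- gat(rule$charge_edits[k, 1])
      charge[a] <- charge[a] + rule$charge_edits[k, 2]
    }
  }
  for (i in seq_len(n)) {
    if (sum(A[i, ]) + hyd[i] > .ELEM_MAXVAL[[elem[i]]]) return(NULL)
  }
  # components by repeated BFS over the matrix
  unassigned <- rep(TRUE, n)
  comps <- list()
  while (any(unassigned)) {
    start <- which(unassigned)[1]
    comp <- start; frontier <- start; unassigned[start] <- FALSE
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] > 0L & unassigned)
        unassigned[nb] <- FALSE
        nxt <- c(nxt, nb)
      }
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  lapply(comps, function(atoms) {
    bonds <- matrix(integer(0), ncol = 3)
    if (length(atoms) > 1L) {
      for (ii in seq_along(atoms)) {
        for (jj in seq_along(atoms)) {
          if (ii < jj && A[atoms[ii], atoms[jj]] > 0L)
            bonds <- rbind(bonds, c(ii, jj, A[atoms[ii], atoms[jj]]))
        }
      }
    }
    m <- molgraph(elem[atoms], charge[atoms], hyd[atoms], bonds)
    cm <- canonicalize_mol(m)
    list(id = smiles_write(cm), mol = cm, mass = mol_mass(cm),
         charge = mol_charge(cm), formula = mol_formula(cm))
  })
}

#' Brute-force reference expansion
#'
#' Exhaustively re-derives the network for a configuration by trying every
#' rule against every reactant tuple of the cumulative pool at every
#' generation, with an independent matcher and rewriter. Intended as the
#' oracle for verifying [expand()] on small systems; guarded at 1000 species.
#'
#' @param config an [expansion_config()]
#' @param guard maximum species count (default 1000)
#' @return a `crn_network`, field-for-field comparable with [expand()] output
#' @export
brute_force_expand <- function(config, guard = 1000L) {
  stopifnot(inherits(config, "expansion_config"))
  pool <- config$seeds
  gens <- rep(0L, length(pool))
  ids <- vapply(pool, function(s) s$canonical_id, "")
  events <- list()
  seen_events <- character(0)
  per_gen <- list()
  saturated_at <- NA_integer_

  for (g in seq_len(config$max_generations)) {
    found_events <- list()
    for (rule in config$rules) {
      ns <- length(rule$slots)
      coag_need <- c(names(rule$coag_consumed), names(rule$coag_catalytic))
      if (length(coag_need) && !all(coag_need %in% ids)) next
      # all ordered tuples from the whole pool
      tuples <- list(integer(0))
      for (si in seq_len(ns)) {
        tuples <- do.call(c, lapply(tuples, function(tp)
          lapply(seq_along(pool), function(i) c(tp, i))))
      }
      for (tp in tuples) {
        slot_species <- pool[tp]
        ok <- TRUE
        mapsets <- vector("list", ns)
        for (si in seq_len(ns)) {
          s <- rule$slots[[si]]
          if (s$kind == "exact") {
            if (slot_species[[si]]$canonical_id != s$species$canonical_id) {
              ok <- FALSE; break
            }
            mapsets[[si]] <- list(seq_len(s$natoms))
          } else {
            mapsets[[si]] <- naive_matches(s$pattern, slot_species[[si]]$mol)
            if (!length(mapsets[[si]])) { ok <- FALSE; break }
          }
        }
        if (!ok) next
        grid <- list(integer(0))
        for (si in seq_len(ns)) {
          grid <- do.call(c, lapply(grid, function(gg)
            lapply(seq_along(mapsets[[si]]), function(i) c(gg, i))))
        }
        for (gg in grid) {
          maps <- lapply(seq_len(ns), function(si) mapsets[[si]][[gg[si]]])
          prods <- naive_apply(rule, slot_species, maps)
          if (is.null(prods)) next
          if (any(vapply(prods, function(p) p$mass, 0L) > config$mass_cap))
            next
          ev <- build_event(rule, slot_species, prods, g)
          k <- event_key(ev)
          if (k %in% seen_events) next
          if (!is.null(found_events[[k]])) next
          ev$product_records <- prods
          found_events[[k]] <- ev
        }
      }
    }
    new_species_ct <- 0L
    for (ev in found_events) {
      seen_events <- c(seen_events, event_key(ev))
      for (p in ev$product_records) {
        if (!p$id %in% ids) {
          sp <- structure(
            list(canonical_id = p$id, formula = p$formula,
                 nominal_mass = p$mass, net_charge = p$charge,
                 is_ubiquitous = p$id %in% ubiquitous_ids(), mol = p$mol),
            class = "crn_species")
          pool[[length(pool) + 1L]] <- sp
          ids <- c(ids, p$id)
          gens <- c(gens, g)
          if (!sp$is_ubiquitous) new_species_ct <- new_species_ct + 1L
          if (length(pool) > guard)
            stop("brute-force guard exceeded (1000 species)", call. = FALSE)
        }
      }
      ev$product_records <- NULL
      events[[length(events) + 1L]] <- ev
    }
    per_gen[[g]] <- c(generation = g, new_species = new_species_ct,
                      new_events = length(found_events))
    if (new_species_ct == 0L && length(found_events) == 0L) {
      saturated_at <- g
      break
    }
  }

  species_df <- data.frame(
    id = ids,
    formula = vapply(pool, function(s) formula_string(s$formula), ""),
    mass = vapply(pool, function(s) s$nominal_mass, 0L),
    charge = vapply(pool, function(s) s$net_charge, 0L),
    ubiquitous = vapply(pool, function(s) s$is_ubiquitous, TRUE),
    first_generation = gens,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    species = species_df,
    mols = stats::setNames(lapply(pool, `[[`, "mol"), ids),
    events = events,
    per_generation = do.call(rbind.data.frame,
                             c(lapply(per_gen, as.list),
                               list(stringsAsFactors = FALSE))),
    saturated_at = saturated_at,
    config = config
  ), class = "crn_network")
}

#' Compare two expanded networks field by field
#'
#' @param a,b `crn_network` objects
#' @return TRUE if species sets, first generations and event sets (with
#'   generation labels) agree exactly; otherwise a character description of
#'   the first difference.
#' @export
networks_equal <- function(a, b) {
  sa <- a$species[order(a$species$id), c("id", "first_generation")]
  sb <- b$species[order(b$species$id), c("id", "first_generation")]
  if (!identical(sa$id, sb$id))
    return(sprintf("species sets differ: %d vs %d",
                   nrow(sa), nrow(sb)))
  if (!identical(sa$first_generation, sb$first_generation))
    return("first generations differ")
  ka <- sort(vapply(a$events, function(e)
    paste(event_key(e), e$generation), ""))
  kb <- sort(vapply(b$events, function(e)
    paste(event_key(e), e$generation), ""))
  if (!identical(ka, kb)) return("event sets differ")
  TRUE
}
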