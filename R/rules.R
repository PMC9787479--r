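# Reaction rules: declarative graph-transformation (L/K/R) mechanisms.
#
# A rule is one or two molecular reactant templates (plus optional "exact"
# co-reactants such as water, and ubiquitous ionic co-agents such as Fe2+/Fe3+
# or H+), together with an edit set: bond order changes, implicit-hydrogen
# deltas and formal-charge deltas over the template atoms. Applying a rule to
# an embedding rewrites the combined reactant graph, splits it into connected
# components, and canonicalizes each component into a product species.
#
# YAML schema (one file = one library):
#   rules:
#   - name: <unique string>
#     iron_dependent: false
#     reactants:
#     - atoms: [{id: c1, elem: C, minH: 1, charge: 0}, ...]   # pattern slot
#       bonds: [[c1, c2, 1], ...]
#     - {exact: "O", ids: [ow]}                               # exact slot
#     coagents:
#       consumed:  {"[Fe+3]": 2}
#       produced:  {"[Fe+2]": 2, "[H+]": 2}
#       catalytic: {"[OH-]": 1}
#     transform:
#       bonds:     [[c1, c3, 1], ...]      # target order (0 = delete)
#       hydrogens: [[c1, -1], ...]
#       charges:   [[c1, 1], ...]
#     combine_slack: 0          # optional: largest product >= total mass - slack
#     inverse_of: <rule name>   # optional metadata
#     provenance: {...}         # optional curation metadata
# Files may also carry `include: [other.yaml]` and `exclude: [rule names]`.

load_rule <- function(doc) {
  if (is.null(doc$name) || !nzchar(doc$name))
    stop("rule without a name", call. = FALSE)
  nm <- doc$name
  err <- function(...) stop(sprintf("rule '%s': %s", nm, sprintf(...)),
                            call. = FALSE)
  if (is.null(doc$reactants) || !length(doc$reactants))
    err("no reactant templates")

  gids <- character(0); gslot <- integer(0); gwithin <- integer(0)
  slots <- list()
  for (si in seq_along(doc$reactants)) {
    r <- doc$reactants[[si]]
    if (!is.null(r$exact)) {
      sp <- parse_and_canonicalize(r$exact)
      na <- n_atoms(sp$mol)
      ids <- if (!is.null(r$ids)) unlist(r$ids) else character(0)
      if (length(ids) && length(ids) != na)
        err("exact reactant '%s' has %d atoms but %d ids", r$exact, na,
            length(ids))
      slots[[si]] <- list(kind = "exact", species = sp, natoms = na)
      if (length(ids)) {
        gids <- c(gids, ids)
        gslot <- c(gslot, rep(si, na))
        gwithin <- c(gwithin, seq_len(na))
      }
    } else {
      if (is.null(r$atoms)) err("reactant %d has no atoms", si)
      ids <- vapply(r$atoms, function(a) as.character(a$id), "")
      elems <- lapply(r$atoms, function(a) {
        e <- if (is.null(a$elem)) "*" else as.character(a$elem)
        if (identical(e, "*")) .WILDCARD_ELEMS
        else if (e %in% .ELEMENTS) e
        else err("unsupported element '%s'", e)
      })
      charges <- vapply(r$atoms, function(a)
        if (is.null(a$charge)) 0L else as.integer(a$charge), 0L)
      minH <- vapply(r$atoms, function(a)
        if (is.null(a$minH)) 0L else as.integer(a$minH), 0L)
      bl <- if (is.null(r$bonds)) list() else r$bonds
      bonds <- matrix(0L, nrow = length(bl), ncol = 3)
      for (k in seq_along(bl)) {
        b <- bl[[k]]
        ia <- match(as.character(b[[1]]), ids)
        ib <- match(as.character(b[[2]]), ids)
        if (is.na(ia) || is.na(ib)) err("bond references unknown atom id")
        bonds[k, ] <- c(ia, ib, as.integer(b[[3]]))
      }
      slots[[si]] <- list(kind = "pattern",
                          pattern = make_pattern(ids, elems, charges, minH,
                                                 bonds),
                          natoms = length(ids))
      gids <- c(gids, ids)
      gslot <- c(gslot, rep(si, length(ids)))
      gwithin <- c(gwithin, seq_along(ids))
    }
  }
  if (anyDuplicated(gids)) err("duplicate atom id '%s'",
                               gids[duplicated(gids)][1])
  gix <- function(id) {
    i <- match(as.character(id), gids)
    if (is.na(i)) err("edit references unknown atom id '%s'", id)
    i
  }

  tr <- if (is.null(doc$transform)) list() else doc$transform
  be <- if (is.null(tr$bonds)) list() else tr$bonds
  bond_edits <- matrix(0L, nrow = length(be), ncol = 3)
  colnames(bond_edits) <- c("a", "b", "to")
  for (k in seq_along(be)) {
    b <- be[[k]]
    bond_edits[k, ] <- c(gix(b[[1]]), gix(b[[2]]), as.integer(b[[3]]))
  }
  he <- if (is.null(tr$hydrogens)) list() else tr$hydrogens
  h_edits <- matrix(0L, nrow = length(he), ncol = 2)
  colnames(h_edits) <- c("atom", "delta")
  for (k in seq_along(he))
    h_edits[k, ] <- c(gix(he[[k]][[1]]), as.integer(he[[k]][[2]]))
  ce <- if (is.null(tr$charges)) list() else tr$charges
  charge_edits <- matrix(0L, nrow = length(ce), ncol = 2)
  colnames(charge_edits) <- c("atom", "delta")
  for (k in seq_along(ce))
    charge_edits[k, ] <- c(gix(ce[[k]][[1]]), as.integer(ce[[k]][[2]]))

  parse_coag <- function(x) {
    if (is.null(x) || !length(x)) return(list())
    out <- list()
    for (s in names(x)) {
      sp <- parse_and_canonicalize(s)
      if (!sp$is_ubiquitous)
        err("co-agent '%s' is not a ubiquitous species", s)
      out[[sp$canonical_id]] <- list(species = sp, count = as.integer(x[[s]]))
    }
    out
  }
  cg <- if (is.null(doc$coagents)) list() else doc$coagents
  coag_consumed <- parse_coag(cg$consumed)
  coag_produced <- parse_coag(cg$produced)
  coag_catalytic <- parse_coag(cg$catalytic)

  rule <- list(
    name = nm,
    iron_dependent = isTRUE(doc$iron_dependent),
    slots = slots,
    gids = gids, gslot = gslot, gwithin = gwithin,
    bond_edits = bond_edits, h_edits = h_edits, charge_edits = charge_edits,
    coag_consumed = coag_consumed, coag_produced = coag_produced,
    coag_catalytic = coag_catalytic,
    combine_slack = if (is.null(doc$combine_slack)) NA_integer_
                    else as.integer(doc$combine_slack),
    inverse_of = doc$inverse_of,
    provenance = doc$provenance,
    spec = doc
  )
  class(rule) <- "crn_rule"
  validate_rule(rule)
  rule$autos <- rule_automorphisms(rule)
  rule
}

# a pattern-or-exact bond order between two *global* atom indices (0 = none)
rule_bond_order <- function(rule, a, b) {
  if (rule$gslot[a] != rule$gslot[b]) return(0L)
  s <- rule$slots[[rule$gslot[a]]]
  wa <- rule$gwithin[a]; wb <- rule$gwithin[b]
  bonds <- if (s$kind == "pattern") s$pattern$bonds else s$species$mol$bonds
  if (!nrow(bonds)) return(0L)
  hit <- (bonds[, 1] == wa & bonds[, 2] == wb) |
         (bonds[, 1] == wb & bonds[, 2] == wa)
  if (any(hit)) bonds[hit, 3][1] else 0L
}

validate_rule <- function(rule) {
  err <- function(...) stop(sprintf("rule '%s': %s", rule$name, sprintf(...)),
                            call. = FALSE)
  # edit-set consistency: deletions/changes need an L bond, additions need none
  if (nrow(rule$bond_edits)) {
    for (k in seq_len(nrow(rule$bond_edits))) {
      a <- rule$bond_edits[k, 1]; b <- rule$bond_edits[k, 2]
      to <- rule$bond_edits[k, 3]
      cur <- rule_bond_order(rule, a, b)
      if (cur == 0L && to == 0L)
        err("edit deletes bond %s-%s that is absent from L",
            rule$gids[a], rule$gids[b])
      if (cur == to)
        err("edit on bond %s-%s is a no-op", rule$gids[a], rule$gids[b])
    }
  }
  # elemental balance: pattern atoms are conserved by construction; implicit-H
  # deltas and charge deltas must be compensated by the co-agent multisets.
  coag_sum <- function(cs, what) {
    tot <- 0L
    for (x in cs) {
      v <- switch(what,
                  H = { f <- x$species$formula
                        if ("H" %in% names(f)) f[["H"]] else 0L },
                  charge = x$species$net_charge,
                  elem = NULL)
      tot <- tot + v * x$count
    }
    tot
  }
  coag_formula <- function(cs) {
    f <- integer(length(.ELEMENTS)); names(f) <- .ELEMENTS
    for (x in cs)
      for (e in names(x$species$formula))
        f[e] <- f[e] + x$species$formula[[e]] * x$count
    f
  }
  fc <- coag_formula(rule$coag_consumed)
  fp <- coag_formula(rule$coag_produced)
  for (e in setdiff(.ELEMENTS, "H"))
    if (fc[e] != fp[e])
      err("co-agents unbalanced in element %s", e)
  dH <- sum(rule$h_edits[, 2])
  if (dH + fp["H"] - fc["H"] != 0L)
    err("hydrogen not conserved (edit sum %+d, co-agents %+d)",
        dH, fp[["H"]] - fc[["H"]])
  dq <- sum(rule$charge_edits[, 2])
  qc <- coag_sum(rule$coag_consumed, "charge")
  qp <- coag_sum(rule$coag_produced, "charge")
  if (dq + qp - qc != 0L)
    err("charge not conserved (edit sum %+d, co-agents %+d)", dq, qp - qc)
  invisible(rule)
}

# ---------------------------------------------------------------------------
# Rule automorphisms: self-maps of the full (multi-slot) template that
# preserve atom constraints, bonds and the edit set. Embeddings related by
# such a symmetry produce the same reaction event and are deduplicated.
# ---------------------------------------------------------------------------
rule_automorphisms <- function(rule) {
  n <- length(rule$gids)
  # constraint signature per global atom
  sig <- vapply(seq_len(n), function(i) {
    s <- rule$slots[[rule$gslot[i]]]
    w <- rule$gwithin[i]
    if (s$kind == "exact")
      paste("X", s$species$canonical_id, s$species$mol$elem[w],
            s$species$mol$charge[w], s$species$mol$hyd[w], sep = "|")
    else
      paste("P", paste(sort(s$pattern$elem[[w]]), collapse = ","),
            ifelse(is.na(s$pattern$charge[w]), "any", s$pattern$charge[w]),
            s$pattern$minH[w], sep = "|")
  }, "")
  bond_of <- function(a, b) rule_bond_order(rule, a, b)
  perms <- list()
  perm <- integer(n)
  used <- logical(n)
  recurse <- function(k) {
    if (k > n) { perms[[length(perms) + 1L]] <<- perm; return(invisible()) }
    for (j in seq_len(n)) {
      if (used[j] || sig[j] != sig[k]) next
      ok <- TRUE
      if (k > 1L) {
        for (p in seq_len(k - 1L)) {
          if (bond_of(k, p) != bond_of(j, perm[p])) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      perm[k] <<- j; used[j] <<- TRUE
      recurse(k + 1L)
      used[j] <<- FALSE
    }
  }
  recurse(1L)
  # keep only symmetries that preserve the edit set
  edit_key <- function(p) {
    bk <- if (nrow(rule$bond_edits))
      sort(apply(rule$bond_edits, 1, function(r) {
        a <- p[r[1]]; b <- p[r[2]]
        paste(min(a, b), max(a, b), r[3], sep = ":")
      })) else character(0)
    hk <- if (nrow(rule$h_edits))
      sort(paste(p[rule$h_edits[, 1]], rule$h_edits[, 2], sep = ":"))
      else character(0)
    ck <- if (nrow(rule$charge_edits))
      sort(paste(p[rule$charge_edits[, 1]], rule$charge_edits[, 2], sep = ":"))
      else character(0)
    paste(paste(bk, collapse = ";"), paste(hk, collapse = ";"),
          paste(ck, collapse = ";"), sep = "&")
  }
  id_key <- edit_key(seq_len(n))
  # symmetries must also map slots onto slots (components already guarantee
  # this) with matching slot kinds, which the signature encodes
  keep <- vapply(perms, function(p) {
    slot_img <- rule$gslot[p]
    # atoms of one slot must land in a single slot
    for (si in unique(rule$gslot))
      if (length(unique(slot_img[rule$gslot == si])) != 1L) return(FALSE)
    edit_key(p) == id_key
  }, TRUE)
  perms[keep]
}

# ---------------------------------------------------------------------------
# Application
# ---------------------------------------------------------------------------

# serialize a molgraph exactly (order-dependent); used for memoization
serialize_mol <- function(m) {
  paste(paste(m$elem, m$charge, m$hyd, sep = ",", collapse = ";"),
        paste(t(m$bonds), collapse = ","), sep = "|")
}

# apply the rule's edits to an embedding; returns list(products = list of
# crn_species-lite (id, mass, mol)) or NULL when the edit is chemically
# rejected (negative hydrogens, valence overflow, bond clash).
apply_embedding_raw <- function(rule, slot_species, maps, canon_memo = NULL) {
  ns <- length(rule$slots)
  offsets <- integer(ns)
  elem <- character(0); charge <- integer(0); hyd <- integer(0)
  bonds <- matrix(integer(0), ncol = 3)
  for (si in seq_len(ns)) {
    m <- slot_species[[si]]$mol
    offsets[si] <- length(elem)
    b <- m$bonds
    if (nrow(b)) { b[, 1] <- b[, 1] + offsets[si]; b[, 2] <- b[, 2] + offsets[si] }
    elem <- c(elem, m$elem); charge <- c(charge, m$charge); hyd <- c(hyd, m$hyd)
    bonds <- rbind(bonds, b)
  }
  # global pattern atom -> combined graph index
  gatom <- integer(length(rule$gids))
  for (i in seq_along(gatom)) {
    si <- rule$gslot[i]
    gatom[i] <- offsets[si] + maps[[si]][rule$gwithin[i]]
  }
  touched <- integer(0)
  if (nrow(rule$bond_edits)) {
    for (k in seq_len(nrow(rule$bond_edits))) {
      a <- gatom[rule$bond_edits[k, 1]]
      b <- gatom[rule$bond_edits[k, 2]]
      to <- rule$bond_edits[k, 3]
      lo <- min(a, b); hi <- max(a, b)
      hit <- which(bonds[, 1] == lo & bonds[, 2] == hi)
      cur <- if (length(hit)) bonds[hit[1], 3] else 0L
      expected <- rule_bond_order(rule, rule$bond_edits[k, 1],
                                  rule$bond_edits[k, 2])
      # creating a bond where one already exists (e.g. ring closure onto
      # already-bonded atoms) is not a valid embedding
      if (expected == 0L && cur != 0L) return(NULL)
      if (to == 0L) {
        bonds <- bonds[-hit[1], , drop = FALSE]
      } else if (length(hit)) {
        bonds[hit[1], 3] <- to
      } else {
        bonds <- rbind(bonds, c(lo, hi, to))
      }
      touched <- c(touched, a, b)
    }
  }
  if (nrow(rule$h_edits)) {
    for (k in seq_len(nrow(rule$h_edits))) {
      a <- gatom[rule$h_edits[k, 1]]
      hyd[a] <- hyd[a] + rule$h_edits[k, 2]
      if (hyd[a] < 0L) return(NULL)
      touched <- c(touched, a)
    }
  }
  if (nrow(rule$charge_edits)) {
    for (k in seq_len(nrow(rule$charge_edits))) {
      a <- gatom[rule$charge_edits[k, 1]]
      charge[a] <- charge[a] + rule$charge_edits[k, 2]
      touched <- c(touched, a)
    }
  }
  combined <- molgraph(elem, charge, hyd, bonds)
  touched <- unique(touched)
  if (!valence_ok(combined, touched)) return(NULL)
  comps <- mol_components(combined)
  products <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    sub <- mol_subset(combined, comps[[ci]])
    key <- serialize_mol(sub)
    hit <- if (!is.null(canon_memo)) canon_memo[[key]] else NULL
    if (is.null(hit)) {
      cm <- canonicalize_mol(sub)
      hit <- list(id = smiles_write(cm), mol = cm, mass = mol_mass(cm),
                  charge = mol_charge(cm), formula = mol_formula(cm))
      if (!is.null(canon_memo)) canon_memo[[key]] <- hit
    }
    products[[ci]] <- hit
  }
  products
}

coag_vector <- function(cs) {
  if (!length(cs)) return(character(0))
  unlist(lapply(names(cs), function(id) rep(id, cs[[id]]$count)))
}

# build the event record (reactant/product id multisets with co-agents)
build_event <- function(rule, slot_species, products, generation = NA_integer_) {
  reac <- c(vapply(slot_species, function(s) s$canonical_id, ""),
            coag_vector(rule$coag_consumed), coag_vector(rule$coag_catalytic))
  prod <- c(vapply(products, function(p) p$id, ""),
            coag_vector(rule$coag_produced), coag_vector(rule$coag_catalytic))
  list(rule = rule$name, iron = rule$iron_dependent,
       reactants = sort(reac), products = sort(prod),
       generation = generation)
}

event_key <- function(ev) {
  paste(ev$rule, paste(ev$reactants, collapse = "+"),
        paste(ev$products, collapse = "+"), sep = " => ")
}

# embedding signature under the rule automorphism group, for deduplication
embedding_signature <- function(rule, slot_ids, maps) {
  n <- length(rule$gids)
  ea <- integer(n); einst <- character(n)
  for (i in seq_len(n)) {
    si <- rule$gslot[i]
    ea[i] <- maps[[si]][rule$gwithin[i]]
    einst[i] <- slot_ids[si]
  }
  best <- NULL
  for (p in rule$autos) {
    s <- paste(einst[p], ea[p], sep = "#", collapse = "|")
    if (is.null(best) || s < best) best <- s
  }
  best
}

#' Find all distinct embeddings of a rule into a pool of species
#'
#' Enumerates every way the rule's reactant templates match species in the
#' pool, complete up to the rule's own symmetries (embeddings related by a
#' template automorphism are returned once).
#'
#' @param rule a `crn_rule`
#' @param pool list of `crn_species`
#' @return list of embeddings: each has `slot_ids` (species canonical ids per
#'   reactant slot) and `maps` (template-atom to species-atom index maps)
#' @export
find_embeddings <- function(rule, pool) {
  ids <- vapply(pool, function(s) s$canonical_id, "")
  by_id <- stats::setNames(pool, ids)
  # required co-agents (consumed or catalytic) must be present in the pool
  coag_need <- c(names(rule$coag_consumed), names(rule$coag_catalytic))
  if (length(coag_need) && !all(coag_need %in% ids)) return(list())
  ns <- length(rule$slots)
  slot_cands <- vector("list", ns)
  for (si in seq_len(ns)) {
    s <- rule$slots[[si]]
    if (s$kind == "exact") {
      if (!s$species$canonical_id %in% ids) return(list())
      slot_cands[[si]] <- list(list(id = s$species$canonical_id,
                                    maps = list(seq_len(s$natoms))))
    } else {
      cands <- list()
      for (id in unique(ids)) {
        mm <- match_pattern(s$pattern, by_id[[id]]$mol)
        if (length(mm)) cands[[length(cands) + 1L]] <- list(id = id, maps = mm)
      }
      if (!length(cands)) return(list())
      slot_cands[[si]] <- cands
    }
  }
  out <- list()
  seen <- new.env(parent = emptyenv())
  pick <- function(si, slot_ids, maps) {
    if (si > ns) {
      sig <- embedding_signature(rule, slot_ids, maps)
      if (is.null(seen[[sig]])) {
        seen[[sig]] <- TRUE
        out[[length(out) + 1L]] <<- list(slot_ids = slot_ids, maps = maps)
      }
      return(invisible())
    }
    for (cand in slot_cands[[si]]) {
      for (m in cand$maps) {
        slot_ids[si] <- cand$id
        maps[[si]] <- m
        pick(si + 1L, slot_ids, maps)
      }
    }
  }
  pick(1L, character(ns), vector("list", ns))
  out
}

#' Apply a rule to one embedding, producing a reaction event
#'
#' Rewrites the reactant graphs according to the rule's edit set and returns
#' the event (reactant and product multisets, with catalytic co-agents on both
#' sides). Chemically impossible rewrites (valence overflow, hydrogen
#' underflow, bond clash) return `NULL`, as if the match had not existed.
#'
#' @param rule a `crn_rule`
#' @param embedding one element of [find_embeddings()] output
#' @param pool the species pool the embedding refers to
#' @return an event list (`rule`, `reactants`, `products`, `iron`) or `NULL`
#' @export
apply_rule <- function(rule, embedding, pool) {
  ids <- vapply(pool, function(s) s$canonical_id, "")
  by_id <- stats::setNames(pool, ids)
  slot_species <- lapply(embedding$slot_ids, function(id) by_id[[id]])
  products <- apply_embedding_raw(rule, slot_species, embedding$maps)
  if (is.null(products)) return(NULL)
  ev <- build_event(rule, slot_species, products)
  ev$product_mols <- products
  ev
}

#' @export
print.crn_rule <- function(x, ...) {
  cat(sprintf("<rule '%s'%s: %d reactant slot(s), %d bond edit(s)>\n",
              x$name, if (x$iron_dependent) " [iron]" else "",
              length(x$slots), nrow(x$bond_edits)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Library IO
# ---------------------------------------------------------------------------

#' Load a rule library from a YAML file
#'
#' Files may include other files (`include:`) and drop rules by name
#' (`exclude:`); rule names must be unique after assembly and every rule must
#' satisfy the structural invariants (consistent edit set, element/charge
#' conservation against its co-agents).
#'
#' @param path YAML file path
#' @return list of `crn_rule`, named by rule name
#' @export
load_rule_library <- function(path) {
  if (!file.exists(path)) stop(sprintf("rule file not found: %s", path),
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  rules <- list()
  add <- function(r) {
    if (!is.null(rules[[r$name]]))
      stop(sprintf("duplicate rule name '%s' in %s", r$name, path),
           call. = FALSE)
    rules[[r$name]] <<- r
  }
  if (!is.null(doc$include)) {
    for (inc in doc$include) {
      sub <- load_rule_library(file.path(dirname(path), inc))
      for (r in sub) add(r)
    }
  }
  if (!is.null(doc$rules)) for (rd in doc$rules) add(load_rule(rd))
  if (!is.null(doc$exclude)) {
    missing <- setdiff(unlist(doc$exclude), names(rules))
    if (length(missing))
      stop(sprintf("exclude lists unknown rule(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    rules[unlist(doc$exclude)] <- NULL
  }
  rules
}

#' Write a rule library back to YAML
#' @param rules list of `crn_rule`
#' @param path output file
#' @export
write_rule_library <- function(rules, path) {
  yaml::write_yaml(list(rules = lapply(rules, function(r) r$spec)), path)
  invisible(path)
}
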