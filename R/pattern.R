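# Subgraph pattern matching for rule application.
#
# A pattern is a small connected template graph: each atom carries an allowed
# element set (wildcard "*" = any of C/N/O), an optional required charge and a
# minimum free (implicit) hydrogen count; bonds carry exact orders. A match is
# an injective, bond-order-preserving map of pattern atoms onto the atoms of a
# species graph. Matches are enumerated by backtracking in a breadth-first
# visit order so every distinct map is produced exactly once.

.WILDCARD_ELEMS <- c("C", "N", "O")

# build internal pattern from parsed atom/bond lists
make_pattern <- function(ids, elems, charges, minH, bonds) {
  np <- length(ids)
  stopifnot(np >= 1L)
  if (nrow(bonds)) {
    stopifnot(all(bonds[, 1:2] >= 1L), all(bonds[, 1:2] <= np))
  }
  # connectivity + BFS visit order
  adj <- vector("list", np)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  if (np > 1L) {
    seen <- logical(np); seen[1] <- TRUE; queue <- 1L; vo <- 1L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (!is.null(adj[[cur]])) {
        for (r in seq_len(nrow(adj[[cur]]))) {
          j <- adj[[cur]][r, 1]
          if (!seen[j]) { seen[j] <- TRUE; queue <- c(queue, j); vo <- c(vo, j) }
        }
      }
    }
    if (!all(seen)) stop("pattern molecule is not connected", call. = FALSE)
  } else vo <- 1L
  # for each visit position > 1: the bonds from that atom to already-visited atoms
  back_bonds <- vector("list", np)
  placed <- logical(np)
  placed[vo[1]] <- TRUE
  for (k in seq_along(vo)[-1]) {
    a <- vo[k]
    bb <- matrix(integer(0), ncol = 2)  # (earlier atom, order)
    if (!is.null(adj[[a]])) {
      for (r in seq_len(nrow(adj[[a]]))) {
        if (placed[adj[[a]][r, 1]])
          bb <- rbind(bb, adj[[a]][r, , drop = FALSE])
      }
    }
    back_bonds[[a]] <- bb
    placed[a] <- TRUE
  }
  structure(list(ids = ids, elem = elems, charge = charges, minH = minH,
                 bonds = bonds, adj = adj, visit = vo,
                 back_bonds = back_bonds),
            class = "crn_pattern")
}

pattern_atom_compatible <- function(pat, pi, mol, mi) {
  mol$elem[mi] %in% pat$elem[[pi]] &&
    (is.na(pat$charge[pi]) || mol$charge[mi] == pat$charge[pi]) &&
    mol$hyd[mi] >= pat$minH[pi]
}

# all injective bond-preserving maps of `pat` into molgraph `mol`;
# returns list of integer vectors (pattern atom index -> mol atom index)
match_pattern <- function(pat, mol) {
  np <- length(pat$ids)
  nm <- n_atoms(mol)
  if (np > nm) return(list())
  # mol adjacency with orders
  madj <- vector("list", nm)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]; o <- mol$bonds[k, 3]
      madj[[i]] <- rbind(madj[[i]], c(j, o))
      madj[[j]] <- rbind(madj[[j]], c(i, o))
    }
  }
  mol_bond <- function(i, j) {
    a <- madj[[i]]
    if (is.null(a)) return(0L)
    hit <- a[a[, 1] == j, 2]
    if (length(hit)) hit[1] else 0L
  }
  res <- list()
  map <- integer(np)
  used <- logical(nm)
  recurse <- function(k) {
    if (k > np) { res[[length(res) + 1L]] <<- map; return(invisible()) }
    pa <- pat$visit[k]
    if (k == 1L) {
      cand <- which(vapply(seq_len(nm), function(mi)
        !used[mi] && pattern_atom_compatible(pat, pa, mol, mi), TRUE))
    } else {
      bb <- pat$back_bonds[[pa]]
      anchor <- map[bb[1, 1]]
      a <- madj[[anchor]]
      cand <- if (is.null(a)) integer(0) else a[a[, 2] == bb[1, 2], 1]
      cand <- cand[!used[cand]]
      cand <- cand[vapply(cand, function(mi)
        pattern_atom_compatible(pat, pa, mol, mi), TRUE)]
      if (nrow(bb) > 1L) {
        for (r in 2:nrow(bb)) {
          cand <- cand[vapply(cand, function(mi)
            mol_bond(mi, map[bb[r, 1]]) == bb[r, 2], TRUE)]
        }
      }
    }
    for (mi in cand) {
      map[pa] <<- mi
      used[mi] <<- TRUE
      recurse(k + 1L)
      used[mi] <<- FALSE
    }
  }
  recurse(1L)
  res
}
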