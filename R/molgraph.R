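#' @importFrom igraph make_graph canonical_permutation graph_from_edgelist
NULL

# Supported elements, nominal (most-abundant-isotope) integer masses, and
# maximum bonding valence used by the post-edit sanity guard.
.ELEMENTS <- c("H", "C", "N", "O", "Fe")
.ELEM_MASS <- c(H = 1L, C = 12L, N = 14L, O = 16L, Fe = 56L)
.ELEM_MAXVAL <- c(H = 1L, C = 4L, N = 3L, O = 2L, Fe = 0L)
# default valence used to fill implicit hydrogens for bare organic-subset atoms
.ELEM_DEFVAL <- c(C = 4L, N = 3L, O = 2L)

#' Construct a molecular graph
#'
#' A `molgraph` is the package's internal molecule representation: heavy atoms
#' (plus bare H for the proton) with element, formal charge and an implicit
#' hydrogen count, and a bond table of integer orders. Hydrogens are not graph
#' vertices; they are per-atom counts, which keeps graphs small and makes the
#' rule edits (H gain/loss) cheap.
#'
#' @param elem character vector of element symbols (C, H, N, O, Fe)
#' @param charge integer vector of formal charges
#' @param hyd integer vector of implicit hydrogen counts
#' @param bonds integer matrix with columns `i`, `j`, `order` (1, 2 or 3)
#' @return an object of class `molgraph`
#' @keywords internal
molgraph <- function(elem, charge = integer(length(elem)),
                     hyd = integer(length(elem)),
                     bonds = matrix(integer(0), ncol = 3)) {
  stopifnot(all(elem %in% .ELEMENTS))
  n <- length(elem)
  bonds <- matrix(as.integer(bonds), ncol = 3)
  colnames(bonds) <- c("i", "j", "order")
  if (nrow(bonds)) {
    swap <- bonds[, 1] > bonds[, 2]
    tmp <- bonds[swap, 1]
    bonds[swap, 1] <- bonds[swap, 2]
    bonds[swap, 2] <- tmp
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  structure(
    list(elem = as.character(elem), charge = as.integer(charge),
         hyd = as.integer(hyd), bonds = bonds),
    class = "molgraph"
  )
}

n_atoms <- function(m) length(m$elem)

# sum of bond orders incident to each atom
bond_order_sums <- function(m) {
  s <- integer(n_atoms(m))
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      s[m$bonds[k, 1]] <- s[m$bonds[k, 1]] + m$bonds[k, 3]
      s[m$bonds[k, 2]] <- s[m$bonds[k, 2]] + m$bonds[k, 3]
    }
  }
  s
}

# valence guard: C <= 4, N <= 3, O <= 2, H <= 1, Fe unbonded
valence_ok <- function(m, atoms = seq_len(n_atoms(m))) {
  s <- bond_order_sums(m)
  all(s[atoms] + m$hyd[atoms] <= .ELEM_MAXVAL[m$elem[atoms]])
}

mol_formula <- function(m) {
  f <- integer(length(.ELEMENTS))
  names(f) <- .ELEMENTS
  for (i in seq_len(n_atoms(m))) {
    f[m$elem[i]] <- f[m$elem[i]] + 1L
    f["H"] <- f["H"] + m$hyd[i]
  }
  f[f > 0L]
}

formula_string <- function(f) {
  ord <- intersect(c("C", "H", "N", "O", "Fe"), names(f))
  paste0(vapply(ord, function(e) {
    if (f[[e]] == 1L) e else paste0(e, f[[e]])
  }, ""), collapse = "")
}

mol_mass <- function(m) {
  sum(.ELEM_MASS[m$elem]) + sum(m$hyd) * .ELEM_MASS[["H"]]
}

mol_charge <- function(m) sum(m$charge)

# connected components over the bond table; returns list of atom index vectors
mol_components <- function(m) {
  n <- n_atoms(m)
  comp <- seq_len(n)
  if (nrow(m$bonds)) {
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(m$bonds))) {
        i <- m$bonds[k, 1]; j <- m$bonds[k, 2]
        lo <- min(comp[i], comp[j])
        if (comp[i] != lo || comp[j] != lo) {
          comp[comp == comp[i] | comp == comp[j]] <- lo
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  lapply(unique(comp), function(cid) which(comp == cid))
}

# extract the sub-molecule induced by a set of atoms
mol_subset <- function(m, atoms) {
  idx <- integer(n_atoms(m))
  idx[atoms] <- seq_along(atoms)
  b <- m$bonds
  if (nrow(b)) {
    keep <- b[, 1] %in% atoms & b[, 2] %in% atoms
    b <- b[keep, , drop = FALSE]
    if (nrow(b)) {
      b[, 1] <- idx[b[, 1]]
      b[, 2] <- idx[b[, 2]]
    }
  }
  molgraph(m$elem[atoms], m$charge[atoms], m$hyd[atoms], b)
}

# ---------------------------------------------------------------------------
# Canonicalization.
#
# Bond orders matter for graph identity, and the BLISS backend only colors
# vertices, so each bond is expanded into an auxiliary vertex colored by its
# order. The canonical labeling of that colored auxiliary graph induces a
# canonical atom order that is invariant under input atom numbering.
# ---------------------------------------------------------------------------

# deterministic canonical reordering of a connected (or single-atom) molgraph
canonicalize_mol <- function(m) {
  n <- n_atoms(m)
  if (n <= 1L) return(m)
  elem_idx <- match(m$elem, .ELEMENTS)
  atom_color <- elem_idx * 1000L + (m$charge + 8L) * 16L + m$hyd
  nb <- nrow(m$bonds)
  if (nb == 0L) {
    ord <- order(atom_color, seq_len(n))
  } else {
    bond_color <- 100000L + m$bonds[, 3]
    edges <- rbind(
      cbind(m$bonds[, 1], n + seq_len(nb)),
      cbind(m$bonds[, 2], n + seq_len(nb))
    )
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    colors <- c(atom_color, bond_color)
    lab <- igraph::canonical_permutation(g, colors = colors)$labeling
    ord <- order(lab[seq_len(n)])
  }
  perm <- integer(n)
  perm[ord] <- seq_len(n)          # old index -> new index
  b <- m$bonds
  if (nrow(b)) {
    b[, 1] <- perm[b[, 1]]
    b[, 2] <- perm[b[, 2]]
  }
  molgraph(m$elem[ord], m$charge[ord], m$hyd[ord], b)
}
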