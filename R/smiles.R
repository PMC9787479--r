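# Restricted SMILES dialect: elements C, N, O, Fe, H; bonds -, =, #; branches;
# ring-closure digits (and %nn); bracket atoms with explicit H count and
# charge. No aromatic atoms, no stereochemistry, no isotopes. Bare C/N/O get
# implicit hydrogens up to their default valence (4/3/2); bracket atoms carry
# exactly the hydrogens written.

#' Parse a line-notation (SMILES) string into a molecular graph
#'
#' @param s a SMILES string in the restricted dialect
#' @return a `molgraph`
#' @keywords internal
smiles_parse <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("malformed input: empty or non-string SMILES", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  pos <- 1L
  elem <- character(0); charge <- integer(0); hyd <- integer(0)
  explicit <- logical(0)   # bracket atom (H count fixed)?
  bonds <- matrix(integer(0), ncol = 3)
  stack <- integer(0)      # branch stack of atom indices
  prev <- 0L               # previous atom index
  pending_order <- NA_integer_
  ring <- list()           # closure digit -> c(atom, order)

  add_atom <- function(e, q, h, expl) {
    elem <<- c(elem, e); charge <<- c(charge, q); hyd <<- c(hyd, h)
    explicit <<- c(explicit, expl)
    idx <- length(elem)
    if (prev > 0L) {
      o <- if (is.na(pending_order)) 1L else pending_order
      bonds <<- rbind(bonds, c(prev, idx, o))
    }
    pending_order <<- NA_integer_
    prev <<- idx
    idx
  }

  fail <- function(tok) {
    stop(sprintf("malformed input: unexpected token '%s' at position %d in \"%s\"",
                 tok, pos, s), call. = FALSE)
  }

  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "(") {
      if (prev == 0L) fail("(")
      stack <- c(stack, prev)
      pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) fail(")")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch == "=") {
      pending_order <- 2L; pos <- pos + 1L
    } else if (ch == "#") {
      pending_order <- 3L; pos <- pos + 1L
    } else if (ch == "-") {
      pending_order <- 1L; pos <- pos + 1L
    } else if (ch %in% c("C", "N", "O")) {
      add_atom(ch, 0L, NA_integer_, FALSE)
      pos <- pos + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (pos + 2L > n) fail("%")
        d <- paste0(chars[pos + 1L], chars[pos + 2L])
        pos <- pos + 3L
      } else {
        d <- ch
        pos <- pos + 1L
      }
      if (prev == 0L) fail(d)
      o <- if (is.na(pending_order)) NA_integer_ else pending_order
      pending_order <- NA_integer_
      if (!is.null(ring[[d]])) {
        op <- ring[[d]]
        oo <- if (!is.na(op[2])) op[2] else if (!is.na(o)) o else 1L
        if (!is.na(op[2]) && !is.na(o) && op[2] != o)
          fail(paste0("ring bond order mismatch at closure ", d))
        bonds <- rbind(bonds, c(op[1], prev, oo))
        ring[[d]] <- NULL
      } else {
        ring[[d]] <- c(prev, o)
      }
    } else if (ch == "[") {
      close <- pos
      while (close <= n && chars[close] != "]") close <- close + 1L
      if (close > n) fail("[")
      body <- paste0(chars[(pos + 1L):(close - 1L)], collapse = "")
      mm <- regmatches(body,
        regexec("^(Fe|C|N|O|H)(H([0-9]?))?(([+-])([0-9]?))?$", body))[[1]]
      if (!length(mm)) {
        if (grepl("^[A-Za-z]{1,2}", body))
          stop(sprintf("unsupported element in bracket atom '[%s]'", body),
               call. = FALSE)
        fail(paste0("[", body, "]"))
      }
      e <- mm[2]
      h <- if (nzchar(mm[3])) {
        if (nzchar(mm[4])) as.integer(mm[4]) else 1L
      } else 0L
      q <- 0L
      if (nzchar(mm[5])) {
        mag <- if (nzchar(mm[7])) as.integer(mm[7]) else 1L
        q <- if (mm[6] == "+") mag else -mag
      }
      if (e == "H" && h > 0L) fail(paste0("[", body, "]"))
      add_atom(e, q, h, TRUE)
      pos <- close + 1L
    } else if (ch == " ") {
      pos <- pos + 1L
    } else {
      if (grepl("[A-Za-z]", ch))
        stop(sprintf("unsupported element '%s' in \"%s\"", ch, s),
             call. = FALSE)
      fail(ch)
    }
  }
  if (length(ring))
    stop(sprintf("malformed input: unclosed ring bond in \"%s\"", s),
         call. = FALSE)
  if (length(stack))
    stop(sprintf("malformed input: unclosed branch in \"%s\"", s),
         call. = FALSE)
  if (!length(elem))
    stop(sprintf("malformed input: no atoms in \"%s\"", s), call. = FALSE)

  m <- molgraph(elem, charge, ifelse(is.na(hyd), 0L, hyd), bonds)
  # fill implicit hydrogens on bare organic-subset atoms
  bsum <- bond_order_sums(m)
  for (i in seq_along(elem)) {
    if (!explicit[i]) {
      dv <- .ELEM_DEFVAL[[elem[i]]]
      h <- dv - bsum[i]
      if (h < 0L)
        stop(sprintf("malformed input: valence of %s exceeded in \"%s\"",
                     elem[i], s), call. = FALSE)
      m$hyd[i] <- h
    }
  }
  if (!valence_ok(m))
    stop(sprintf("malformed input: valence violation in \"%s\"", s),
         call. = FALSE)
  if (length(mol_components(m)) > 1L)
    stop(sprintf("malformed input: disconnected species in \"%s\" (one molecule per string)", s),
         call. = FALSE)
  m
}

#' Write a molecular graph as SMILES, in the atom order given
#'
#' Deterministic writer: depth-first from atom 1, neighbors visited in index
#' order, ring closures numbered in discovery order. Applied to a canonically
#' ordered graph this yields the canonical id.
#' @keywords internal
smiles_write <- function(m) {
  n <- n_atoms(m)
  adj <- vector("list", n)
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      i <- m$bonds[k, 1]; j <- m$bonds[k, 2]; o <- m$bonds[k, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
    adj <- lapply(adj, function(a) a[order(a[, 1]), , drop = FALSE])
  }
  visited <- logical(n)
  ring_num <- 0L
  ring_open <- list()  # key "i-j" -> digit
  bondsym <- c("", "=", "#")

  atom_token <- function(i) {
    e <- m$elem[i]; q <- m$charge[i]; h <- m$hyd[i]
    bs <- sum(if (is.null(adj[[i]])) 0L else adj[[i]][, 2])
    if (q == 0L && e %in% names(.ELEM_DEFVAL) && h == .ELEM_DEFVAL[[e]] - bs)
      return(e)
    qs <- if (q == 0L) "" else {
      sgn <- if (q > 0L) "+" else "-"
      if (abs(q) == 1L) sgn else paste0(sgn, abs(q))
    }
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    paste0("[", e, hs, qs, "]")
  }

  # pre-pass: find ring (non-tree) edges via the same DFS order
  ring_edges <- character(0)
  dfs_mark <- function(i, parent) {
    visited[i] <<- TRUE
    if (!is.null(adj[[i]])) {
      for (r in seq_len(nrow(adj[[i]]))) {
        j <- adj[[i]][r, 1]
        if (j == parent) next
        if (visited[j]) {
          key <- paste(min(i, j), max(i, j), sep = "-")
          if (!key %in% ring_edges) ring_edges <<- c(ring_edges, key)
        } else {
          dfs_mark(j, i)
        }
      }
    }
  }
  dfs_mark(1L, 0L)
  visited <- logical(n)

  write_atom <- function(i, parent, bond_in) {
    visited[i] <<- TRUE
    out <- if (bond_in > 0L) bondsym[bond_in] else ""
    out <- paste0(out, atom_token(i))
    closures <- ""
    children <- list()
    if (!is.null(adj[[i]])) {
      for (r in seq_len(nrow(adj[[i]]))) {
        j <- adj[[i]][r, 1]; o <- adj[[i]][r, 2]
        if (j == parent) next
        key <- paste(min(i, j), max(i, j), sep = "-")
        if (key %in% ring_edges) {
          if (!is.null(ring_open[[key]])) {
            closures <- paste0(closures, ring_open[[key]]$digit)
            ring_open[[key]] <<- NULL
          } else {
            ring_num <<- ring_num + 1L
            digit <- if (ring_num < 10L) as.character(ring_num)
                     else sprintf("%%%02d", ring_num)
            ring_open[[key]] <<- list(digit = digit)
            closures <- paste0(closures, bondsym[o], digit)
          }
        } else if (!visited[j]) {
          children[[length(children) + 1L]] <- c(j, o)
        }
      }
    }
    out <- paste0(out, closures)
    if (length(children)) {
      for (c_i in seq_along(children)) {
        j <- children[[c_i]][1]; o <- children[[c_i]][2]
        piece <- write_atom(j, i, o)
        if (c_i < length(children)) piece <- paste0("(", piece, ")")
        out <- paste0(out, piece)
      }
    }
    out
  }
  write_atom(1L, 0L, 0L)
}

#' Canonical SMILES of a molecular graph
#' @keywords internal
canonical_smiles <- function(m) smiles_write(canonicalize_mol(m))
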