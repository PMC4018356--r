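#' @keywords internal
"_PACKAGE"

# Element data --------------------------------------------------------------

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ELEMS <- c("B", "C", "N", "O", "P", "S")

.ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.453, K = 39.098, Ca = 40.078, Zn = 65.38, Br = 79.904, I = 126.904
)

.KNOWN_ELEMENTS <- c(
  "H", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P", "S", "Cl",
  "K", "Ca", "Zn", "Br", "I", "Li", "Be", "Se", "As", "Sn", "Te", "Cu",
  "Fe", "Mn", "Co", "Ni", "Ag", "Au", "Pt", "Hg", "Pb", "Ba", "Sr"
)

.VDW_RADII <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Si = 2.10,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

# default valence lists used for implicit hydrogen assignment
.VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Construct a molecular graph
#'
#' A `molgraph` is the heavy-atom/bond graph underlying all featurization in
#' this package: atoms carry element symbol, formal charge, aromatic flag and
#' an implicit hydrogen count; bonds carry endpoint indices and an order
#' (1, 2, 3, or 1.5 for aromatic).
#'
#' @param atoms data.frame with columns `symbol`, `charge`, `aromatic`,
#'   `hcount`.
#' @param bonds data.frame with columns `a1`, `a2`, `order`.
#' @param id compound identifier.
#' @param source_smiles SMILES string the graph was built from, if any.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds, id = NA_character_,
                     source_smiles = NA_character_) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(atoms) < 1L) stop("molgraph requires at least one heavy atom")
  if (nrow(bonds) > 0L) {
    idx <- c(bonds$a1, bonds$a2)
    if (any(idx < 1L | idx > nrow(atoms)))
      stop("bond endpoint indices out of range")
  }
  structure(
    list(atoms = atoms, bonds = bonds, id = id, source_smiles = source_smiles),
    class = "molgraph"
  )
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph %s: %d atoms, %d bonds>\n",
              ifelse(is.na(x$id), "", x$id), n_atoms(x), nrow(x$bonds)))
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param mol a `molgraph`.
#' @return integer count of heavy atoms.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Molecular weight including implicit hydrogens
#' @param mol a `molgraph`.
#' @return weight in g/mol.
#' @export
molecular_weight <- function(mol) {
  w <- .ATOMIC_WEIGHTS[mol$atoms$symbol]
  w[is.na(w)] <- 0
  sum(w) + sum(mol$atoms$hcount) * .ATOMIC_WEIGHTS[["H"]]
}

# adjacency list: element i = data.frame(nbr, order, bond)
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(0), order = numeric(0))
  b <- mol$bonds
  if (nrow(b) > 0L) {
    for (k in seq_len(nrow(b))) {
      i <- b$a1[k]; j <- b$a2[k]; o <- b$order[k]
      adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$order <- c(adj[[i]]$order, o)
      adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$order <- c(adj[[j]]$order, o)
    }
  }
  adj
}

# connected components; returns integer membership vector
graph_components <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]$nbr) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# BFS graph distances from a source atom (Inf when unreachable)
bfs_distances <- function(adj, source) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[source] <- 0
  queue <- source
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]$nbr) if (!is.finite(d[w])) { d[w] <- d[v] + 1; queue <- c(queue, w) }
  }
  d
}

# implicit hydrogen count for an organic-subset atom given its bond orders.
# Aromatic neighbours contribute 1.5; aromatic atoms use the simplified
# sigma-count rule (c: 3 - degree; other aromatic elements: 0).
implicit_hydrogens <- function(symbol, aromatic, charge, orders) {
  if (aromatic) {
    if (symbol == "C") return(max(0L, 3L - length(orders)))
    if (symbol == "B") return(max(0L, 2L - length(orders)))
    return(0L)  # aromatic n/o/s/p without bracket H are pyridine-type
  }
  bsum <- ceiling(sum(orders))
  val <- .VALENCES[[symbol]]
  if (is.null(val)) return(0L)
  if (charge != 0) {
    if (symbol == "C") val <- val - abs(charge) else val <- val + charge
  }
  val <- val[val >= bsum]
  if (length(val) == 0L) return(0L)
  as.integer(min(val) - bsum)
}

# recompute implicit H for every organic-subset atom that has no explicit
# hydrogen specification (used after parsing and after H-folding)
assign_implicit_h <- function(mol, explicit = rep(FALSE, n_atoms(mol))) {
  adj <- adjacency(mol)
  for (i in seq_len(n_atoms(mol))) {
    if (explicit[i]) next
    a <- mol$atoms[i, ]
    if (!(a$symbol %in% .ORGANIC_SUBSET)) next
    mol$atoms$hcount[i] <- implicit_hydrogens(a$symbol, a$aromatic, a$charge,
                                              adj[[i]]$order)
  }
  mol
}

# Ring perception -----------------------------------------------------------

# bonds that lie on at least one cycle (non-bridges), by removal test
ring_bond_flags <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  flags <- logical(nb)
  for (k in seq_len(nb)) {
    m2 <- mol
    m2$bonds <- mol$bonds[-k, , drop = FALSE]
    adj2 <- adjacency(m2)
    d <- bfs_distances(adj2, mol$bonds$a1[k])
    flags[k] <- is.finite(d[mol$bonds$a2[k]])
  }
  flags
}

#' Smallest set of smallest rings
#'
#' Returns the SSSR of a molecular graph as a list of atom-index vectors.
#' The cyclomatic number (bonds - atoms + components) fixes the ring count;
#' candidate rings are the shortest cycles through each ring bond, selected
#' greedily by size under GF(2) independence of their bond sets.
#'
#' @param mol a `molgraph`.
#' @return list of integer vectors (ring atom indices, in ring order).
#' @export
sssr <- function(mol) {
  nb <- nrow(mol$bonds)
  comp <- graph_components(mol)
  mu <- nb - n_atoms(mol) + max(comp)
  if (mu <= 0L) return(list())
  rflags <- ring_bond_flags(mol)
  adj <- adjacency(mol)
  candidates <- list()
  for (k in which(rflags)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    # shortest a->b path avoiding bond k
    prev <- rep(0L, n_atoms(mol)); seen <- rep(FALSE, n_atoms(mol))
    seen[a] <- TRUE; queue <- a
    while (length(queue) > 0L && !seen[b]) {
      v <- queue[1L]; queue <- queue[-1L]
      nbrs <- adj[[v]]$nbr
      for (w in nbrs) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) { seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w) }
      }
    }
    if (!seen[b]) next
    path <- b
    while (path[1L] != a) path <- c(prev[path[1L]], path)
    candidates[[length(candidates) + 1L]] <- path
  }
  if (length(candidates) == 0L) return(list())
  # deduplicate by sorted atom set
  keys <- vapply(candidates, function(p) paste(sort(p), collapse = ","), "")
  candidates <- candidates[!duplicated(keys)]
  sizes <- lengths(candidates)
  candidates <- candidates[order(sizes)]
  # GF(2) independence over bond index space
  bond_id <- function(i, j) {
    hit <- which((mol$bonds$a1 == i & mol$bonds$a2 == j) |
                 (mol$bonds$a1 == j & mol$bonds$a2 == i))
    hit[1L]
  }
  basis <- matrix(0L, nrow = 0L, ncol = nb)
  chosen <- list()
  for (p in candidates) {
    vec <- integer(nb)
    np <- length(p)
    for (t in seq_len(np)) {
      vec[bond_id(p[t], p[if (t == np) 1L else t + 1L])] <- 1L
    }
    red <- vec
    if (nrow(basis) > 0L) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ] == 1L)[1L]
        if (red[piv] == 1L) red <- (red + basis[r, ]) %% 2L
      }
    }
    if (any(red == 1L)) {
      basis <- rbind(basis, red)
      chosen[[length(chosen) + 1L]] <- p
      if (length(chosen) == mu) break
    }
  }
  chosen
}

# Aromaticity perception for Kekule input: a single SSSR ring is aromatized
# when every ring atom is sp2-capable and the simple electron count obeys
# 4n+2. Fused-envelope aromaticity is out of scope; lowercase input aromaticity
# is always trusted.
perceive_aromaticity <- function(mol) {
  rings <- sssr(mol)
  if (length(rings) == 0L) return(mol)
  adj <- adjacency(mol)
  for (ring in rings) {
    if (length(ring) < 5L || length(ring) > 7L) next
    if (all(mol$atoms$aromatic[ring])) next
    pis <- integer(length(ring))
    ok <- TRUE
    for (t in seq_along(ring)) {
      i <- ring[t]
      a <- mol$atoms[i, ]
      if (a$aromatic) { pis[t] <- 1L; next }
      ords <- adj[[i]]$order
      nbrs <- adj[[i]]$nbr
      in_ring_dbl <- any(ords == 2 & nbrs %in% ring)
      exo_dbl <- any(ords == 2 & !(nbrs %in% ring))
      if (in_ring_dbl) {
        pis[t] <- 1L
      } else if (exo_dbl) {
        pis[t] <- 0L          # exocyclic =O etc: empty contribution
      } else if (a$symbol %in% c("N", "O", "S") && a$charge <= 0) {
        pis[t] <- 2L          # heteroatom lone pair
      } else {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    if (sum(pis) %% 4L != 2L) next
    mol$atoms$aromatic[ring] <- TRUE
    for (t in seq_along(ring)) {
      j <- ring[if (t == length(ring)) 1L else t + 1L]
      k <- which((mol$bonds$a1 == ring[t] & mol$bonds$a2 == j) |
                 (mol$bonds$a1 == j & mol$bonds$a2 == ring[t]))
      mol$bonds$order[k] <- 1.5
    }
  }
  mol
}

#' Test two molecular graphs for isomorphism
#'
#' Compares canonical whole-molecule keys (element, charge, aromatic flag,
#' hydrogen count, bond orders), so the result is independent of atom
#' numbering.
#'
#' @param a,b `molgraph` objects.
#' @return logical.
#' @export
is_isomorphic <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || nrow(a$bonds) != nrow(b$bonds)) return(FALSE)
  identical(molecule_key(a), molecule_key(b))
}
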