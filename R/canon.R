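# Canonical rooted-subgraph strings.
#
# ACF keys and whole-molecule isomorphism keys both need a string that is
# invariant under atom relabelling. The scheme: iterative partition
# refinement (Weisfeiler-Lehman style) seeded with chemically meaningful
# invariants, followed by individualization of tied cells with a
# lexicographic-minimum search, and finally a deterministic DFS rendering
# with ring-closure labels. Fragments are small (tens of atoms), so the
# worst-case search cost is never a concern in practice.

# refine integer colors until the partition is stable. Input and output
# numberings are permutation-invariant (derived from sorted signatures), so
# the stopping test compares partitions, not raw numberings.
wl_refine <- function(colors, adjn, adjo) {
  repeat {
    sig <- vapply(seq_along(colors), function(i) {
      nb <- adjn[[i]]
      if (length(nb) == 0L) return(sprintf("%d|", colors[i]))
      pairs <- sort(paste0(adjo[[i]], ":", colors[nb]))
      paste0(colors[i], "|", paste(pairs, collapse = ","))
    }, "")
    new_colors <- match(sig, sort(unique(sig)))
    same_partition <- identical(match(colors, unique(colors)),
                                match(new_colors, unique(new_colors)))
    if (same_partition) return(new_colors)
    colors <- new_colors
  }
}

# deterministic DFS string given a discrete (or orbit-stable) coloring
render_canonical <- function(start, labels, colors, adjn, adjo) {
  n <- length(labels)
  visited <- rep(FALSE, n)
  ring_id <- 0L
  ring_open <- new.env(parent = emptyenv())
  closure_of <- vector("list", n)

  # pass 1: identify back edges under rank-ordered DFS
  back <- character(0)
  seen <- rep(FALSE, n)
  ekey <- function(i, j) paste(min(i, j), max(i, j), sep = "-")
  d1 <- function(v, from) {
    seen[v] <<- TRUE
    nb <- adjn[[v]]
    ordnb <- nb[order(colors[nb], nb)]
    for (w in ordnb) {
      if (!is.na(from) && w == from) next
      k <- ekey(v, w)
      if (seen[w]) { if (!(k %in% back)) back <<- c(back, k) }
      else if (!(k %in% back)) d1(w, v)
    }
  }
  d1(start, NA_integer_)

  emit <- function(v, from) {
    visited[v] <<- TRUE
    nb <- adjn[[v]]
    ords <- adjo[[v]]
    pr <- order(colors[nb], nb)
    closures <- ""
    child_str <- character(0)
    for (t in pr) {
      w <- nb[t]
      if (!is.na(from) && w == from) next
      k <- ekey(v, w)
      if (k %in% back) {
        if (!is.null(ring_open[[k]])) {
          closures <- paste0(closures, ords[t], "%", ring_open[[k]])
        } else {
          ring_id <<- ring_id + 1L
          ring_open[[k]] <- ring_id
          closures <- paste0(closures, ords[t], "%", ring_id)
        }
      } else if (!visited[w]) {
        child_str <- c(child_str, paste0(ords[t], emit(w, v)))
      }
    }
    out <- paste0(labels[v], closures)
    if (length(child_str) > 0L)
      out <- paste0(out, paste0("(", child_str, ")", collapse = ""))
    out
  }
  emit(start, NA_integer_)
}

# canonical string for a vertex-labelled small graph.
#   labels: per-atom invariant label strings (already include center marks etc.)
#   adjn/adjo: adjacency (neighbor indices / bond-order strings)
#   root: fixed root index, or NA to canonicalize over the minimum-rank cell
canonical_string <- function(labels, adjn, adjo, root = NA_integer_,
                             seed_colors = NULL) {
  n <- length(labels)
  if (n == 1L) return(labels[1L])
  colors <- if (is.null(seed_colors)) match(labels, sort(unique(labels)))
             else seed_colors
  colors <- wl_refine(colors, adjn, adjo)

  canon_rec <- function(colors) {
    # find first tied cell (smallest color with >1 member)
    tab <- table(colors)
    tied <- as.integer(names(tab)[tab > 1L])
    if (length(tied) == 0L) {
      start <- if (is.na(root)) which.min(colors) else root
      return(render_canonical(start, labels, colors, adjn, adjo))
    }
    cell <- which(colors == tied[1L])
    best <- NULL
    for (cand in cell) {
      c2 <- colors
      c2[cand] <- 0L                       # individualize below all others
      c2 <- match(c2, sort(unique(c2)))
      c2 <- wl_refine(c2, adjn, adjo)
      s <- canon_rec(c2)
      if (is.null(best) || s < best) best <- s
    }
    best
  }
  canon_rec(colors)
}

bond_order_token <- function(o) {
  if (o == 1) "-" else if (o == 2) "=" else if (o == 3) "#" else ":"
}

# canonical rooted-tree string (AHU): children rendered recursively and
# sorted lexicographically. Used as a fast path for acyclic fragments.
ahu_string <- function(root, labels, adjn, adjo) {
  rec <- function(v, from) {
    nb <- adjn[[v]]
    out <- labels[v]
    if (length(nb) > 0L) {
      parts <- character(0)
      for (t in seq_along(nb)) {
        w <- nb[t]
        if (!is.na(from) && w == from) next
        parts <- c(parts, paste0(adjo[[v]][t], rec(w, v)))
      }
      if (length(parts) > 0L)
        out <- paste0(out, paste0("(", sort(parts), ")", collapse = ""))
    }
    out
  }
  rec(root, NA_integer_)
}

# canonical key of an induced subgraph of mol.
#   atoms_idx: atom indices of the fragment
#   center: atom index (in mol numbering) marked as the ACF center, or NA
#   cuts: integer vector (per fragment atom) of bonds severed at the boundary
#   adj: optional precomputed molecule adjacency
fragment_canonical_key <- function(mol, atoms_idx, center = NA_integer_,
                                   cuts = NULL, adj = NULL) {
  sub_n <- length(atoms_idx)
  if (is.null(adj)) adj <- adjacency(mol)
  pos <- integer(n_atoms(mol)); pos[atoms_idx] <- seq_len(sub_n)
  adjn <- vector("list", sub_n)
  adjo <- vector("list", sub_n)
  n_edges <- 0L
  for (t in seq_len(sub_n)) {
    nb <- adj[[atoms_idx[t]]]$nbr
    keep <- pos[nb] > 0L
    adjn[[t]] <- pos[nb[keep]]
    adjo[[t]] <- vapply(adj[[atoms_idx[t]]]$order[keep], bond_order_token, "")
    n_edges <- n_edges + sum(keep)
  }
  n_edges <- n_edges / 2L
  if (is.null(cuts)) cuts <- integer(sub_n)
  sym <- mol$atoms$symbol[atoms_idx]
  arom <- mol$atoms$aromatic[atoms_idx]
  chg <- mol$atoms$charge[atoms_idx]
  labels <- paste0(
    ifelse(!is.na(center) & atoms_idx == center, "!", ""),
    ifelse(arom, tolower(sym), sym),
    ifelse(chg == 0L, "", sprintf("%+d", chg)),
    strrep("*", cuts)
  )
  root <- if (is.na(center)) NA_integer_ else pos[center]
  if (n_edges == sub_n - 1L && !is.na(root)) {
    # acyclic connected fragment: rooted-tree canonical form, no search
    return(ahu_string(root, labels, adjn, adjo))
  }
  # seed colors with graph distance from the center for faster, stabler
  # refinement of rooted fragments
  seed <- NULL
  if (!is.na(center)) {
    dmat <- local({
      d <- rep(Inf, sub_n); d[root] <- 0; q <- root
      while (length(q) > 0L) {
        v <- q[1L]; q <- q[-1L]
        for (w in adjn[[v]]) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
      }
      d
    })
    sig <- paste0(dmat, "|", labels)
    seed <- match(sig, sort(unique(sig)))
  }
  canonical_string(labels, adjn, adjo, root = root, seed_colors = seed)
}

#' Canonical whole-molecule key
#'
#' A string invariant under atom renumbering, built from element, charge,
#' aromatic flag, hydrogen count and bond orders. Two graphs are isomorphic
#' (under those attributes) iff their keys are equal.
#'
#' @param mol a [molgraph].
#' @return character key.
#' @export
molecule_key <- function(mol) {
  n <- n_atoms(mol)
  adjn <- vector("list", n); adjo <- vector("list", n)
  for (t in seq_len(n)) { adjn[[t]] <- integer(0); adjo[[t]] <- character(0) }
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    tok <- bond_order_token(b$order[k])
    adjn[[i]] <- c(adjn[[i]], j); adjo[[i]] <- c(adjo[[i]], tok)
    adjn[[j]] <- c(adjn[[j]], i); adjo[[j]] <- c(adjo[[j]], tok)
  }
  labels <- vapply(seq_len(n), function(t) {
    a <- mol$atoms[t, ]
    sym <- if (a$aromatic) tolower(a$symbol) else a$symbol
    chg <- if (a$charge == 0L) "" else sprintf("%+d", a$charge)
    paste0(sym, chg, "H", a$hcount)
  }, "")
  canonical_string(labels, adjn, adjo, root = NA_integer_)
}
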