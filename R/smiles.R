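# SMILES reading and writing.
#
# The supported dialect covers the organic subset (B C N O P S F Cl Br I),
# aromatic lowercase atoms, bracket atoms with isotope/H-count/charge,
# branches, ring closures (including %nn), dot-separated fragments and
# explicit bond symbols - = # : (/ and \ are accepted and read as single;
# stereo descriptors are dropped). This is the dialect the synthetic-library
# generator emits and the one supported throughout the package.

.BOND_CHARS <- c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1)

#' Parse a SMILES string into a molecular graph
#'
#' Builds the heavy-atom graph, assigns implicit hydrogens by the standard
#' valence model, and perceives aromaticity (lowercase notation is trusted;
#' Kekule rings are aromatized by a simple Hueckel rule).
#'
#' @param text a single SMILES string.
#' @param id optional compound identifier attached to the graph.
#' @return A [molgraph].
#' @export
#' @examples
#' mol <- parse_smiles("c1ccccc1O", id = "phenol")
#' n_atoms(mol)
parse_smiles <- function(text, id = NA_character_) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || nchar(text) == 0L)
    stop("SMILES must be a single non-empty string")
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)

  atoms <- list()   # each: list(symbol, charge, aromatic, hcount, explicit_h)
  bonds <- list()   # each: list(a1, a2, order)
  prev <- NA_integer_
  pending <- NA_real_
  stack <- integer(0)
  rings <- list()   # label -> list(atom, order)

  perr <- function(i, msg) {
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 i, chars[min(i, n)], msg), call. = FALSE)
  }

  add_atom <- function(symbol, charge, aromatic, hcount, explicit_h) {
    atoms[[length(atoms) + 1L]] <<- list(symbol = symbol, charge = charge,
                                         aromatic = aromatic, hcount = hcount,
                                         explicit_h = explicit_h)
    idx <- length(atoms)
    if (!is.na(prev)) {
      o <- pending
      if (is.na(o)) o <- if (atoms[[prev]]$aromatic && aromatic) 1.5 else 1
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = idx, order = o)
    }
    prev <<- idx
    pending <<- NA_real_
    idx
  }

  close_ring <- function(label, i) {
    lab <- as.character(label)
    if (is.na(prev)) perr(i, "ring closure before any atom")
    if (is.null(rings[[lab]])) {
      rings[[lab]] <<- list(atom = prev, order = pending)
      pending <<- NA_real_
    } else {
      open <- rings[[lab]]
      o <- pending
      if (is.na(o)) o <- open$order
      if (!is.na(open$order) && !is.na(pending) && open$order != pending)
        perr(i, "conflicting ring-closure bond orders")
      if (is.na(o)) o <- if (atoms[[open$atom]]$aromatic && atoms[[prev]]$aromatic) 1.5 else 1
      if (open$atom == prev) perr(i, "ring closure to self")
      bonds[[length(bonds) + 1L]] <<- list(a1 = open$atom, a2 = prev, order = o)
      rings[[lab]] <<- NULL
      pending <<- NA_real_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% names(.BOND_CHARS)) {
      pending <- unname(.BOND_CHARS[ch]); i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) perr(i, "branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) perr(i, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_real_; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        perr(i, "%% must be followed by two digits")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), i); i <- i + 3L
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) perr(i, "unterminated bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) perr(i, sprintf("malformed bracket atom '[%s]'", body))
      sym_raw <- m[3]
      aromatic <- sym_raw == tolower(sym_raw) && nchar(sym_raw) <= 2L &&
        toupper(substr(sym_raw, 1, 1)) %in% substr(.AROMATIC_ELEMS, 1, 1)
      symbol <- paste0(toupper(substr(sym_raw, 1, 1)), substring(sym_raw, 2))
      if (aromatic && !(symbol %in% .AROMATIC_ELEMS)) aromatic <- FALSE
      if (!(symbol %in% .KNOWN_ELEMENTS))
        perr(i, sprintf("unknown element '%s'", sym_raw))
      hc <- 0L
      if (nchar(m[5]) > 0L) {
        hc <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
      }
      charge <- 0L
      if (nchar(m[6]) > 0L) {
        cs <- m[6]
        if (grepl("^\\++$", cs)) charge <- nchar(cs)
        else if (grepl("^-+$", cs)) charge <- -nchar(cs)
        else if (grepl("^\\+[0-9]+$", cs)) charge <- as.integer(substring(cs, 2))
        else charge <- -as.integer(substring(cs, 2))
      }
      add_atom(symbol, charge, aromatic, hc, explicit_h = TRUE)
      i <- j + 1L
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, 0L, FALSE, 0L, FALSE); i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        add_atom(ch, 0L, FALSE, 0L, FALSE); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), 0L, TRUE, 0L, FALSE); i <- i + 1L
      } else {
        perr(i, "unrecognized atom symbol")
      }
    } else {
      perr(i, "unrecognized token")
    }
  }
  if (length(rings) > 0L) stop("SMILES parse error: unclosed ring bond(s)")
  if (length(atoms) == 0L) stop("SMILES parse error: no atoms")

  at <- data.frame(
    symbol = vapply(atoms, `[[`, "", "symbol"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    hcount = vapply(atoms, `[[`, 0L, "hcount"),
    stringsAsFactors = FALSE
  )
  bd <- if (length(bonds) == 0L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  } else {
    data.frame(
      a1 = vapply(bonds, `[[`, 0L, "a1"),
      a2 = vapply(bonds, `[[`, 0L, "a2"),
      order = vapply(bonds, `[[`, 0, "order")
    )
  }
  mol <- molgraph(at, bd, id = id, source_smiles = text)
  explicit <- vapply(atoms, `[[`, FALSE, "explicit_h")
  mol <- assign_implicit_h(mol, explicit)
  perceive_aromaticity(mol)
}

#' Write a molecular graph as a SMILES string
#'
#' Emits a parseable SMILES (not necessarily canonical). The round trip
#' parse -> write -> parse yields an isomorphic graph.
#'
#' @param mol a [molgraph].
#' @return a SMILES string.
#' @export
write_smiles <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  comp <- graph_components(mol)

  # ring-closure bookkeeping: assign labels to back edges during DFS
  visited <- rep(FALSE, n)
  ring_label <- 0L
  open_labels <- list()  # key "i-j" sorted -> label
  closure_at <- vector("list", n)  # atom -> list of (label, order)

  edge_key <- function(i, j) paste(min(i, j), max(i, j), sep = "-")

  # pass 1: recursive DFS in adjacency order (identical to the emit pass)
  # classifying each edge as tree or back; back edges become ring closures
  pre_back <- character(0)
  seen1 <- rep(FALSE, n)
  dfs1 <- function(v, from) {
    seen1[v] <<- TRUE
    for (w in adj[[v]]$nbr) {
      if (!is.na(from) && w == from) next
      k <- edge_key(v, w)
      if (seen1[w]) {
        if (!(k %in% pre_back)) pre_back <<- c(pre_back, k)
      } else if (!(k %in% pre_back)) {
        dfs1(w, v)
      }
    }
  }

  bond_sym <- function(o, arom_pair) {
    if (o == 2) return("=")
    if (o == 3) return("#")
    if (o == 1.5) return(if (arom_pair) "" else ":")
    if (o == 1 && arom_pair) return("-")
    ""
  }

  atom_token <- function(i, orders) {
    a <- mol$atoms[i, ]
    sym <- if (a$aromatic) tolower(a$symbol) else a$symbol
    plain_ok <- a$symbol %in% .ORGANIC_SUBSET && a$charge == 0L
    if (plain_ok) {
      implied <- implicit_hydrogens(a$symbol, a$aromatic, a$charge, orders)
      if (implied == a$hcount) return(sym)
    }
    hstr <- if (a$hcount == 0L) "" else if (a$hcount == 1L) "H" else paste0("H", a$hcount)
    cstr <- if (a$charge == 0L) "" else if (a$charge > 0L)
      paste0("+", if (a$charge > 1L) a$charge else "") else
      paste0("-", if (a$charge < -1L) -a$charge else "")
    paste0("[", sym, hstr, cstr, "]")
  }

  emit <- function(v, from) {
    visited[v] <<- TRUE
    nbrs <- adj[[v]]$nbr
    ords <- adj[[v]]$order
    # ring closure digits opened toward v
    closures <- ""
    keep <- integer(0); keep_o <- numeric(0)
    for (t in seq_along(nbrs)) {
      w <- nbrs[t]
      if (!is.na(from) && w == from) next
      k <- edge_key(v, w)
      if (visited[w]) {
        # back edge: open or close a ring label
        if (!is.null(open_labels[[k]])) {
          lab <- open_labels[[k]]$label
          open_labels[[k]] <<- NULL
          closures <- paste0(closures,
            bond_sym(ords[t], mol$atoms$aromatic[v] && mol$atoms$aromatic[w]),
            if (lab > 9L) paste0("%", lab) else lab)
        }
      } else if (!(k %in% names(open_labels)) && (k %in% pre_back_set)) {
        ring_label <<- ring_label + 1L
        open_labels[[k]] <<- list(label = ring_label)
        closures <- paste0(closures,
          bond_sym(ords[t], mol$atoms$aromatic[v] && mol$atoms$aromatic[w]),
          if (ring_label > 9L) paste0("%", ring_label) else ring_label)
      } else {
        keep <- c(keep, w); keep_o <- c(keep_o, ords[t])
      }
    }
    out <- paste0(atom_token(v, adj[[v]]$order), closures)
    if (length(keep) > 0L) {
      parts <- character(0)
      for (t in seq_along(keep)) {
        w <- keep[t]
        if (visited[w]) next  # became visited via a ring path
        sub <- emit(w, v)
        parts <- c(parts, paste0(
          bond_sym(keep_o[t], mol$atoms$aromatic[v] && mol$atoms$aromatic[w]), sub))
      }
      if (length(parts) > 1L) {
        out <- paste0(out,
          paste0(vapply(parts[-length(parts)], function(p) paste0("(", p, ")"), ""),
                 collapse = ""),
          parts[length(parts)])
      } else if (length(parts) == 1L) {
        out <- paste0(out, parts[1L])
      }
    }
    out
  }

  roots <- unname(vapply(split(seq_len(n), comp), min, 0L))
  for (root in roots) dfs1(root, NA_integer_)
  pre_back_set <- pre_back
  pieces <- character(0)
  for (root in roots) {
    if (!visited[root]) pieces <- c(pieces, emit(root, NA_integer_))
  }
  paste(pieces, collapse = ".")
}
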