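# Sparse structural feature sets: circular (ECFP-style) fingerprints and
# atom-center fragments (ACF).
#
# Both featurizers emit a `featureset`: a named integer vector of occurrence
# counts whose names are canonical feature keys. Keys embed the family and
# the level/diameter ("ACF2:..." / "CIRC4:..."), so features from different
# configurations never collide.

#' Construct a feature set
#'
#' @param compound_id compound identifier.
#' @param keys character vector of feature keys (may repeat).
#' @return object of class `featureset`: named integer vector of counts with
#'   attribute `compound_id`.
#' @export
featureset <- function(compound_id, keys = character(0)) {
  counts <- if (length(keys) == 0L) {
    structure(integer(0), names = character(0))
  } else {
    tab <- table(keys)
    structure(as.integer(tab), names = names(tab))
  }
  structure(counts, compound_id = compound_id, class = "featureset")
}

#' @export
print.featureset <- function(x, ...) {
  cat(sprintf("<featureset %s: %d unique features, %d total>\n",
              attr(x, "compound_id"), length(x), sum(x)))
  invisible(x)
}

#' Feature keys present in a feature set
#' @param fs a `featureset`.
#' @return character vector of keys.
#' @export
feature_keys <- function(fs) names(fs)

# 31-bit modular mixing hash: exact in double arithmetic, fixed across
# platforms. Values are reduced mod (2^31 - 1); multiplier 31.
.HASH_MOD <- 2147483647
mix_hash <- function(values) {
  h <- 17
  for (v in values) h <- (h * 31 + (v %% .HASH_MOD) + 1) %% .HASH_MOD
  h
}

# numeric code of an atom's initial invariant
atom_invariant <- function(mol, adj, i) {
  a <- mol$atoms[i, ]
  elem <- match(a$symbol, names(.ATOMIC_WEIGHTS))
  if (is.na(elem)) elem <- 99L
  mix_hash(c(elem, a$charge + 10L, length(adj[[i]]$nbr), a$hcount,
             as.integer(a$aromatic)))
}

#' Sparse circular fingerprint (ECFP-style)
#'
#' Iterative neighborhood hashing: every atom starts from an invariant of
#' (element, charge, degree, attached hydrogens, aromatic flag); each of the
#' `diameter/2` update rounds hashes the atom's own identifier together with
#' the sorted (bond order, neighbor identifier) pairs. Environments covering
#' an atom set already produced by an earlier (or same-round, smaller-id)
#' environment are removed. Identifiers are sparse 31-bit integers; no
#' folding is applied, since downstream learners consume feature sets.
#'
#' @param mol a standardized [molgraph].
#' @param diameter even integer, 4 or 6 (the number of update rounds is
#'   `diameter/2`).
#' @return a [featureset] of keys `"CIRC<diameter>:<id>"` with environment
#'   counts.
#' @export
circular_fingerprint <- function(mol, diameter = 4) {
  stopifnot(diameter %% 2 == 0, diameter >= 2)
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  n_rounds <- diameter / 2

  ids <- vapply(seq_len(n), function(i) atom_invariant(mol, adj, i), 0)
  # env sets per atom, growing each round
  env <- lapply(seq_len(n), function(i) i)

  bond_code <- function(o) if (o == 1.5) 4 else as.integer(o)

  accepted_sets <- character(0)
  feats <- character(0)
  # round 0: every atom is an environment
  ord0 <- order(ids, vapply(env, function(s) paste(sort(s), collapse = ","), ""))
  for (i in ord0) {
    key <- paste(sort(env[[i]]), collapse = ",")
    if (key %in% accepted_sets) next
    accepted_sets <- c(accepted_sets, key)
    feats <- c(feats, sprintf("CIRC%d:%.0f", diameter, ids[i]))
  }

  for (r in seq_len(n_rounds)) {
    new_ids <- numeric(n)
    new_env <- vector("list", n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]$nbr
      if (length(nb) == 0L) {
        new_ids[i] <- mix_hash(c(r, ids[i]))
        new_env[[i]] <- env[[i]]
        next
      }
      pairs <- cbind(vapply(adj[[i]]$order, bond_code, 0), ids[nb])
      ord <- order(pairs[, 1], pairs[, 2])
      new_ids[i] <- mix_hash(c(r, ids[i], t(pairs[ord, , drop = FALSE])))
      new_env[[i]] <- sort(unique(c(env[[i]], unlist(env[nb]))))
    }
    ids <- new_ids
    env <- new_env
    ordr <- order(ids, vapply(env, function(s) paste(s, collapse = ","), ""))
    for (i in ordr) {
      key <- paste(env[[i]], collapse = ",")
      if (key %in% accepted_sets) next
      accepted_sets <- c(accepted_sets, key)
      feats <- c(feats, sprintf("CIRC%d:%.0f", diameter, ids[i]))
    }
  }
  featureset(mol$id, feats)
}

#' Enumerate atom-center fragments at one level
#'
#' For every heavy atom, the ACF of level `n` is the induced subgraph of all
#' atoms within graph distance `n` of the center, keeping the bonding
#' topology inside the fragment (ring-closure bonds between in-reach atoms
#' are retained). The center is marked in the canonical key; bonds severed
#' at the fragment boundary are recorded as attachment-point markers. One
#' fragment is emitted per heavy atom, so occurrence counts at a fixed level
#' always sum to the heavy-atom count.
#'
#' @param mol a standardized [molgraph].
#' @param level fragment radius in bonds (1..6).
#' @return a [featureset] of keys `"ACF<level>:<canonical string>"`.
#' @export
acf_enumerate <- function(mol, level) {
  if (!is.numeric(level) || level < 1)
    stop("ACF level must be a positive integer")
  keys <- acf_keys(mol, levels = as.integer(level))
  featureset(mol$id, keys)
}

# shared worker: one BFS per center serves all requested levels
acf_keys <- function(mol, levels) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  keys <- character(0)
  for (c0 in seq_len(n)) {
    d <- bfs_distances(adj, c0)
    for (lv in levels) {
      members <- which(d <= lv)
      cuts <- vapply(members, function(i)
        sum(!(adj[[i]]$nbr %in% members)), 0L)
      keys <- c(keys, paste0("ACF", lv, ":",
                             fragment_canonical_key(mol, members, center = c0,
                                                    cuts = cuts, adj = adj)))
    }
  }
  keys
}

#' Multilevel atom-center fragments
#'
#' Union (with counts) of [acf_enumerate] at levels `1..max_level`. Keys
#' carry their level, so identical shapes arising at different levels remain
#' distinct features.
#'
#' @param mol a standardized [molgraph].
#' @param max_level maximum fragment radius (1..6).
#' @return a [featureset].
#' @export
acf_multilevel <- function(mol, max_level = 3) {
  stopifnot(max_level >= 1, max_level <= 6)
  featureset(mol$id, acf_keys(mol, levels = seq_len(as.integer(max_level))))
}

#' Featurize a library of records
#'
#' @param records list of `list(mol, activity)` entries.
#' @param method `"acf"` or `"circular"`.
#' @param level ACF maximum level (multilevel union) when `method = "acf"`.
#' @param diameter fingerprint diameter when `method = "circular"`.
#' @return list of [featureset]s, names = compound ids.
#' @export
featurize_library <- function(records, method = c("acf", "circular"),
                              level = 3, diameter = 4) {
  method <- match.arg(method)
  out <- lapply(records, function(r) {
    if (method == "acf") acf_multilevel(r$mol, level)
    else circular_fingerprint(r$mol, diameter)
  })
  names(out) <- vapply(records, function(r) r$mol$id, "")
  out
}

#' Binary feature matrix from feature sets
#'
#' @param fsets list of [featureset]s.
#' @param keys optional fixed key universe (columns); defaults to the sorted
#'   union of all keys present.
#' @return logical matrix compounds x features.
#' @export
feature_matrix <- function(fsets, keys = NULL) {
  if (is.null(keys)) keys <- sort(unique(unlist(lapply(fsets, names))))
  m <- matrix(FALSE, nrow = length(fsets), ncol = length(keys),
              dimnames = list(vapply(fsets, function(f) attr(f, "compound_id"), ""),
                              keys))
  for (i in seq_along(fsets)) {
    hit <- match(names(fsets[[i]]), keys)
    m[i, hit[!is.na(hit)]] <- TRUE
  }
  m
}

#' Serialize feature sets to a tab-delimited table
#'
#' Writes one row per (compound, feature) with columns `compound_id`,
#' `family`, `level`, `canonical_string`, `count`, plus a JSON sidecar
#' (`<path>.json`) echoing the featurization parameters. [read_featuresets]
#' reproduces the exact sets.
#'
#' @param fsets list of [featureset]s.
#' @param path output TSV path.
#' @param params list of featurization parameters for the sidecar.
#' @export
write_featuresets <- function(fsets, path, params = list()) {
  rows <- list()
  for (fs in fsets) {
    if (length(fs) == 0L) next
    parts <- regmatches(names(fs), regexec("^([A-Z]+)([0-9]+):(.*)$", names(fs)))
    rows[[length(rows) + 1L]] <- data.frame(
      compound_id = attr(fs, "compound_id"),
      family = vapply(parts, `[`, "", 2),
      level = vapply(parts, `[`, "", 3),
      canonical_string = vapply(parts, `[`, "", 4),
      count = as.integer(fs),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read feature sets written by [write_featuresets]
#'
#' @param path TSV path.
#' @return list of [featureset]s (names = compound ids).
#' @export
read_featuresets <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  out <- list()
  for (id in unique(tab$compound_id)) {
    sub <- tab[tab$compound_id == id, , drop = FALSE]
    keys <- sprintf("%s%s:%s", sub$family, sub$level, sub$canonical_string)
    fs <- structure(as.integer(sub$count), names = keys,
                    compound_id = id, class = "featureset")
    out[[id]] <- fs
  }
  out
}
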