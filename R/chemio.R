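# Compound I/O, standardization, activity labelling and data splitting.

#' Create an activity record
#'
#' @param compound_id compound identifier.
#' @param assay_type `"Ki"`, `"IC50"`, or `NA`. Ki and IC50 records are pooled
#'   without conversion; the assay type is retained as metadata only.
#' @param value_nM positive assay value in nanomolar, or `NA`.
#' @return list of class `activity_record`.
#' @export
activity_record <- function(compound_id, assay_type = NA_character_,
                            value_nM = NA_real_) {
  if (!is.na(value_nM) && value_nM <= 0)
    stop("assay value must be positive (nM)")
  if (!is.na(assay_type) && !(assay_type %in% c("Ki", "IC50")))
    stop("assay_type must be 'Ki' or 'IC50'")
  structure(list(compound_id = compound_id, assay_type = assay_type,
                 value_nM = value_nM), class = "activity_record")
}

#' Label a compound as inhibitor or non-inhibitor
#'
#' A compound is an inhibitor iff its assay value is strictly below the
#' cutoff; a value exactly equal to the cutoff is a non-inhibitor. The
#' default cutoff is 10 uM (10000 nM); 1 uM and 5 uM are the conventional
#' alternatives for sensitivity analyses.
#'
#' @param record an [activity_record] (or anything with `$value_nM`).
#' @param cutoff_nM positive activity cutoff in nM.
#' @return `"inhibitor"`, `"non_inhibitor"`, or `"unlabeled"` when the value
#'   is missing.
#' @export
label_activity <- function(record, cutoff_nM = 10000) {
  stopifnot(is.numeric(cutoff_nM), cutoff_nM > 0)
  v <- record$value_nM
  if (is.null(v) || is.na(v)) return("unlabeled")
  if (v < cutoff_nM) "inhibitor" else "non_inhibitor"
}

#' Inhibition index of an assay value
#'
#' Returns `-log10(value in mol/L) + 2`, i.e. the molar pKi/pIC50 plus an
#' offset of 2, the potency scale used when correlating descriptors against
#' activity.
#'
#' @param record an [activity_record].
#' @return numeric index.
#' @export
inhibition_index <- function(record) {
  v <- record$value_nM
  if (is.null(v) || is.na(v)) stop("assay value missing")
  if (v <= 0) stop("assay value must be positive")
  -log10(v * 1e-9) + 2
}

#' Standardize a molecular graph
#'
#' Keeps the largest covalent fragment (salt stripping), folds explicit
#' hydrogen atoms into implicit counts, and re-perceives aromaticity.
#' Idempotent.
#'
#' @param mol a [molgraph].
#' @return a standardized [molgraph].
#' @export
standardize <- function(mol) {
  # fold explicit H atoms
  h_idx <- which(mol$atoms$symbol == "H")
  if (length(h_idx) > 0L) {
    keep <- setdiff(seq_len(n_atoms(mol)), h_idx)
    if (length(keep) == 0L) stop("molecule has no heavy atoms")
    for (h in h_idx) {
      k <- which(mol$bonds$a1 == h | mol$bonds$a2 == h)
      for (kk in k) {
        other <- if (mol$bonds$a1[kk] == h) mol$bonds$a2[kk] else mol$bonds$a1[kk]
        if (!(other %in% h_idx))
          mol$atoms$hcount[other] <- mol$atoms$hcount[other] + 1L
      }
    }
    remap <- match(seq_len(n_atoms(mol)), keep)
    bonds <- mol$bonds[!(mol$bonds$a1 %in% h_idx | mol$bonds$a2 %in% h_idx), ,
                       drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    mol <- molgraph(mol$atoms[keep, , drop = FALSE], bonds,
                    id = mol$id, source_smiles = mol$source_smiles)
  }
  # largest covalent fragment
  comp <- graph_components(mol)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    best <- which.max(sizes)  # ties: lowest component id (input order)
    keep <- which(comp == best)
    remap <- match(seq_len(n_atoms(mol)), keep)
    bonds <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, ,
                       drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    mol <- molgraph(mol$atoms[keep, , drop = FALSE], bonds,
                    id = mol$id, source_smiles = mol$source_smiles)
  }
  perceive_aromaticity(mol)
}

#' Read a compound library
#'
#' Reads either a whitespace-delimited SMILES table (columns: SMILES, ID,
#' optional assay type, optional value in nM; `#` starts a comment) or an SDF
#' file (V2000 MOL blocks with activity in property tags). Malformed entries
#' are skipped with a message; their count is attached as an attribute.
#'
#' @param path file path.
#' @param format `"smiles_table"` or `"sdf"`.
#' @param type_tag,value_tag SDF property tags holding the assay type and the
#'   value in nM.
#' @return list of records, each `list(mol = molgraph, activity =
#'   activity_record)`, with attribute `n_skipped`.
#' @export
read_library <- function(path, format = c("smiles_table", "sdf"),
                         type_tag = "ASSAY_TYPE", value_tag = "VALUE_NM") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read library: '%s'", path))
  out <- list()
  skipped <- 0L
  if (format == "smiles_table") {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nchar(lines) > 0L]
    for (ln in lines) {
      fields <- strsplit(ln, "[ \t]+")[[1]]
      rec <- tryCatch({
        mol <- parse_smiles(fields[1], id = if (length(fields) >= 2L) fields[2]
                                            else fields[1])
        atype <- if (length(fields) >= 3L && fields[3] %in% c("Ki", "IC50"))
          fields[3] else NA_character_
        val <- if (length(fields) >= 4L) suppressWarnings(as.numeric(fields[4]))
               else NA_real_
        list(mol = mol, activity = activity_record(mol$id, atype, val))
      }, error = function(e) e)
      if (inherits(rec, "error")) {
        skipped <- skipped + 1L
        message(sprintf("skipping malformed entry '%s': %s",
                        substr(ln, 1, 40), conditionMessage(rec)))
      } else out[[length(out) + 1L]] <- rec
    }
  } else {
    blocks <- read_sdf_blocks(path)
    for (bl in blocks) {
      rec <- tryCatch({
        mol <- parse_molblock(bl$mol, id = bl$id)
        atype <- bl$props[[type_tag]]
        if (is.null(atype) || !(atype %in% c("Ki", "IC50"))) atype <- NA_character_
        val <- bl$props[[value_tag]]
        val <- if (is.null(val)) NA_real_ else suppressWarnings(as.numeric(val))
        list(mol = mol, activity = activity_record(mol$id, atype, val))
      }, error = function(e) e)
      if (inherits(rec, "error")) {
        skipped <- skipped + 1L
        message(sprintf("skipping malformed SDF record '%s': %s",
                        bl$id, conditionMessage(rec)))
      } else out[[length(out) + 1L]] <- rec
    }
  }
  if (length(out) == 0L) stop("no parseable records in library")
  attr(out, "n_skipped") <- skipped
  out
}

# split an SDF file into records: list(id, mol = molblock lines, props)
read_sdf_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L) ends <- length(lines) + 1L
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- list()
  for (t in seq_along(starts)) {
    seg <- lines[starts[t]:(min(ends[t], length(lines) + 1L) - 1L)]
    if (all(trimws(seg) == "")) next
    mend <- which(trimws(seg) == "M  END")
    if (length(mend) == 0L) mend <- length(seg)
    props <- list()
    rest <- if (mend[1] < length(seg)) seg[(mend[1] + 1L):length(seg)] else character(0)
    tag_lines <- grep("^>", rest)
    for (ti in seq_along(tag_lines)) {
      tag <- sub("^>\\s*<([^>]*)>.*$", "\\1", rest[tag_lines[ti]])
      to <- if (ti < length(tag_lines)) tag_lines[ti + 1L] - 1L else length(rest)
      val <- trimws(rest[(tag_lines[ti] + 1L):to])
      val <- val[nchar(val) > 0L]
      props[[tag]] <- if (length(val) > 0L) val[1] else ""
    }
    id <- trimws(seg[1])
    if (nchar(id) == 0L) id <- sprintf("MOL%04d", t)
    blocks[[length(blocks) + 1L]] <-
      list(id = id, mol = seg[seq_len(mend[1])], props = props)
  }
  blocks
}

# minimal V2000 molblock reader (counts line, atom block, bond block)
parse_molblock <- function(lines, id = NA_character_) {
  if (length(lines) < 4L) stop("molblock too short")
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("malformed counts line")
  if (na < 1L) stop("molblock has no atoms")
  atoms <- data.frame(symbol = character(na), charge = integer(na),
                      aromatic = logical(na), hcount = integer(na),
                      stringsAsFactors = FALSE)
  for (i in seq_len(na)) {
    ln <- lines[4L + i]
    sym <- trimws(substr(ln, 32, 34))
    if (nchar(sym) == 0L) stop(sprintf("missing element symbol at atom %d", i))
    atoms$symbol[i] <- sym
    chg_code <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    # old-style charge column: 1..7 -> +3..-3 (4 = unused)
    atoms$charge[i] <- if (!is.na(chg_code) && chg_code %in% c(1:3, 5:7))
      (4L - chg_code) else 0L
  }
  bonds <- data.frame(a1 = integer(nb), a2 = integer(nb), order = numeric(nb))
  for (k in seq_len(nb)) {
    ln <- lines[4L + na + k]
    bonds$a1[k] <- as.integer(substr(ln, 1, 3))
    bonds$a2[k] <- as.integer(substr(ln, 4, 6))
    o <- as.integer(substr(ln, 7, 9))
    bonds$order[k] <- if (o == 4L) 1.5 else as.numeric(o)
  }
  # M  CHG lines override
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    nset <- toks[1]
    for (t in seq_len(nset)) atoms$charge[toks[2 * t]] <- toks[2 * t + 1L]
  }
  atoms$aromatic <- FALSE
  mol <- molgraph(atoms, bonds, id = id)
  # mark aromatic flags from order-4 bonds, then perceive Kekule rings
  arom_atoms <- unique(c(bonds$a1[bonds$order == 1.5], bonds$a2[bonds$order == 1.5]))
  mol$atoms$aromatic[arom_atoms] <- TRUE
  mol <- assign_implicit_h(mol)
  perceive_aromaticity(mol)
}

#' Collapse duplicate structures
#'
#' Records whose standardized graphs are isomorphic are collapsed to a single
#' record keeping the lowest assay value (the most potent evidence).
#'
#' @param records list of `list(mol, activity)` entries (standardized).
#' @return deduplicated list of records.
#' @export
dedupe_library <- function(records) {
  keys <- vapply(records, function(r) molecule_key(r$mol), "")
  keep <- integer(0)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    if (length(idx) == 1L) { keep <- c(keep, idx); next }
    vals <- vapply(idx, function(i) {
      v <- records[[i]]$activity$value_nM
      if (is.null(v) || is.na(v)) Inf else v
    }, 0)
    keep <- c(keep, idx[which.min(vals)])
  }
  records[sort(keep)]
}

#' Random train/test split
#'
#' Uniformly random assignment of compound ids to a test set of size
#' `round(n * test_fraction)`; the remainder is the training set.
#' Deterministic given the seed. A stratified option balances the class
#' fraction across the two parts.
#'
#' @param ids character vector of compound ids (unique).
#' @param test_fraction fraction in (0,1) assigned to the test set.
#' @param seed integer seed.
#' @param stratify optional character/factor vector of class labels parallel
#'   to `ids`; when supplied, sampling is stratified per class.
#' @return list with `training_ids`, `test_ids`, `seed`.
#' @export
split_train_test <- function(ids, test_fraction, seed, stratify = NULL) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0,1)")
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  if (length(ids) < 2L) stop("need at least 2 records to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (is.null(stratify)) {
    n_test <- round(length(ids) * test_fraction)
    test <- sample(ids, n_test)
  } else {
    stopifnot(length(stratify) == length(ids))
    test <- character(0)
    for (cl in sort(unique(as.character(stratify)))) {
      sub <- ids[stratify == cl]
      test <- c(test, sample(sub, round(length(sub) * test_fraction)))
    }
  }
  list(training_ids = setdiff(ids, test), test_ids = test,
       seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
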