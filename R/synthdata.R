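# Synthetic compound libraries with planted class-defining substructures.
#
# The generator assembles valence-respecting molecules by concatenating
# curated SMILES pieces via single bonds (every piece starts and ends on an
# atom with spare valence). Class membership is driven by planted
# substructures: with probability equal to the configured fidelity a
# compound carries its own class's planted piece (otherwise none), so
# fragment/class association is controlled exactly by the fidelity.
# Assay values are sampled log-uniformly on the correct side of the
# activity cutoff and carry no information beyond the class.

.DEFAULT_VOCAB <- c(
  "c1ccccc1", "c1ccc(F)cc1", "c1ccncc1", "C1CCCCC1", "CC", "CCC",
  "CC(C)C", "COC", "CCOC", "CS", "c1ccc(Cl)cc1", "CCCC"
)

# planted pieces: nitrogen in a saturated ring for actives (strong H-bond
# acceptor motif) vs an N-acyl lactam-type motif for non-actives. Both are
# interior-safe: concatenation only touches their first/last written atom,
# so the key fragment environments are identical wherever the piece occurs.
# With probability fidelity a compound carries its own class's piece,
# otherwise no planted piece at all, so each planted fragment occurs only
# in its own class and its class association equals the fidelity.
.DEFAULT_ACTIVE_FRAGMENT <- "C1CCNCC1"
.DEFAULT_INACTIVE_FRAGMENT <- "N1C(=O)C=CC=C1"

#' Configuration for the synthetic-library generator
#'
#' Defaults emulate the composition of a realistic kinase-inhibitor
#' classification set: ~80% actives, molecular weight roughly 140-700
#' g/mol, activity cutoff 10 uM.
#'
#' @param n_compounds library size.
#' @param active_fraction expected fraction of actives.
#' @param fidelity probability (> 0.5) that a compound carries its own
#'   class's planted fragment rather than the opposite one.
#' @param active_fragment,inactive_fragment planted SMILES pieces.
#' @param vocabulary scaffold SMILES pieces used for assembly.
#' @param cutoff_nM activity cutoff separating the classes' assay values.
#' @param mw_range target molecular-weight band (g/mol).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 500, active_fraction = 0.80,
                             fidelity = 0.9,
                             active_fragment = .DEFAULT_ACTIVE_FRAGMENT,
                             inactive_fragment = .DEFAULT_INACTIVE_FRAGMENT,
                             vocabulary = .DEFAULT_VOCAB,
                             cutoff_nM = 10000, mw_range = c(140, 700),
                             seed = 1) {
  if (fidelity <= 0.5 || fidelity > 1)
    stop("fidelity must lie in (0.5, 1]")
  if (length(vocabulary) == 0L) stop("vocabulary must be non-empty")
  for (s in c(vocabulary, active_fragment, inactive_fragment)) {
    ok <- tryCatch({ parse_smiles(s); TRUE }, error = function(e) FALSE)
    if (!ok) stop(sprintf("invalid vocabulary SMILES: '%s'", s))
  }
  structure(list(n_compounds = n_compounds, active_fraction = active_fraction,
                 fidelity = fidelity, active_fragment = active_fragment,
                 inactive_fragment = inactive_fragment,
                 vocabulary = vocabulary, cutoff_nM = cutoff_nM,
                 mw_range = mw_range, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a labeled synthetic compound library
#'
#' @param cfg a [generator_config].
#' @return data.frame with columns `smiles`, `id`, `assay_type`, `value_nM`,
#'   `label`.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n <- cfg$n_compounds
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    active <- stats::runif(1) < cfg$active_fraction
    planted <- if (stats::runif(1) < cfg$fidelity) {
      if (active) cfg$active_fragment else cfg$inactive_fragment
    } else NA_character_
    smiles <- NA_character_
    for (attempt in 1:50) {
      k <- sample(2:4, 1)
      pieces <- sample(cfg$vocabulary, k, replace = TRUE)
      if (!is.na(planted)) {
        pos <- sample(k + 1L, 1)
        pieces <- append(pieces, planted, after = pos - 1L)
      }
      cand <- paste(pieces, collapse = "")
      mw <- tryCatch(molecular_weight(parse_smiles(cand)),
                     error = function(e) NA_real_)
      if (!is.na(mw) && mw >= cfg$mw_range[1] && mw <= cfg$mw_range[2]) {
        smiles <- cand
        break
      }
    }
    if (is.na(smiles)) stop("could not assemble a molecule in the MW band")
    value <- if (active) {
      10^stats::runif(1, 0, log10(cfg$cutoff_nM * 0.999))
    } else {
      10^stats::runif(1, log10(cfg$cutoff_nM), 7)
    }
    rows[[i]] <- data.frame(
      smiles = smiles, id = sprintf("SYN%05d", i),
      assay_type = sample(c("Ki", "IC50"), 1),
      value_nM = value,
      label = if (active) "inhibitor" else "non_inhibitor",
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Write a generated library in the SMILES-table dialect
#'
#' @param lib data.frame from [generate_library].
#' @param path output path.
#' @export
write_library_table <- function(lib, path) {
  lines <- sprintf("%s\t%s\t%s\t%.6g", lib$smiles, lib$id, lib$assay_type,
                   lib$value_nM)
  writeLines(c("# SMILES\tID\tTYPE\tVALUE_NM", lines), path)
  invisible(path)
}

#' ACF key of a planted fragment's distinguished center
#'
#' Computes the level-`level` ACF keys of the isolated fragment and returns
#' those whose center is the given element. For the default planted pieces
#' the level-1 nitrogen-centered key is embedding-invariant (assembly never
#' bonds to the atoms within one bond of the nitrogen), so it identifies
#' the planted fragment inside any generated library.
#'
#' @param fragment_smiles the planted piece.
#' @param level ACF level.
#' @param element center element symbol.
#' @return character vector of keys.
#' @export
planted_fragment_keys <- function(fragment_smiles, level = 1,
                                  element = "N") {
  mol <- standardize(parse_smiles(fragment_smiles, id = "fragment"))
  adj <- adjacency(mol)
  centers <- which(mol$atoms$symbol == element)
  keys <- character(0)
  for (c0 in centers) {
    d <- bfs_distances(adj, c0)
    members <- which(d <= level)
    cuts <- vapply(members, function(i) sum(!(adj[[i]]$nbr %in% members)), 0L)
    keys <- c(keys, paste0("ACF", level, ":",
                           fragment_canonical_key(mol, members, center = c0,
                                                  cuts = cuts, adj = adj)))
  }
  unique(keys)
}

#' Published benchmark confusion rows
#'
#' The 26 training/test confusion rows (with their printed metric values)
#' of a published mTOR inhibitor/non-inhibitor benchmark: 13 recursive-
#' partitioning and 13 Bayesian models over descriptor/fingerprint
#' combinations. Used as regression fixtures for the metric engine.
#'
#' @return data.frame with columns `method`, `descriptors`, `split`, `TP`,
#'   `FN`, `TN`, `FP`, `SE`, `SP`, `Q_i`, `Q_ni`, `C`, `AUC`.
#' @export
benchmark_confusion_rows <- function() {
  path <- system.file("extdata", "benchmark_confusion.tsv", package = "acfnb")
  if (path == "") stop("benchmark_confusion.tsv not found")
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
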