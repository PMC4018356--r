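test_that("count descriptors match manual rule application", {
  m <- compute_descriptors(standardize(parse_smiles("C")))
  expect_equal(m[["MW"]], 16.043, tolerance = 1e-3)
  expect_equal(unname(m[c("nHBDon", "nHBAcc", "nRing", "N_plus_O")]),
               c(0, 0, 0, 0))

  b <- compute_descriptors(parse_smiles("c1ccccc1"))
  expect_equal(unname(b[c("nAR", "nRing", "N_rot")]), c(1, 1, 0))

  e <- compute_descriptors(parse_smiles("CCO"))
  expect_equal(unname(e[c("nHBDon", "nHBAcc", "N_plus_O", "N_rot")]),
               c(1, 1, 1, 0))

  # ibuprofen: 1 aromatic ring, 4 rotatable bonds by the simple rule
  ibu <- compute_descriptors(standardize(parse_smiles("CC(C)Cc1ccc(cc1)C(C)C(=O)O")))
  expect_equal(ibu[["nAR"]], 1)
  expect_equal(ibu[["MW"]], 206.28, tolerance = 0.01)
  expect_equal(ibu[["N_rot"]], 4)

  # acceptor exclusions: amide N and pyrrole-type NH are not acceptors
  para <- compute_descriptors(standardize(parse_smiles("CC(=O)Nc1ccc(O)cc1")))
  expect_equal(para[["nHBAcc"]], 2)  # carbonyl O + phenol O, not the amide N
  pyr <- compute_descriptors(parse_smiles("c1cc[nH]c1"))
  expect_equal(pyr[["nHBAcc"]], 0)
  pyd <- compute_descriptors(parse_smiles("c1ccncc1"))
  expect_equal(pyd[["nHBAcc"]], 1)
})

test_that("MFPSA is the MPSA/MSA ratio and provider failures degrade to NA", {
  d <- compute_descriptors(standardize(parse_smiles("CC(=O)O")))
  expect_equal(d[["MFPSA"]], d[["MPSA"]] / d[["MSA"]])
  expect_true(d[["MPSA"]] > 0)

  boom <- function(mol, counts) stop("backend offline")
  expect_warning(d2 <- compute_descriptors(parse_smiles("CCO"), provider = boom),
                 "provider failed")
  expect_true(all(is.na(d2[c("AlogP", "logD", "logS", "MPSA", "MFPSA", "MSA")])))
  expect_equal(d2[["nHBDon"]], 1)  # counts survive
})

test_that("circular fingerprints match the symmetry oracles", {
  m <- circular_fingerprint(parse_smiles("C", id = "m"), 4)
  expect_length(m, 1L)

  # benzene: all atoms equivalent, so exactly one identifier per round,
  # each covering all six atom-environments
  b <- circular_fingerprint(parse_smiles("c1ccccc1", id = "b"), 4)
  expect_length(b, 3L)       # round 0, 1, 2
  expect_true(all(b == 6L))

  d6 <- circular_fingerprint(parse_smiles("c1ccccc1", id = "b"), 6)
  expect_length(d6, 4L)
})

test_that("circular fingerprints are invariant under atom permutation", {
  set.seed(11)
  for (s in fixture_smiles_20[1:8]) {
    mol <- parse_smiles(s, id = s)
    ref <- sort(names(circular_fingerprint(mol, 4)))
    for (r in 1:5) {
      mp <- permute_mol(mol, sample(n_atoms(mol)))
      expect_identical(sort(names(circular_fingerprint(mp, 4))), ref,
                       label = sprintf("CIRC4 invariance '%s'", s))
    }
  }
})

test_that("ACF enumeration matches exhaustive manual enumeration", {
  m <- acf_enumerate(parse_smiles("C", id = "m"), 1)
  expect_length(m, 1L)
  expect_equal(sum(m), 1L)

  e <- acf_enumerate(parse_smiles("CCO", id = "e"), 1)
  expect_length(e, 3L)        # three distinct keys
  expect_equal(sum(e), 3L)    # one fragment per heavy atom

  b <- acf_enumerate(parse_smiles("c1ccccc1", id = "b"), 1)
  expect_length(b, 1L)
  expect_equal(unname(as.integer(b)), 6L)

  expect_error(acf_enumerate(parse_smiles("C"), 0), "positive")
})

test_that("multilevel ACFs keep levels distinct and conserve counts", {
  m <- acf_multilevel(parse_smiles("C", id = "m"), 3)
  expect_length(m, 3L)  # one feature per level for a lone atom

  mol <- parse_smiles("CC(=O)Nc1ccc(O)cc1", id = "x")
  for (lv in 1:3) {
    fs <- acf_enumerate(mol, lv)
    expect_equal(sum(fs), n_atoms(mol),
                 label = sprintf("count conservation at level %d", lv))
  }
  ml <- acf_multilevel(mol, 3)
  expect_equal(sum(ml), 3L * n_atoms(mol))

  # level-2 ACFs of ethanol reach the whole molecule from every center
  e2 <- acf_enumerate(parse_smiles("CCO", id = "e"), 2)
  esat <- acf_enumerate(parse_smiles("CCO", id = "e"), 6)
  strip <- function(k) sub("^ACF[0-9]+:", "", names(k))
  expect_setequal(strip(e2), strip(esat))
})

test_that("ACF nesting and saturation hold across the fixture set", {
  for (s in fixture_smiles_20) {
    mol <- parse_smiles(s, id = s)
    adj <- acfnb:::adjacency(mol)
    for (c0 in seq_len(min(n_atoms(mol), 4L))) {
      d <- acfnb:::bfs_distances(adj, c0)
      for (lv in 1:3) {
        expect_true(all(which(d <= lv) %in% which(d <= lv + 1)))
      }
    }
    # saturation: once the level reaches the graph diameter, every fragment
    # is the whole molecule rooted at its center, so raising the level
    # further changes nothing but the level tag
    diam <- max(vapply(seq_len(n_atoms(mol)), function(i) {
      di <- acfnb:::bfs_distances(adj, i); max(di[is.finite(di)])
    }, 0))
    strip <- function(fs) sort(sub("^ACF[0-9]+:", "", names(fs)))
    expect_identical(strip(acf_enumerate(mol, diam + 1)),
                     strip(acf_enumerate(mol, diam + 2)),
                     label = sprintf("saturation '%s'", s))
  }
})

test_that("ACF keys are invariant under atom permutation", {
  set.seed(12)
  for (s in fixture_smiles_20[c(8, 14, 15, 17)]) {
    mol <- parse_smiles(s, id = s)
    ref <- sort(names(acf_multilevel(mol, 2)))
    for (r in 1:5) {
      mp <- permute_mol(mol, sample(n_atoms(mol)))
      expect_identical(sort(names(acf_multilevel(mp, 2))), ref,
                       label = sprintf("ACF invariance '%s'", s))
    }
  }
})

test_that("featureset serialization round trips exactly", {
  mols <- lapply(c("CCO", "c1ccncc1", "CC(=O)N"), function(s)
    list(mol = parse_smiles(s, id = s), activity = NULL))
  fsets <- featurize_library(mols, method = "acf", level = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_featuresets(fsets, path, params = list(method = "acf", level = 2))
  back <- read_featuresets(path)
  expect_setequal(names(back), names(fsets))
  for (id in names(fsets)) {
    expect_identical(sort(names(back[[id]])), sort(names(fsets[[id]])))
    expect_identical(back[[id]][sort(names(back[[id]]))],
                     fsets[[id]][sort(names(fsets[[id]]))])
  }
  expect_true(file.exists(paste0(path, ".json")))
})
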