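test_that("parse_smiles builds the expected graphs", {
  m <- parse_smiles("C")
  expect_equal(n_atoms(m), 1L)
  expect_equal(nrow(m$bonds), 0L)
  expect_equal(m$atoms$hcount, 4L)

  b <- parse_smiles("c1ccccc1")
  expect_equal(n_atoms(b), 6L)
  expect_true(all(b$atoms$aromatic))
  expect_equal(sum(b$bonds$order == 1.5), 6L)

  e <- parse_smiles("CCO")
  expect_equal(n_atoms(e), 3L)
  expect_equal(nrow(e$bonds), 2L)
  expect_true(all(e$bonds$order == 1))
  expect_equal(e$atoms$hcount, c(3L, 2L, 1L))
})

test_that("malformed SMILES report the offending position", {
  expect_error(parse_smiles("CC)O"), "position 3")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("C[Qz]C"), "position")
})

test_that("parse -> write -> parse round trips are isomorphic", {
  for (s in fixture_smiles_50) {
    m1 <- parse_smiles(s)
    m2 <- parse_smiles(write_smiles(m1))
    expect_true(is_isomorphic(m1, m2), label = sprintf("round trip '%s'", s))
  }
})

test_that("standardize strips salts, folds hydrogens and is idempotent", {
  m <- standardize(parse_smiles("CCO.[Na+]"))
  expect_equal(n_atoms(m), 3L)
  expect_equal(sort(m$atoms$symbol), c("C", "C", "O"))

  # H-folding oracle: methanol written with explicit hydrogens
  m2 <- standardize(parse_smiles("[H]OC([H])([H])[H]"))
  expect_equal(n_atoms(m2), 2L)
  expect_equal(m2$atoms$hcount[m2$atoms$symbol == "O"], 1L)
  expect_equal(m2$atoms$hcount[m2$atoms$symbol == "C"], 3L)
  expect_true(is_isomorphic(m2, parse_smiles("CO")))

  m3 <- parse_smiles("CC(=O)Nc1ccc(O)cc1")
  expect_true(is_isomorphic(standardize(m3), standardize(standardize(m3))))
})

test_that("label_activity applies a strict below-cutoff rule", {
  expect_equal(label_activity(activity_record("a", "Ki", 9999), 10000),
               "inhibitor")
  expect_equal(label_activity(activity_record("a", "Ki", 10000), 10000),
               "non_inhibitor")
  expect_equal(label_activity(activity_record("a", "IC50", 0.08), 10000),
               "inhibitor")
  expect_equal(label_activity(activity_record("a"), 10000), "unlabeled")
})

test_that("label_activity is monotone in the cutoff", {
  set.seed(42)
  vals <- 10^runif(200, -1, 7)
  cuts <- sort(10^runif(5, 2, 5))
  for (v in vals) {
    labs <- vapply(cuts, function(ct)
      label_activity(activity_record("x", "Ki", v), ct), "")
    # once inhibitor at some cutoff, inhibitor at every larger cutoff
    inh <- labs == "inhibitor"
    expect_true(all(diff(inh) >= 0))
  }
})

test_that("inhibition_index follows the molar pXC50 + 2 convention", {
  expect_equal(inhibition_index(activity_record("a", "Ki", 1000)), 8.0)
  expect_equal(inhibition_index(activity_record("a", "Ki", 1e9)), 2.0)
  expect_equal(inhibition_index(activity_record("a", "Ki", 1)), 11.0)
  expect_error(activity_record("a", "Ki", -5), "positive")
  expect_error(inhibition_index(activity_record("a")), "missing")
})

test_that("split_train_test partitions deterministically", {
  ids <- sprintf("c%04d", 1:1264)
  sp <- split_train_test(ids, 300 / 1264, seed = 5)
  expect_equal(length(sp$test_ids), 300L)
  expect_equal(length(sp$training_ids), 964L)
  expect_length(intersect(sp$training_ids, sp$test_ids), 0)
  expect_setequal(c(sp$training_ids, sp$test_ids), ids)
  sp2 <- split_train_test(ids, 300 / 1264, seed = 5)
  expect_identical(sp, sp2)
  expect_error(split_train_test(ids, 1.2, seed = 1), "\\(0,1\\)")
})

test_that("empirical test fraction is calibrated over many seeds", {
  ids <- sprintf("c%03d", 1:200)
  fracs <- vapply(1:100, function(s)
    length(split_train_test(ids, 0.25, seed = s)$test_ids) / 200, 0)
  expect_lt(abs(mean(fracs) - 0.25), 0.01)
})

test_that("stratified splitting balances classes", {
  ids <- sprintf("c%03d", 1:200)
  cls <- rep(c("inhibitor", "non_inhibitor"), c(160, 40))
  sp <- split_train_test(ids, 0.25, seed = 3, stratify = cls)
  test_cls <- cls[match(sp$test_ids, ids)]
  expect_equal(sum(test_cls == "non_inhibitor"), 10L)
})

test_that("read_library parses SMILES tables and skips malformed rows", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c(
    "# SMILES ID TYPE VALUE_NM",
    "CCO eth IC50 250",
    "c1ccccc1 benz Ki 55000",
    "CC(C)C iso"
  ), path)
  recs <- read_library(path)
  expect_length(recs, 3L)
  expect_equal(attr(recs, "n_skipped"), 0L)
  expect_equal(recs[[1]]$activity$value_nM, 250)
  expect_equal(recs[[1]]$activity$assay_type, "IC50")
  expect_true(is.na(recs[[3]]$activity$value_nM))

  writeLines(c("CCO a IC50 10", "C1CC b", "CC c", "CC)( d", "CCN e"), path)
  expect_message(recs2 <- read_library(path), "skipping")
  expect_length(recs2, 3L)
  expect_equal(attr(recs2, "n_skipped"), 2L)

  writeLines("not_smiles_at_all&&", path)
  expect_error(suppressMessages(read_library(path)), "no parseable")
  expect_error(read_library(file.path(tempdir(), "nope.smi")), "cannot read")
})

test_that("read_library reads SDF records with activity tags", {
  path <- withr::local_tempfile(fileext = ".sdf")
  write_test_sdf(path, list(
    list(id = "eth", atoms = data.frame(symbol = c("C", "C", "O")),
         bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = c(1, 1)),
         props = list(ASSAY_TYPE = "IC50", VALUE_NM = "250")),
    list(id = "benzene",
         atoms = data.frame(symbol = rep("C", 6)),
         bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1),
                            order = c(2, 1, 2, 1, 2, 1)),
         props = list(ASSAY_TYPE = "Ki", VALUE_NM = "55000"))
  ))
  recs <- read_library(path, format = "sdf")
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$activity$value_nM, 250)
  expect_true(is_isomorphic(recs[[1]]$mol, parse_smiles("CCO")))
  # Kekule benzene from the molblock is perceived aromatic
  expect_true(all(recs[[2]]$mol$atoms$aromatic))
})

test_that("dedupe_library keeps the most potent duplicate", {
  recs <- list(
    list(mol = standardize(parse_smiles("CCO", id = "a")),
         activity = activity_record("a", "Ki", 500)),
    list(mol = standardize(parse_smiles("OCC", id = "b")),
         activity = activity_record("b", "IC50", 100)),
    list(mol = standardize(parse_smiles("CCN", id = "c")),
         activity = activity_record("c", "Ki", 50))
  )
  out <- dedupe_library(recs)
  expect_length(out, 2L)
  kept <- vapply(out, function(r) r$activity$compound_id, "")
  expect_true("b" %in% kept)  # lower value wins
  expect_false("a" %in% kept)
})
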