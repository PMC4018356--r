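# Shared fixtures and helpers for the test suite. Everything is built in
# code; no binary fixtures.

# 50 diverse, dialect-valid SMILES for round-trip testing
fixture_smiles_50 <- c(
  "C", "CC", "CCC", "CCO", "CCN", "CC(C)C", "CC(C)(C)C", "C=C", "C#N",
  "CC=O", "CC(=O)O", "CC(=O)N", "CCOC", "CCOCC", "CS", "CSC", "CCl",
  "C(F)(F)F", "ClC(Cl)(Cl)Cl", "OCC(O)CO",
  "c1ccccc1", "c1ccncc1", "c1ccc(O)cc1", "c1ccc(N)cc1", "c1ccc(F)cc1",
  "c1ccc(Cl)cc1", "Cc1ccccc1", "CCc1ccccn1", "c1ccc2ccccc2c1",
  "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "c1cnc[nH]1",
  "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "C1CCCC1", "C1CC1",
  "O=C1C=CC=CN1", "N1C(=O)C=CC=C1", "CC(=O)Nc1ccc(O)cc1",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "O=S(=O)(N)c1ccccc1",
  "N#Cc1ccccc1", "CN1CCCC1", "[Na+].CC([O-])=O", "C[N+](C)(C)C",
  "CC(=O)OC1CCCCC1", "c1ccc(-c2ccccc2)cc1", "COc1cc2ccccc2cc1"
)

# 20 compact molecules for canonicality sweeps (kept small so that 100
# atom permutations stay fast)
fixture_smiles_20 <- c(
  "CCO", "CC(C)C", "CC=O", "CC(=O)O", "CCOC", "CS", "C(F)(F)F",
  "c1ccccc1", "c1ccncc1", "c1ccc(O)cc1", "Cc1ccccc1", "c1cc[nH]c1",
  "c1ccoc1", "C1CCCCC1", "C1CCNCC1", "C1CC1", "O=C1C=CC=CN1",
  "CN1CCCC1", "N#Cc1ccccc1", "CC(=O)N"
)

# apply an atom permutation p to a molgraph (new index of old atom i is
# which(p == i))
permute_mol <- function(mol, p) {
  mol$atoms <- mol$atoms[p, , drop = FALSE]
  q <- order(p)
  mol$bonds$a1 <- q[mol$bonds$a1]
  mol$bonds$a2 <- q[mol$bonds$a2]
  mol
}

# records + labels from a generated library data.frame
records_from_library <- function(lib) {
  records <- lapply(seq_len(nrow(lib)), function(i) {
    mol <- standardize(parse_smiles(lib$smiles[i], id = lib$id[i]))
    list(mol = mol,
         activity = activity_record(lib$id[i], lib$assay_type[i],
                                    lib$value_nM[i]))
  })
  names(records) <- lib$id
  records
}

# tiny deterministic featureset builder for classifier unit tests
fs_of <- function(id, keys) featureset(id, keys)

# attach a kinds attribute to a subset model matrix
with_kinds <- function(m, kinds) `attr<-`(m, "kinds", kinds)

# minimal V2000 SDF writer for I/O tests
write_test_sdf <- function(path, entries) {
  lines <- character(0)
  for (e in entries) {
    na <- nrow(e$atoms); nb <- nrow(e$bonds)
    lines <- c(lines, e$id, "  acfnb-test", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
    for (i in seq_len(na)) {
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0", 0, 0, 0,
                                e$atoms$symbol[i]))
    }
    for (k in seq_len(nb)) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", e$bonds$a1[k], e$bonds$a2[k],
                                e$bonds$order[k]))
    }
    lines <- c(lines, "M  END")
    for (tag in names(e$props)) {
      lines <- c(lines, sprintf(">  <%s>", tag), e$props[[tag]], "")
    }
    lines <- c(lines, "$$$$")
  }
  writeLines(lines, path)
  path
}
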