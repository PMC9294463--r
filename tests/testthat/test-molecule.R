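test_that("ethane parses to two bonded heavy atoms", {
  mol <- mol_from_smiles("CC", id = "ethane")
  hv <- which(mol$atoms$element != "H")
  expect_length(hv, 2L)
  d <- mol_distances(mol)
  expect_equal(unname(d[1, 2]), 1)
  expect_equal(sum(mol$atoms$element == "H"), 6L)
})

test_that("the thiazolidine-2,4-dione core is a five-membered ring with 7 heavy atoms", {
  mol <- mol_from_smiles("O=C1NC(=O)CS1", id = "tzd")
  hv <- which(mol$atoms$element != "H")
  expect_length(hv, 7L)
  heavy_bonds <- mol$bonds[mol$atoms$element[mol$bonds$i] != "H" &
                           mol$atoms$element[mol$bonds$j] != "H", ]
  # 7 heavy atoms, 7 heavy bonds -> exactly one cycle; its length is 5
  expect_equal(nrow(heavy_bonds), 7L)
  ring_atoms <- setdiff(hv, which(mol$atoms$element == "O"))
  expect_length(ring_atoms, 5L)
})

test_that("benzene has degree 2 everywhere in the hydrogen-suppressed graph", {
  mol <- mol_from_smiles("c1ccccc1", id = "benzene")
  d <- mol_distances(mol)
  expect_equal(unname(rowSums(d == 1)), rep(2, 6))
})

test_that("topological distances are a metric", {
  for (smi in c("c1ccccc1", "COc1cc(/C=C2\\SC(=O)NC2=O)cc(OC)c1OC")) {
    d <- mol_distances(mol_from_smiles(smi))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    n <- nrow(d)
    for (k in seq_len(n)) {
      expect_true(all(d <= outer(d[, k], d[k, ], "+") + 1e-12))
    }
    # agreement with an independent BFS
    mol <- mol_from_smiles(smi)
    hv <- which(mol$atoms$element != "H")
    hmap <- match(seq_len(nrow(mol$atoms)), hv)
    eb <- as.matrix(mol$bonds[, c("i", "j")])
    he <- eb[!is.na(hmap[eb[, 1]]) & !is.na(hmap[eb[, 2]]), , drop = FALSE]
    oracle <- bfs_distances(length(hv), cbind(hmap[he[, 1]], hmap[he[, 2]]))
    expect_equal(unname(d), oracle)
  }
})

test_that("multi-fragment and invalid inputs are rejected", {
  expect_error(mol_from_smiles("CC.CC"), "fragment")
  expect_error(mol_from_smiles("C1CC"), "parse")
})

test_that("SMILES files and SDF round trips preserve the molecule", {
  tf <- tempfile(fileext = ".smi")
  writeLines(c("CC eth", "CCO etha"), tf)
  mols <- read_smiles_file(tf)
  expect_length(mols, 2L)
  expect_equal(mols[[2]]$id, "etha")

  emb <- embedded_phenol()
  sdf <- tempfile(fileext = ".sdf")
  write_sdf(emb, sdf)
  back <- read_sdf_mols(sdf)[[1]]
  expect_equal(back$atoms$element, emb$atoms$element)
  expect_equal(back$atoms$x, emb$atoms$x, tolerance = 1e-3)
  expect_equal(as.matrix(back$bonds), as.matrix(emb$bonds))
})
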