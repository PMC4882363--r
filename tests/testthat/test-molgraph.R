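test_that("benzene parses to the aromatic 6-cycle with the expected descriptors", {
  g <- parse_smiles("c1ccccc1", "benzene")
  expect_equal(n_atoms(g), 6L)
  expect_equal(nrow(g$bonds), 6L)
  expect_true(all(g$elements == "C"))
  expect_true(all(g$aromatic))
  expect_equal(g$heavy_neighbors, rep(2L, 6))
  expect_equal(g$pi_electrons, rep(1L, 6))
})

test_that("ethane and methane parse to the trivial graphs", {
  e <- parse_smiles("CC", "ethane")
  expect_equal(n_atoms(e), 2L)
  expect_equal(nrow(e$bonds), 1L)
  expect_equal(e$heavy_neighbors, c(1L, 1L))
  expect_equal(e$pi_electrons, c(0L, 0L))
  m <- parse_smiles("C", "methane")
  expect_equal(n_atoms(m), 1L)
  expect_equal(nrow(m$bonds), 0L)
  expect_equal(m$heavy_neighbors, 0L)
})

test_that("topological distances are shortest-path bond counts", {
  g <- parse_smiles("c1ccccc1")
  d <- topological_distances(g)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0L, 6))
  expect_equal(d[1, 2], 1L)   # bonded pair
  expect_equal(d[1, 4], 3L)   # para carbons
  expect_equal(max(d), 3L)
  e <- topological_distances(parse_smiles("CC"))
  expect_equal(e[1, 2], 1L)
})

test_that("distance tables are symmetric and satisfy the triangle inequality", {
  for (smi in TEST_SMILES) {
    g <- parse_smiles(smi)
    d <- topological_distances(g)
    expect_true(isSymmetric(d))
    n <- nrow(d)
    if (n >= 3) {
      for (k in seq_len(n)) {
        expect_true(all(d <= outer(d[, k], d[k, ], `+`)))
      }
    }
  }
})

test_that("heavy-neighbour counts equal graph degree for every parsed molecule", {
  for (smi in TEST_SMILES) {
    g <- parse_smiles(smi)
    deg <- tabulate(c(g$bonds$a, g$bonds$b), nbins = n_atoms(g))
    expect_equal(g$heavy_neighbors, as.integer(deg))
  }
})

test_that("parsing is deterministic", {
  for (smi in TEST_SMILES[1:6]) {
    expect_identical(parse_smiles(smi, "x"), parse_smiles(smi, "x"))
  }
})

test_that("hydrogens are excluded and never counted as neighbours", {
  g <- parse_smiles("[H]C([H])([H])C([H])([H])[H]", "ethane_explicit")
  expect_equal(n_atoms(g), 2L)
  expect_equal(g$heavy_neighbors, c(1L, 1L))
  expect_identical(atom_pairs(g)$features, atom_pairs(parse_smiles("CC"))$features)
})

test_that("disconnected structures keep the largest heavy-atom fragment", {
  g <- parse_smiles("CC(=O)[O-].[Na+]", "acetate")
  expect_equal(n_atoms(g), 4L)
  expect_true(all(g$elements %in% c("C", "O")))
  # tie in fragment size: first fragment wins
  t2 <- parse_smiles("CC.OO", "tie")
  expect_equal(t2$elements, c("C", "C"))
})

test_that("nitro groups fingerprint identically however they are drawn", {
  a <- parse_smiles("O=[N+]([O-])c1ccccc1", "cs")
  b <- parse_smiles("O=N(=O)c1ccccc1", "neutral")
  expect_identical(atom_pairs(a)$features, atom_pairs(b)$features)
  # exactly one nitro oxygen carries the pi electron
  ox <- which(a$elements == "O")
  expect_setequal(a$pi_electrons[ox], c(1L, 0L))
})

test_that("kekulized aromatic rings are perceived as aromatic", {
  kek <- parse_smiles("C1=CC=CC=C1", "kekulized")
  expect_true(all(kek$aromatic))
  expect_identical(atom_pairs(kek)$features,
                   atom_pairs(parse_smiles("c1ccccc1"))$features)
})

test_that("unparsable SMILES raise structured errors naming the id", {
  expect_error(parse_smiles("C(", "badmol"), "badmol")
  expect_error(parse_smiles("C1CC", "openring"), "ring")
  expect_error(parse_smiles("", "empty"), "empty")
  expect_error(parse_smiles("C%1C", "pct"), "%")
  err <- tryCatch(parse_smiles("Cq", "weird"), error = identity)
  expect_s3_class(err, "toxbasket_parse_error")
})

test_that("SMILES files read into named graph lists", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "CC ethane", "# comment", ""), path)
  gs <- read_smiles_file(path)
  expect_named(gs, c("benzene", "ethane"))
  expect_equal(n_atoms(gs$benzene), 6L)
})

test_that("SDF V2000 input maps to the same graphs as SMILES", {
  skip_if_not_installed("ChemmineR")
  atom <- function(el) sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                               0, 0, 0, el)
  bond <- function(a, b, o) sprintf("%3d%3d%3d  0", a, b, o)
  sdf <- c("benzene", "  toxbasket-test", "",
           "  6  6  0  0  0  0  0  0  0  0999 V2000",
           vapply(rep("C", 6), atom, character(1)),
           bond(1, 2, 2), bond(2, 3, 1), bond(3, 4, 2),
           bond(4, 5, 1), bond(5, 6, 2), bond(6, 1, 1),
           "M  END", "$$$$")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, path)
  gs <- read_sdf_file(path)
  expect_length(gs, 1L)
  expect_true(all(gs[[1]]$aromatic))
  expect_identical(atom_pairs(gs[[1]])$features,
                   atom_pairs(parse_smiles("c1ccccc1"))$features)
})
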