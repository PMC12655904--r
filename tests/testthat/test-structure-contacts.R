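test_that("generated complexes contain exactly the planted contacts", {
  cx <- generateComplex(12, c(3, 7), cutoff = 5, seed = 61)
  found <- findContacts(cx, 5)
  expect_equal(found$resno, c(3, 7))
  expect_equal(found$resno, oracleContacts(cx, 5))
  # empty contact set
  none <- generateComplex(8, integer(), cutoff = 5, seed = 62)
  expect_equal(nrow(findContacts(none, 5)), 0)
  # determinism
  again <- generateComplex(12, c(3, 7), cutoff = 5, seed = 61)
  expect_identical(cx@atoms, again@atoms)
  expect_error(generateComplex(5, c(2), cutoff = 1.0), "impossible geometry")
  expect_error(generateComplex(5, c(9), cutoff = 5), "within 1..n",
               fixed = TRUE)
})

test_that("contact detection matches the all-pairs oracle on random complexes", {
  for (seed in 1:25) {
    set.seed(seed)
    nres <- sample(20:50, 1)
    contacts <- sort(sample(nres, sample(0:6, 1)))
    cx <- generateComplex(nres, contacts, cutoff = 5, seed = seed)
    expect_equal(findContacts(cx, 5)$resno, oracleContacts(cx, 5))
  }
})

test_that("contacts respect the inclusive cutoff boundary", {
  atoms <- data.frame(
    element = c("C", "N", "N"),
    x = c(0, 4.9, 5.1), y = 0, z = 0,
    resname = c("LIG", "LEU", "PHE"), resno = c(1L, 10L, 20L),
    chain = c("L", "A", "A"), ligand = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  cx <- new("ComplexStructure", complexId = "edge", atoms = atoms)
  hits <- findContacts(cx, 5)
  expect_equal(hits$resno, 10)            # 4.9 in, 5.1 out
  exact <- atoms; exact$x[3] <- 5.0
  cx2 <- new("ComplexStructure", complexId = "edge2", atoms = exact)
  expect_equal(findContacts(cx2, 5)$resno, c(10, 20))  # 5.0 inclusive
})

test_that("contact detection is invariant under rigid motion", {
  cx <- generateComplex(20, c(2, 11, 19), cutoff = 5, seed = 63)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  a <- cx@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, c(12, -4, 7), "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  moved <- new("ComplexStructure", complexId = "moved", atoms = a)
  expect_equal(findContacts(moved, 5)$resno, findContacts(cx, 5)$resno)
})

test_that("PDB writing round-trips through the standard parser", {
  cx <- generateComplex(6, c(1, 4), cutoff = 5, seed = 64)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeComplexPdb(cx, path)
  back <- parseComplex(path)
  expect_equal(nrow(back@atoms), nrow(cx@atoms))
  expect_equal(back@atoms$x, cx@atoms$x, tolerance = 1e-3)
  expect_equal(back@atoms$resno, cx@atoms$resno)
  expect_equal(back@atoms$ligand, cx@atoms$ligand)
  expect_equal(back@atoms$resname[!back@atoms$ligand],
               cx@atoms$resname[!cx@atoms$ligand])
  expect_equal(findContacts(back, 5)$resno, c(1, 4))
  # a file without HETATM records and no selector errors
  rec <- cx@atoms[!cx@atoms$ligand, ]
  recOnly <- new("ComplexStructure", complexId = "rec", atoms = rec)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeComplexPdb(recOnly, path2)
  expect_error(parseComplex(path2), "no ligand atoms")
})

test_that("aggregation counts residue instances and percentages sum to 100", {
  one <- list(data.frame(resno = 1:3, resname = c("LEU", "LEU", "PHE"),
                         chain = "A", minDist = 4, nAtomPairs = c(2L, 1L, 5L)))
  prof <- aggregateFrequencies(one)
  expect_equal(contactCounts(prof), c(LEU = 2L, PHE = 1L))
  expect_equal(unname(contactPercentages(prof)), c(200 / 3, 100 / 3),
               tolerance = 1e-10)
  expect_equal(sum(contactPercentages(prof)), 100)
  # per-complex presence counts each type once per complex
  pres <- aggregateFrequencies(one, unit = "complex")
  expect_equal(contactCounts(pres)[["LEU"]], 1L)
  # atom-pair unit uses the pair counts
  pairs <- aggregateFrequencies(one, unit = "atom_pair")
  expect_equal(contactCounts(pairs)[["PHE"]], 5L)
  # no contacts anywhere: empty profile without percentages
  empty <- aggregateFrequencies(list(one[[1]][0, ]))
  expect_length(contactCounts(empty), 0)
  expect_length(contactPercentages(empty), 0)
})

test_that("aggregated counts over synthetic complexes equal the planted design", {
  planted <- lapply(1:15, function(i) {
    set.seed(i)
    sort(sample(20, sample(1:4, 1)))
  })
  sets <- lapply(seq_along(planted), function(i)
    findContacts(generateComplex(20, planted[[i]], cutoff = 5,
                                 seed = 100 + i), 5))
  prof <- aggregateFrequencies(sets)
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  expected <- table(aa[unlist(planted)])
  expect_equal(sum(contactCounts(prof)), length(unlist(planted)))
  for (nm in names(expected))
    expect_equal(contactCounts(prof)[[nm]], as.integer(expected[[nm]]))
  expect_equal(sum(contactPercentages(prof)), 100, tolerance = 1e-6)
})

test_that("FASTA export maps residues in number order with X fallback", {
  contacts <- data.frame(resno = c(404, 346, 353),
                         resname = c("PHE", "LEU", "GLU"),
                         chain = "A", minDist = 4, nAtomPairs = 1L)
  lines <- exportFasta(list(cplx1 = contacts))
  expect_equal(lines, c(">cplx1", "LEF"))
  # empty contact set yields an empty-sequence record
  lines2 <- exportFasta(list(empty = contacts[0, ]))
  expect_equal(lines2, c(">empty", ""))
  # non-standard residue becomes X
  odd <- data.frame(resno = c(1, 2), resname = c("LEU", "XYZ"),
                    chain = "A", minDist = 4, nAtomPairs = 1L)
  expect_equal(exportFasta(list(c1 = odd))[2], "LX")
  expect_error(exportFasta(list(contacts)), "named")
})
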