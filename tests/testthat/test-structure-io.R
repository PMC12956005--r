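test_that("multi-model files give one structure per MODEL with records intact", {
  s <- makeTwoChainScaffold(2)
  at <- atoms(s)[1:10, ]
  m1 <- new("PDBStructure", modelId = 1L, atoms = at, title = "two models")
  at2 <- at
  at2$x <- at2$x + 1
  m2 <- new("PDBStructure", modelId = 2L, atoms = at2, title = "two models")
  parsed <- parsePDB(writePDB(list(m1, m2)))
  expect_length(parsed, 2L)
  expect_equal(vapply(parsed, nAtoms, integer(1)), c(10L, 10L))
  expect_equal(vapply(parsed, function(x) x@modelId, integer(1)), 1:2)
  # a single structure writes without MODEL records
  txt <- writePDB(m1)
  expect_false(grepl("MODEL", txt))
  expect_length(parsePDB(txt), 1L)
})

test_that("altloc collapse follows the policy, ties broken by letter", {
  txt <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  N   ALA A   1       2.000   0.000   0.000  1.00  0.00           N",
    sep = "\n")
  s <- parsePDB(txt, altloc = "highest_occupancy")[[1L]]
  expect_equal(nAtoms(s), 2L)
  expect_equal(atoms(s)$occupancy[atoms(s)$name == "CA"], 0.6)
  s_first <- parsePDB(txt, altloc = "first")[[1L]]
  expect_equal(atoms(s_first)$x[atoms(s_first)$name == "CA"], 0)
  # equal occupancies: altloc letter order decides
  tie <- gsub("0.60", "0.40", txt, fixed = TRUE)
  s_tie <- parsePDB(tie, altloc = "highest_occupancy")[[1L]]
  expect_equal(atoms(s_tie)$x[atoms(s_tie)$name == "CA"], 0)
})

test_that("write/parse round trip is the identity on atom tables", {
  for (seed in 1:8) {
    fx <- plantWaterBridges(makeTwoChainScaffold(6, seed = seed),
                            k = 2, nDecoys = 2, seed = seed)
    s <- fx$structure
    back <- parsePDB(writePDB(s))[[1L]]
    a0 <- atoms(s)
    a1 <- atoms(back)
    for (col in c("x", "y", "z")) a0[[col]] <- round(a0[[col]], 3)
    expect_equal(a1[, names(a0)], a0, tolerance = 1e-12)
  }
})

test_that("malformed and empty inputs raise informative parse errors", {
  bad <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       xxx.0   0.000   0.000  1.00  0.00           C",
    sep = "\n")
  expect_error(parsePDB(bad), "line 2")
  expect_error(parsePDB("HEADER only\nEND"), "no ATOM or HETATM")
  s <- makeTwoChainScaffold(3)
  at <- atoms(s)
  at$chain[at$chain == "B"] <- "AB"
  s2 <- new("PDBStructure", modelId = 1L, atoms = at, title = "")
  expect_error(writePDB(s2), "chain id")
})

test_that("water identification follows the configured residue names", {
  fx <- plantWaterBridges(makeTwoChainScaffold(10), k = 3, nDecoys = 4)
  expect_setequal(identifyWaters(fx$structure),
                  c(fx$trueBridgeWaters, fx$decoyWaters))
  expect_length(
    identifyWaters(fx$structure,
                   analysisConfig(waterResnames = character(0))), 0L)
  expect_length(identifyWaters(makeTwoChainScaffold(4)), 0L)
})

test_that("interface residues match brute force and behave as a set function", {
  s <- makeTwoChainScaffold(8)
  got <- interfaceResidues(s, "A", "B", 5)
  expect_identical(got, oracleInterface(s, "A", "B", 5))
  # symmetry
  expect_identical(got, interfaceResidues(s, "B", "A", 5))
  # monotone in the cutoff
  sizes <- vapply(c(3, 4, 5, 6, 8), function(cc)
    length(interfaceResidues(s, "A", "B", cc)), integer(1))
  expect_true(all(diff(sizes) >= 0))
  # distant chains: empty interface
  far <- makeTwoChainScaffold(6, separation = 50)
  expect_length(interfaceResidues(far, "A", "B", 5), 0L)
  expect_error(interfaceResidues(s, "A", "Q", 5), "chain 'Q'")
})

test_that("a single contact pair at 4 A yields exactly those two residues", {
  # one residue per chain, closest heavy atoms exactly 4 A apart
  s <- makeTwoChainScaffold(4, separation = 40)
  at <- atoms(s)
  keys <- dimerstab:::.atomKeys(at)
  at <- at[keys %in% c("A:2", "B:2"), ]
  ia <- which(at$chain == "A" & at$element != "H")
  ib <- which(at$chain == "B" & at$element != "H")
  d <- dimerstab:::crossDist(as.matrix(at[ia, c("x", "y", "z")]),
                             as.matrix(at[ib, c("x", "y", "z")]))
  hit <- which(d == min(d), arr.ind = TRUE)[1, ]
  p_a <- as.numeric(at[ia[hit[1]], c("x", "y", "z")])
  p_b <- as.numeric(at[ib[hit[2]], c("x", "y", "z")])
  shift <- (p_b - p_a) * (1 - 4 / sqrt(sum((p_b - p_a)^2)))
  sel <- at$chain == "B"
  at$x[sel] <- at$x[sel] - shift[1]
  at$y[sel] <- at$y[sel] - shift[2]
  at$z[sel] <- at$z[sel] - shift[3]
  at$serial <- seq_len(nrow(at))
  s2 <- new("PDBStructure", modelId = 1L, atoms = at, title = "")
  got <- interfaceResidues(s2, "A", "B", 5)
  expect_setequal(got, c("A:2", "B:2"))
  expect_identical(got, oracleInterface(s2, "A", "B", 5))
  # just beyond the cutoff nothing is reported
  expect_length(interfaceResidues(s2, "A", "B", 3.9), 0L)
})

test_that("parsed structures agree with an independent PDB reader", {
  fx <- plantWaterBridges(makeTwoChainScaffold(5), k = 1, nDecoys = 1)
  tmp <- tempfile(fileext = ".pdb")
  writePDB(fx$structure, tmp)
  ours <- atoms(parsePDB(tmp)[[1L]])
  ref <- bio3d::read.pdb(tmp)$atom
  expect_equal(nrow(ours), nrow(ref))
  expect_equal(ours$x, ref$x, tolerance = 1e-9)
  expect_equal(ours$y, ref$y, tolerance = 1e-9)
  expect_equal(ours$z, ref$z, tolerance = 1e-9)
  expect_equal(trimws(ours$name), trimws(ref$elety))
  expect_equal(ours$resseq, ref$resno)
  expect_equal(ours$chain, ref$chain)
})

test_that("the MD protocol record validates and yields the frame count", {
  p <- mdProtocol()
  expect_equal(expectedFrames(p), 50L)
  expect_error(mdProtocol(production = -1), "positive")
  expect_error(mdProtocol(production = 101, saveInterval = 2), "integer frame")
})

test_that("analysis config validates cutoffs and reads from YAML", {
  expect_error(analysisConfig(dCut = 0), "dCut")
  expect_error(analysisConfig(thetaCut = 200), "thetaCut")
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("d_cut: 3.2", "theta_cut: 140", "hbond_mode: heavy",
               "ligand_resnames: [URI]"), tmp)
  cfg <- readAnalysisConfig(tmp)
  expect_equal(cfg@dCut, 3.2)
  expect_equal(cfg@thetaCut, 140)
  expect_equal(cfg@hbondMode, "heavy")
  expect_equal(cfg@ligandResnames, "URI")
})
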