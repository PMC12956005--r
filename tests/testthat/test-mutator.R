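test_that("A->T rebuilds the side chain in place with ideal topology", {
  s <- makeTwoChainScaffold(8)
  res <- applyMutation(s, mutationSpec("A", 4, "A", "T"), addHydrogens = TRUE)
  ra <- residueAtoms(res$structure, "A:4")
  expect_true(all(c("OG1", "CG2", "HG1") %in% ra$name))
  expect_equal(ra$resname[1], "THR")
  # backbone and every other residue untouched (RMSD 0)
  a0 <- atoms(s)
  a1 <- atoms(res$structure)
  k0 <- dimerstab:::.atomKeys(a0)
  k1 <- dimerstab:::.atomKeys(a1)
  for (nm in c("N", "CA", "C", "O", "CB")) {
    p0 <- a0[k0 == "A:4" & a0$name == nm, c("x", "y", "z")]
    p1 <- a1[k1 == "A:4" & a1$name == nm, c("x", "y", "z")]
    expect_equal(unlist(p1), unlist(p0), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  o0 <- a0[k0 != "A:4", c("name", "chain", "resseq", "x", "y", "z")]
  o1 <- a1[k1 != "A:4", c("name", "chain", "resseq", "x", "y", "z")]
  expect_equal(o1, o0, ignore_attr = TRUE)
  # ideal bond lengths of the new atoms
  pos <- function(n) as.numeric(ra[ra$name == n, c("x", "y", "z")])
  expect_equal(sqrt(sum((pos("OG1") - pos("CB"))^2)), 1.433,
               tolerance = 1e-6)
  expect_equal(sqrt(sum((pos("CG2") - pos("CB"))^2)), 1.521,
               tolerance = 1e-6)
})

test_that("identity mutation returns the structure unchanged", {
  s <- makeTwoChainScaffold(6)
  res <- applyMutation(s, mutationSpec("A", 3, "A", "A"))
  expect_identical(atoms(res$structure), atoms(s))
  expect_gte(res$clashScore, 0)
})

test_that("mutation is deterministic bit-for-bit", {
  s <- makeTwoChainScaffold(8)
  r1 <- applyMutation(s, mutationSpec("A", 4, "A", "T"))
  r2 <- applyMutation(s, mutationSpec("A", 4, "A", "T"))
  expect_identical(atoms(r1$structure), atoms(r2$structure))
  expect_identical(r1$chiAngles, r2$chiAngles)
})

test_that("identity and completeness guards fire", {
  s <- makeTwoChainScaffold(6)
  expect_error(applyMutation(s, mutationSpec("A", 3, "S", "T")),
               "identity mismatch")
  at <- atoms(s)
  keys <- dimerstab:::.atomKeys(at)
  broken <- new("PDBStructure", modelId = 1L,
                atoms = at[!(keys == "A:3" & at$name == "CA"), ],
                title = "")
  expect_error(applyMutation(broken, mutationSpec("A", 3, "A", "T")),
               "incomplete residue")
  expect_error(applyMutation(s, mutationSpec("Q", 3, "A", "T")),
               "not found")
  expect_error(mutationSpec("A", 3, "A", "Z"), "canonical")
})

test_that("clash score follows the squared-overlap formula", {
  mk <- function(d) {
    at <- data.frame(serial = 1:2, name = "O", element = "O", altloc = "",
                     resname = "HOH", chain = "W", resseq = 1:2, icode = "",
                     x = c(0, d), y = 0, z = 0, occupancy = 1, bfactor = 0,
                     is_hetero = TRUE, stringsAsFactors = FALSE)
    new("PDBStructure", modelId = 1L, atoms = at, title = "")
  }
  rsum <- 2 * 1.52  # O + O van der Waals radii
  # exactly at the vdW sum: zero
  expect_equal(clashScore(mk(rsum), "W:1"), 0)
  # 0.5 A overlap on one pair: 0.25
  expect_equal(clashScore(mk(rsum - 0.5), "W:1"), 0.25, tolerance = 1e-12)
  # isolated residue: zero
  expect_equal(clashScore(mk(50), "W:1"), 0)
  # scaffold residues are clash-free by construction
  s <- makeTwoChainScaffold(6)
  cs <- vapply(residueTable(s)$key, function(k) clashScore(s, k), numeric(1))
  expect_true(all(cs == 0))
})

test_that("rotamer choice lands in the clash-free set of a 1-degree oracle", {
  # on the extended scaffold, two of the three coarse chi1 grid points
  # bury the new side chain in a neighbouring residue; the survivor is
  # found and is clash-free
  s <- makeTwoChainScaffold(8)
  ra <- residueAtoms(s, "A:4")
  pos <- function(n) as.numeric(ra[ra$name == n, c("x", "y", "z")])
  res <- applyMutation(s, mutationSpec("A", 4, "A", "T"))

  # oracle: exhaustive 1-degree chi1 grid; clash of OG1/CG2 against all
  # heavy atoms of other residues with plain loops and own radii, the
  # covalently constrained contacts (previous C, next N) excepted
  at <- atoms(s)
  oth <- at[!(dimerstab:::.atomKeys(at) == "A:4") & at$element != "H", ]
  vdw <- c(O = 1.52, C = 1.70, N = 1.55)
  oracle_clash <- function(chi) {
    og1 <- dimerstab:::placeAtom(pos("N"), pos("CA"), pos("CB"),
                                 1.433, 109.6, chi)
    cg2 <- dimerstab:::placeAtom(pos("N"), pos("CA"), pos("CB"),
                                 1.521, 110.5, chi - 120)
    tot <- 0
    for (p in list(c(og1, 1.52), c(cg2, 1.70))) {
      for (r in seq_len(nrow(oth))) {
        if (oth$chain[r] == "A" && oth$resseq[r] == 3 &&
              oth$name[r] == "C") next
        if (oth$chain[r] == "A" && oth$resseq[r] == 5 &&
              oth$name[r] == "N") next
        d <- sqrt(sum((p[1:3] - c(oth$x[r], oth$y[r], oth$z[r]))^2))
        tot <- tot + max(0, p[4] + vdw[[oth$element[r]]] - d)^2
      }
    }
    tot
  }
  grid <- seq(-179, 180)
  oc <- vapply(grid, oracle_clash, numeric(1))
  clash_free <- grid[oc == 0]
  expect_true(length(clash_free) > 0)
  # the other coarse grid points bury the side chain in a neighbour
  expect_gt(oracle_clash(60), 0)
  expect_gt(oracle_clash(180), 0)
  # chosen rotamer is clash-free and lies in the oracle's clash-free set
  expect_equal(res$clashScore, 0)
  expect_true(min(abs((res$chiAngles[1] - clash_free + 180) %% 360 - 180))
              <= 1)
})
test_that("polar hydrogen placement is complete, oriented and idempotent", {
  n <- 7
  s_raw <- makeTwoChainScaffold(n)
  at <- atoms(s_raw)
  expect_equal(sum(at$element == "H"), 2 * (n - 1))  # amide H per chain
  # idempotent: nothing further to add
  again <- addPolarHydrogens(s_raw)
  expect_identical(atoms(again), atoms(s_raw))

  # amide H sits in the peptide plane, ~1.01 A from N
  keys <- dimerstab:::.atomKeys(at)
  hN <- at[keys == "A:2" & at$name %in% c("N", "H"), ]
  expect_equal(sqrt(sum((hN[hN$name == "H", c("x", "y", "z")] -
                           hN[hN$name == "N", c("x", "y", "z")])^2)),
               1.01, tolerance = 1e-6)

  # hydroxyl torsion points at a nearby acceptor: 1-degree grid oracle
  mutd <- applyMutation(s_raw, mutationSpec("A", 4, "A", "T"))$structure
  ra <- residueAtoms(mutd, "A:4")
  pos <- function(n2) as.numeric(ra[ra$name == n2, c("x", "y", "z")])
  og1 <- pos("OG1"); cb <- pos("CB")
  dir <- og1 - cb; dir <- dir / sqrt(sum(dir^2))
  up <- c(0, 0, 1); up <- up - sum(up * dir) * dir
  acc <- og1 + 2.8 * (0.4 * dir + 0.6 * up / sqrt(sum(up^2)))
  acc <- og1 + 2.8 * ((acc - og1) / sqrt(sum((acc - og1)^2)))
  at2 <- atoms(mutd)
  at2 <- rbind(at2, data.frame(serial = 0L, name = "O", element = "O",
                               altloc = "", resname = "HOH", chain = "W",
                               resseq = 1L, icode = "", x = acc[1],
                               y = acc[2], z = acc[3], occupancy = 1,
                               bfactor = 0, is_hetero = TRUE))
  at2$serial <- seq_len(nrow(at2))
  s2 <- addPolarHydrogens(new("PDBStructure", modelId = 1L, atoms = at2,
                              title = ""))
  ra2 <- residueAtoms(s2, "A:4")
  hg1 <- as.numeric(ra2[ra2$name == "HG1", c("x", "y", "z")])
  got <- dimerstab:::pointAngle(og1, hg1, acc)
  # oracle: spin the O-H about the CB-OG1 axis in 1-degree steps
  h0 <- dimerstab:::placeAtom(pos("CA"), cb, og1, 0.96, 109, 0)
  best <- max(vapply(seq(0, 359), function(tau) {
    h <- og1 + as.numeric(dimerstab:::rotateAboutAxis(
      matrix(h0 - og1, 1), og1 - cb, tau))
    dimerstab:::pointAngle(og1, h, acc)
  }, numeric(1)))
  expect_gte(got, best - 0.2)
})

test_that("unknown residue names are skipped with a warning", {
  s <- makeTwoChainScaffold(4)
  at <- atoms(s)
  at$resname[at$resseq == 2 & at$chain == "A"] <- "XYZ"
  at <- at[!(at$name == "H" & dimerstab:::.atomKeys(at) == "A:2"), ]
  at$serial <- seq_len(nrow(at))
  s2 <- new("PDBStructure", modelId = 1L, atoms = at, title = "")
  expect_warning(addPolarHydrogens(s2), "XYZ")
})
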