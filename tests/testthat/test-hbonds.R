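test_that("distance and angle thresholds are inclusive", {
  cfg <- analysisConfig()
  # exactly 3.50 A and exactly 150.0 degrees: a bond
  hb <- findHBonds(boundaryPair(3.5, 150), cfg)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 3.5, tolerance = 1e-9)
  expect_equal(hb$angle, 150, tolerance = 1e-9)
  # 3.6 A: no bond
  expect_equal(nrow(findHBonds(boundaryPair(3.6, 170), cfg)), 0L)
  # angle below the cutoff: no bond
  expect_equal(nrow(findHBonds(boundaryPair(3.2, 145), cfg)), 0L)
  # a comfortable bond: water O 2.8 A from an acceptor, angle ~175
  expect_equal(nrow(findHBonds(boundaryPair(2.8, 175), cfg)), 1L)
})

test_that("strict mode without hydrogens is a mode error", {
  s <- makeTwoChainScaffold(4)
  at <- atoms(s)
  at <- at[at$element != "H", ]
  at$serial <- seq_len(nrow(at))
  bare <- new("PDBStructure", modelId = 1L, atoms = at, title = "")
  expect_error(findHBonds(bare), "heavy|addPolarHydrogens")
  expect_silent(findHBonds(bare, analysisConfig(hbondMode = "heavy")))
})

test_that("binned search equals exhaustive enumeration on random fixtures", {
  cfg <- analysisConfig()
  for (seed in 1:10) {
    s <- waterBox(nWaters = 40, seed = seed)
    expect_identical(hbondTriples(findHBonds(s, cfg)), oracleHBonds(s, cfg))
  }
  # heavy mode too
  cfg_h <- analysisConfig(hbondMode = "heavy")
  s <- waterBox(nWaters = 40, seed = 99)
  expect_identical(hbondTriples(findHBonds(s, cfg_h)), oracleHBonds(s, cfg_h))
})

test_that("detection is invariant under atom permutation and rigid motion", {
  fx <- plantWaterBridges(makeTwoChainScaffold(10), k = 3, nDecoys = 5,
                          seed = 4)
  s <- fx$structure
  hb0 <- findHBonds(s)
  sig0 <- hbondSignatures(hb0)
  # rigid rotation + translation preserves everything
  for (seed in 1:5) {
    hb1 <- findHBonds(rigidTransform(s, seed))
    expect_identical(hbondSignatures(hb1), sig0)
    expect_equal(sort(hb1$distance), sort(hb0$distance), tolerance = 1e-8)
    expect_equal(sort(hb1$angle), sort(hb0$angle), tolerance = 1e-6)
  }
  # residue-block permutation preserves the bond set
  at <- atoms(s)
  keys <- dimerstab:::.atomKeys(at)
  blocks <- split(seq_len(nrow(at)), factor(keys, levels = unique(keys)))
  set.seed(1)
  at2 <- at[unlist(blocks[sample(length(blocks))]), ]
  at2$serial <- seq_len(nrow(at2))
  rownames(at2) <- NULL
  s2 <- new("PDBStructure", modelId = 1L, atoms = at2, title = "")
  expect_identical(hbondSignatures(findHBonds(s2)), sig0)
})

test_that("planted bridges are recovered exactly, decoys rejected", {
  s <- makeTwoChainScaffold(20)
  fx <- plantWaterBridges(s, k = 5, nDecoys = 12, seed = 2)
  br <- findWaterBridges(fx$structure)
  expect_setequal(unique(br$water), fx$trueBridgeWaters)
  expect_equal(countBridges(br, "waters"), 5L)
  expect_equal(countBridges(br, "pairs"), fx$truePairCount)
  # structure without waters: empty result
  expect_equal(nrow(findWaterBridges(makeTwoChainScaffold(6))), 0L)
  # every bridge partner pair appears in the H-bond output
  hb <- findHBonds(fx$structure)
  hb_atoms <- unique(c(paste(hb$donor_key, hb$donor_atom),
                       paste(hb$acceptor_key, hb$acceptor_atom)))
  expect_true(all(paste(br$a_key, br$a_atom) %in% hb_atoms))
  expect_true(all(paste(br$b_key, br$b_atom) %in% hb_atoms))
  expect_error(findWaterBridges(fx$structure, "A", "A"), "must differ")
})

test_that("a water bonded to only one chain is not a bridge", {
  fx <- plantWaterBridges(makeTwoChainScaffold(8), k = 2, nDecoys = 0)
  # against a chain with no bonded partners there is no bridge
  br <- findWaterBridges(fx$structure, "A", "C")
  expect_equal(nrow(br), 0L)
})

test_that("bridge counting metrics follow their definitions", {
  expect_equal(countBridges(data.frame(water = character(0))), 0L)
  # one water bonded to 2 atoms of A and 1 of B: waters = 1, pairs = 2
  br <- data.frame(water = "W:1", a_key = c("A:1", "A:2"), a_atom = "O",
                   b_key = "B:1", b_atom = "O")
  expect_equal(countBridges(br, "waters"), 1L)
  expect_equal(countBridges(br, "pairs"), 2L)
  fx <- plantWaterBridges(makeTwoChainScaffold(46), k = 20, nDecoys = 0,
                          seed = 8)
  expect_equal(countBridges(findWaterBridges(fx$structure), "waters"), 20L)
})

test_that("bridge counts are monotone in both cutoffs", {
  fx <- plantWaterBridges(makeTwoChainScaffold(14), k = 3, nDecoys = 8,
                          seed = 3)
  counts_d <- vapply(seq(3.0, 4.0, by = 0.1), function(dc)
    countBridges(findWaterBridges(fx$structure,
                                  config = analysisConfig(dCut = dc)),
                 "waters"), integer(1))
  expect_true(all(diff(counts_d) >= 0))
  counts_t <- vapply(seq(170, 130, by = -5), function(tc)
    countBridges(findWaterBridges(fx$structure,
                                  config = analysisConfig(thetaCut = tc)),
                 "waters"), integer(1))
  expect_true(all(diff(counts_t) >= 0))
})

test_that("network diffs partition into conserved/added/removed", {
  wt <- plantWaterBridges(makeTwoChainScaffold(12), k = 2, nDecoys = 0,
                          seed = 6)
  mut <- plantWaterBridges(makeTwoChainScaffold(12), k = 3, nDecoys = 0,
                           seed = 6)
  sig_wt <- hbondSignatures(findHBonds(wt$structure),
                            findWaterBridges(wt$structure))
  sig_mut <- hbondSignatures(findHBonds(mut$structure),
                             findWaterBridges(mut$structure))
  d <- diffHBonds(sig_wt, sig_mut)
  expect_length(intersect(d$conserved, d$added), 0L)
  expect_length(intersect(d$conserved, d$removed), 0L)
  expect_length(d$removed, 0L)
  expect_gt(length(d$added), 0L)
  expect_setequal(c(d$conserved, d$added), sig_mut)
  expect_setequal(c(d$conserved, d$removed), sig_wt)
  # identical inputs: nothing added or removed
  d0 <- diffHBonds(sig_wt, sig_wt)
  expect_length(d0$added, 0L)
  expect_length(d0$removed, 0L)
  # disjoint inputs: nothing conserved
  d2 <- diffHBonds(c("x>y"), c("u>v"))
  expect_length(d2$conserved, 0L)
})
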