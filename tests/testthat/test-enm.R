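twoNodeStructure <- function(d = 3.8) {
  at <- data.frame(serial = 1:2, name = "CA", element = "C", altloc = "",
                   resname = "ALA", chain = "A", resseq = 1:2, icode = "",
                   x = c(0, d), y = 0, z = 0, occupancy = 1, bfactor = 0,
                   is_hetero = FALSE, stringsAsFactors = FALSE)
  new("PDBStructure", modelId = 1L, atoms = at, title = "")
}

test_that("two connected nodes give the closed-form spectrum", {
  for (g in c(0.5, 1, 2)) {
    sp <- normalModes(buildENM(twoNodeStructure(), gamma = g))
    vals <- modeValues(sp)
    expect_equal(vals[6], 2 * g, tolerance = 1e-12)
    expect_true(all(abs(vals[1:5]) < 1e-12))
  }
})

test_that("the Hessian annihilates uniform translations", {
  for (seed in 1:3) {
    enm <- buildENM(randomCoil(15, seed))
    n <- nrow(enm@nodes)
    for (axis in 1:3) {
      tv <- rep(0, 3 * n)
      tv[seq(axis, 3 * n, by = 3)] <- 1
      expect_lt(max(abs(enm@hessian %*% tv)), 1e-12)
    }
  }
})

test_that("connected non-collinear networks have exactly six zero modes", {
  for (seed in c(1, 7, 21)) {
    sp <- normalModes(buildENM(randomCoil(12, seed)))
    expect_equal(sp@nZero, 6L)
  }
})

test_that("assembled Hessian equals the naive double-loop reference", {
  s <- randomCoil(40, seed = 5)
  enm <- buildENM(s, cutoff = 13, gamma = 1.3)
  H_ref <- oracleHessian(coords(s), 13, 1.3)
  expect_equal(enm@hessian, H_ref, tolerance = 1e-12)
})

test_that("eigendecomposition is consistent with generic linear algebra", {
  enm <- buildENM(randomCoil(50, seed = 9))
  sp <- normalModes(enm)
  # eigen residuals: H v = lambda v
  res <- enm@hessian %*% sp@vectors -
    sweep(sp@vectors, 2, sp@values, "*")
  expect_lt(max(abs(res)), 1e-8 * max(abs(sp@values)))
  # orthonormal modes
  expect_equal(crossprod(sp@vectors), diag(ncol(sp@vectors)),
               tolerance = 1e-8)
  # non-zero spectrum matches singular values of the symmetric PSD Hessian
  sv <- sort(svd(enm@hessian, nu = 0, nv = 0)$d)
  nz <- sp@nZero
  expect_equal(sp@values[(nz + 1):length(sp@values)],
               sv[(nz + 1):length(sv)], tolerance = 1e-8)
})

test_that("a disconnected network is flagged and gains zero modes", {
  a <- atoms(randomCoil(8, 1, chain = "A"))
  b <- atoms(randomCoil(8, 2, chain = "B"))
  b$x <- b$x + 200
  at <- rbind(a, b)
  at$serial <- seq_len(nrow(at))
  s <- new("PDBStructure", modelId = 1L, atoms = at, title = "")
  enm <- buildENM(s, cutoff = 13)
  expect_match(enm@warnings, "disconnected", all = FALSE)
  expect_equal(normalModes(enm)@nZero, 12L)
})

test_that("vibrational entropy has its closed-form scaling and exact zeros", {
  s <- randomCoil(20, seed = 3)
  sp1 <- normalModes(buildENM(s, gamma = 1))
  sp2 <- normalModes(buildENM(s, gamma = 0.5))
  e1 <- vibrationalEntropy(sp1)
  e2 <- vibrationalEntropy(sp2)
  kB <- 0.0019872041 * 1000
  expect_equal(e2$sVib - e1$sVib, (kB / 2) * e1$nModesUsed * log(2),
               tolerance = 1e-10)
  # identical spectra: difference exactly zero
  e1b <- vibrationalEntropy(normalModes(buildENM(s, gamma = 1)))
  expect_identical(e1$sVib - e1b$sVib, 0)
  # entropy difference equals the SVD pseudo-log-determinant route
  H1 <- buildENM(s, gamma = 1)@hessian
  H2 <- buildENM(s, gamma = 0.5)@hessian
  expect_equal(e2$sVib - e1$sVib,
               -(kB / 2) * (pseudoLogDet(H2) - pseudoLogDet(H1)),
               tolerance = 1e-8)
})

test_that("degenerate networks raise an error instead of entropies", {
  far <- twoNodeStructure(50)
  enm <- buildENM(far, cutoff = 13)
  expect_error(vibrationalEntropy(normalModes(enm)), "degenerate")
})

test_that("stability proxy is zero for identical inputs and antisymmetric", {
  fx <- makeEnmFixturePair(
    nRes = 10,
    springEdits = data.frame(key_i = "A:5", key_j = "A:6", factor = 3))
  self <- stateStability(fx$wt, fx$wt, "active")
  expect_identical(ddgProxy(self), 0)
  expect_identical(ddsVib(self), 0)
  expect_true(all(perResidueDds(self) == 0))

  fwd <- stateStability(fx$wt, fx$mut, "active",
                        enmWt = fx$enmWt, enmMut = fx$enmMut)
  rev <- stateStability(fx$mut, fx$wt, "active",
                        enmWt = fx$enmMut, enmMut = fx$enmWt)
  expect_equal(ddsVib(rev), -ddsVib(fwd), tolerance = 1e-12)
  expect_equal(perResidueDds(rev), -perResidueDds(fwd), tolerance = 1e-12)
  expect_equal(ddgProxy(rev), -ddgProxy(fwd), tolerance = 1e-12)
  # per-residue attribution sums to the total
  expect_equal(sum(perResidueDds(fwd)), ddsVib(fwd), tolerance = 1e-9)
})

test_that("sign behaviour: gained bridge + stiffening stabilizes, softening destabilizes", {
  stiff <- data.frame(key_i = "A:5", key_j = c("A:6", "A:4", "B:5"),
                      factor = 4)
  fx <- makeEnmFixturePair(nRes = 10, springEdits = stiff, bridgeDelta = 1,
                           seed = 2)
  rep1 <- stateStability(fx$wt, fx$mut, "active",
                         enmWt = fx$enmWt, enmMut = fx$enmMut)
  expect_gt(ddgProxy(rep1), 0)
  expect_equal(rep1@deltaContacts, 1L)
  expect_lt(ddsVib(rep1), 0)  # stiffening rigidifies
  pr <- perResidueDds(rep1)
  expect_equal(names(pr)[which.max(abs(pr))], "A:5")

  soft <- data.frame(key_i = "A:5", key_j = c("A:6", "A:4", "B:5"),
                     factor = 0.25)
  fx2 <- makeEnmFixturePair(nRes = 10, springEdits = soft, bridgeDelta = 0,
                            seed = 2)
  rep2 <- stateStability(fx2$wt, fx2$mut, "inactive",
                         enmWt = fx2$enmWt, enmMut = fx2$enmMut)
  expect_lt(ddgProxy(rep2), 0)
  expect_gt(ddsVib(rep2), 0)
})

test_that("mismatched backbones raise an alignment error", {
  a <- makeTwoChainScaffold(8)
  b <- makeTwoChainScaffold(9)
  expect_error(stateStability(a, b, "active"), "alignment")
})

test_that("spring edits outside the network are rejected", {
  s <- makeTwoChainScaffold(8)
  expect_error(buildENM(s, springEdits = data.frame(
    key_i = "A:1", key_j = "Z:9", factor = 2)), "absent node")
})
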