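# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no files are read.

# A small protein fragment plus randomly placed, randomly oriented rigid
# waters in a box around it: exercises donors, acceptors and both
# hydrogens of each water across the full distance/angle range.
waterBox <- function(nWaters = 60, seed = 1, nRes = 4, box = 14) {
  set.seed(seed)
  s <- makeTwoChainScaffold(nRes)
  at <- atoms(s)
  ctr <- colMeans(at[, c("x", "y", "z")])
  rows <- list()
  for (w in seq_len(nWaters)) {
    O <- ctr + runif(3, -box / 2, box / 2)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    half <- 104.5 / 2 * pi / 180
    h1 <- O + 0.957 * (cos(half) * u + sin(half) * v)
    h2 <- O + 0.957 * (cos(half) * u - sin(half) * v)
    p <- rbind(O, h1, h2)
    rows[[w]] <- data.frame(
      serial = 0L, name = c("O", "H1", "H2"), element = c("O", "H", "H"),
      altloc = "", resname = "HOH", chain = "W", resseq = w, icode = "",
      x = p[, 1], y = p[, 2], z = p[, 3], occupancy = 1, bfactor = 0,
      is_hetero = TRUE, stringsAsFactors = FALSE)
  }
  out <- rbind(at, do.call(rbind, rows))
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  new("PDBStructure", modelId = 1L, atoms = out, title = "water box")
}

# Calpha-only random coil: consecutive nodes 3.8 A apart in random
# directions. Non-collinear and connected at the default cutoff.
randomCoil <- function(n = 20, seed = 1, chain = "A") {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      p <- xyz[i - 1, ] + 3.8 * u
      if (i == 2 || sqrt(sum((p - xyz[i - 2, ])^2)) > 3.0) break
    }
    xyz[i, ] <- p
  }
  at <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                   altloc = "", resname = "ALA", chain = chain,
                   resseq = seq_len(n), icode = "", x = xyz[, 1],
                   y = xyz[, 2], z = xyz[, 3], occupancy = 1, bfactor = 0,
                   is_hetero = FALSE, stringsAsFactors = FALSE)
  new("PDBStructure", modelId = 1L, atoms = at, title = "random coil")
}

# Two heavy-only waters placed so that the donor-acceptor distance is
# exactly `d` and the D-H...A angle at the hydrogen exactly `angle`
# degrees (donor water keeps one hydrogen on the x axis).
boundaryPair <- function(d = 3.5, angle = 150) {
  O <- c(0, 0, 0)
  H <- c(0.957, 0, 0)
  th <- (180 - angle) * pi / 180  # angle of H->A with +x
  u <- c(cos(th), sin(th), 0)
  # |H + r u| = d
  b <- 2 * sum(H * u)
  cc <- sum(H * H) - d^2
  r <- (-b + sqrt(b^2 - 4 * cc)) / 2
  A <- H + r * u
  at <- data.frame(
    serial = 1:4,
    name = c("O", "H1", "H2", "O"),
    element = c("O", "H", "H", "O"),
    altloc = "", resname = "HOH", chain = "W", resseq = c(1, 1, 1, 2),
    icode = "",
    x = c(O[1], H[1], -0.24, A[1]),
    y = c(O[2], H[2], 0.93, A[2]),
    z = c(O[3], H[3], 0, A[3]),
    occupancy = 1, bfactor = 0, is_hetero = TRUE, stringsAsFactors = FALSE)
  new("PDBStructure", modelId = 1L, atoms = at, title = "boundary pair")
}

# Apply a rigid rotation + translation to a structure.
rigidTransform <- function(s, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3)
  ang <- runif(1, 10, 350)
  shift <- runif(3, -20, 20)
  at <- atoms(s)
  xyz <- dimerstab:::rotateAboutAxis(as.matrix(at[, c("x", "y", "z")]),
                                     ax, ang)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  new("PDBStructure", modelId = s@modelId, atoms = at, title = s@title)
}

# The four-condition fixture set used by the end-to-end tests: the
# variant gains two interchain bridges and stiffened local springs in the
# active-like state, and loses rigidity (softened springs) in the
# inactive-like state.
fourFixtureConfig <- function(seed = 5, outputDir = NULL,
                              withTrajectories = TRUE) {
  base <- makeTwoChainScaffold(14)
  wtA <- plantWaterBridges(base, k = 2, nDecoys = 3, seed = 11)$structure
  wtI <- plantWaterBridges(base, k = 2, nDecoys = 3, seed = 12)$structure
  mutA <- plantWaterBridges(base, k = 4, nDecoys = 3, seed = 11)$structure
  mutI <- plantWaterBridges(base, k = 1, nDecoys = 3, seed = 12)$structure
  stiff <- data.frame(key_i = "A:7", key_j = c("A:8", "A:6", "B:7"),
                      factor = 4)
  soft <- data.frame(key_i = "A:7", key_j = c("A:8", "A:6", "B:7"),
                     factor = 0.25)
  traj <- list()
  if (withTrajectories) {
    set.seed(seed)
    traj <- list(
      wt_active = makePseudoTrajectory(pmin(rpois(10, 4) + 2, 12),
                                       seed = 21, nRes = 20)$frames,
      mut_active = makePseudoTrajectory(pmin(rpois(10, 4) + 6, 14),
                                        seed = 22, nRes = 20)$frames)
  }
  runConfig(wtActive = wtA, wtInactive = wtI,
            mutActive = mutA, mutInactive = mutI,
            mutation = mutationSpec("A", 7, "A", "T"),
            springEdits = list(active = stiff, inactive = soft),
            trajectories = traj, seed = seed, outputDir = outputDir)
}
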