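# Independent oracles: exhaustive enumeration and generic linear algebra,
# no spatial binning and no reuse of the implementation's search paths.

# Exhaustive O(n^2) H-bond enumeration. Chemistry (which atoms donate /
# accept) is taken from the package tables; the candidate search, the
# distance and the angle are recomputed here with plain loops.
oracleHBonds <- function(structure, config = analysisConfig()) {
  at <- atoms(structure)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  keys <- dimerstab:::.atomKeys(at)
  don <- dimerstab:::.donorIndices(at, config)
  acc <- dimerstab:::.acceptorIndices(at, config)
  strict <- config@hbondMode == "strict"
  ang3 <- function(p1, p2, p3) {
    u <- p1 - p2; v <- p3 - p2
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  triples <- character(0)
  for (i in don) {
    hs <- integer(0)
    for (h in which(at$element == "H")) {
      if (keys[h] == keys[i] &&
          sqrt(sum((xyz[h, ] - xyz[i, ])^2)) <= 1.25)
        hs <- c(hs, h)
    }
    cond <- dimerstab:::.conditionalDonor(at, i)
    if (strict && !length(hs)) next
    if (!strict && cond && !length(hs)) next
    for (j in acc) {
      if (j == i) next
      d <- sqrt(sum((xyz[j, ] - xyz[i, ])^2))
      if (d > config@dCut || d < 2.0) next
      if (strict) {
        for (h in hs) {
          if (ang3(xyz[i, ], xyz[h, ], xyz[j, ]) >= config@thetaCut)
            triples <- c(triples, paste(i, h, j))
        }
      } else {
        triples <- c(triples, paste(i, NA, j))
      }
    }
  }
  sort(triples)
}

hbondTriples <- function(hb) {
  if (!nrow(hb)) return(character(0))
  sort(paste(hb$donor_idx, hb$hydrogen_idx, hb$acceptor_idx))
}

# Naive double-loop anisotropic-network Hessian.
oracleHessian <- function(xyz, cutoff, gamma) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    rij <- xyz[j, ] - xyz[i, ]
    d2 <- sum(rij^2)
    if (sqrt(d2) > cutoff) next
    blk <- -(gamma / d2) * outer(rij, rij)
    ri <- (3 * (i - 1) + 1):(3 * i)
    rj <- (3 * (j - 1) + 1):(3 * j)
    H[ri, rj] <- H[ri, rj] + blk
    H[ri, ri] <- H[ri, ri] - blk
  }
  H
}

# Brute-force interface residues: loop over all heavy-atom pairs.
oracleInterface <- function(structure, chainA, chainB, cutoff,
                            config = analysisConfig()) {
  at <- atoms(structure)
  keep <- !at$is_hetero & at$element != "H" &
    !(at$resname %in% config@waterResnames)
  at <- at[keep, , drop = FALSE]
  keys <- dimerstab:::.atomKeys(at)
  res <- character(0)
  ia <- which(at$chain == chainA)
  ib <- which(at$chain == chainB)
  for (i in ia) for (j in ib) {
    d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
    if (d <= cutoff) res <- c(res, keys[i], keys[j])
  }
  sort(unique(res))
}

# Pseudo-log-determinant over non-zero singular values (SVD route,
# independent of the eigendecomposition used by the package).
pseudoLogDet <- function(H, tol = 1e-9) {
  sv <- svd(H, nu = 0, nv = 0)$d
  sv <- sv[sv > tol * max(sv)]
  sum(log(sv))
}
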