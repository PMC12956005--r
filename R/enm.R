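#' @include AllClasses.R structure-utils.R
NULL

# Boltzmann constant, kcal/(mol K); entropies are reported in cal/(mol K).
.KB_KCAL <- 0.0019872041

#' Build an anisotropic elastic network from Calpha atoms
#'
#' Nodes are the Calpha atoms of all protein residues (waters, ligands and
#' other hetero residues excluded); both chains of a dimer enter one
#' network. For each node pair within the cutoff the Hessian off-diagonal
#' 3x3 super-block is `-gamma / |r_ij|^2 * r_ij r_ij^T`; diagonal
#' super-blocks are the negated sums of their row, so uniform translations
#' are annihilated exactly. Node masses are uniform (they cancel in every
#' difference the package reports).
#'
#' @param structure a [PDBStructure-class].
#' @param cutoff spring cutoff R_c, Angstrom (default 13).
#' @param gamma uniform spring constant, kcal/mol/Angstrom^2 (default 1).
#' @param springEdits optional data.frame with columns `key_i`, `key_j`,
#'   `factor`: multiply the spring between the two residues by `factor`
#'   (used by the fixture generators to stiffen or soften local springs).
#' @param config an [AnalysisConfig-class] (water/ligand residue names).
#' @return an [ElasticNetworkModel-class]. A network that is disconnected
#'   at the given cutoff is recorded in the model's `warnings` slot (extra
#'   zero modes are then expected).
#' @examples
#' enm <- buildENM(makeTwoChainScaffold(6), cutoff = 13)
#' enm
#' @export
buildENM <- function(structure, cutoff = 13, gamma = 1, springEdits = NULL,
                     config = analysisConfig()) {
  at <- atoms(structure)
  sel <- which(!at$is_hetero & at$name == "CA" &
                 !(at$resname %in% config@waterResnames) &
                 !(at$resname %in% config@ligandResnames))
  if (length(sel) < 2L)
    stop("need at least two Calpha atoms to build an elastic network",
         call. = FALSE)
  xyz <- as.matrix(at[sel, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  keys <- .atomKeys(at)[sel]
  n <- nrow(xyz)

  d <- crossDist(xyz, xyz)
  adj <- d <= cutoff & upper.tri(d)
  pairs <- which(adj, arr.ind = TRUE)

  gmat <- matrix(0, n, n)
  gmat[pairs] <- gamma
  if (!is.null(springEdits) && nrow(springEdits)) {
    for (r in seq_len(nrow(springEdits))) {
      i <- match(springEdits$key_i[r], keys)
      j <- match(springEdits$key_j[r], keys)
      if (is.na(i) || is.na(j))
        stop("spring edit references absent node(s): ",
             springEdits$key_i[r], " / ", springEdits$key_j[r],
             call. = FALSE)
      ii <- min(i, j); jj <- max(i, j)
      if (gmat[cbind(ii, jj)] == 0)
        stop(sprintf("spring edit %s-%s outside the cutoff %g",
                     keys[ii], keys[jj], cutoff), call. = FALSE)
      gmat[ii, jj] <- gmat[ii, jj] * springEdits$factor[r]
    }
  }

  H <- matrix(0, 3L * n, 3L * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    g <- gmat[i, j]
    if (g == 0) next
    rij <- xyz[j, ] - xyz[i, ]
    blk <- -(g / sum(rij * rij)) * tcrossprod(rij)
    ri <- (3L * (i - 1L) + 1L):(3L * i)
    rj <- (3L * (j - 1L) + 1L):(3L * j)
    H[ri, rj] <- H[ri, rj] + blk
    H[rj, ri] <- H[rj, ri] + blk
    H[ri, ri] <- H[ri, ri] - blk
    H[rj, rj] <- H[rj, rj] - blk
  }

  warnings <- character(0)
  # connectivity check by breadth-first search over the spring graph
  nbr <- lapply(seq_len(n), function(i)
    unique(c(pairs[pairs[, 1L] == i, 2L], pairs[pairs[, 2L] == i, 1L])))
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in nbr[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  if (!all(seen))
    warnings <- c(warnings,
                  sprintf("network disconnected at cutoff %g (%d of %d nodes reached); extra zero modes expected",
                          cutoff, sum(seen), n))

  new("ElasticNetworkModel", nodes = xyz, keys = keys, cutoff = cutoff,
      gamma = gamma, hessian = H, warnings = warnings)
}

#' Normal modes of an elastic network
#'
#' Full symmetric eigendecomposition of the Hessian; eigenvalues ascending
#' with orthonormal eigenvectors. For a non-collinear connected network
#' exactly six near-zero rigid-body modes are expected.
#'
#' @param enm an [ElasticNetworkModel-class].
#' @param zeroTol relative tolerance classifying near-zero modes
#'   (eigenvalue below `zeroTol * max(eigenvalue)`).
#' @return a [ModeSpectrum-class].
#' @export
normalModes <- function(enm, zeroTol = 1e-10) {
  H <- enm@hessian
  if (max(abs(H - t(H))) > 1e-8)
    stop("internal inconsistency: Hessian is not symmetric", call. = FALSE)
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  lam_max <- max(abs(vals))
  nz <- sum(abs(vals) < zeroTol * lam_max)
  new("ModeSpectrum", values = vals, vectors = vecs, nZero = as.integer(nz))
}

#' Classical vibrational entropy of a mode spectrum
#'
#' Harmonic-oscillator entropy over the non-zero modes,
#' `S_vib = (k_B / 2) * sum_i log(k_B T / lambda_i)`, in cal/(mol K).
#' The additive constant of the classical form is dropped; it cancels in
#' every reported difference, which is the only way the quantity is used.
#'
#' @param spectrum a [ModeSpectrum-class].
#' @param temperature K (default 300).
#' @return list with `sVib` (cal/(mol K)), `temperature`, `nModesUsed`.
#' @export
vibrationalEntropy <- function(spectrum, temperature = 300) {
  vals <- spectrum@values
  nz <- spectrum@nZero
  lam <- vals[(nz + 1L):length(vals)]
  if (nz >= length(vals) || !length(lam) || all(lam <= 0))
    stop("degenerate network: no non-zero modes", call. = FALSE)
  s <- (.KB_KCAL / 2) * sum(log(.KB_KCAL * temperature / lam)) * 1000
  list(sVib = s, temperature = temperature, nModesUsed = length(lam))
}
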