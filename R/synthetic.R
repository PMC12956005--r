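#' @include AllClasses.R structure-utils.R hydrogens.R hbonds.R enm.R
NULL

# Ideal peptide geometry used by the scaffold builder.
.PEP <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
             a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
             a_ca_c_o = 120.5)

# Build one extended (phi = psi = omega = 180) poly-ALA strand of n
# residues starting near the origin; returns a list of per-residue named
# position lists.
.buildStrand <- function(n) {
  phi <- 180; psi <- 180; omega <- 180
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(.PEP$b_n_ca, 0, 0)
  ang <- (180 - .PEP$a_n_ca_c) * .deg2rad
  C <- CA + .PEP$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    Nn <- placeAtom(N, CA, C, .PEP$b_c_n, .PEP$a_ca_c_n, psi)
    O <- placeAtom(N, CA, C, .PEP$b_c_o, .PEP$a_ca_c_o, psi + 180)
    CB <- placeAtom(C, N, CA, .CB_SPEC$len, .CB_SPEC$ang, .CB_SPEC$tors)
    res[[i]] <- list(N = N, CA = CA, C = C, O = O, CB = CB)
    if (i < n) {
      CAn <- placeAtom(CA, C, Nn, .PEP$b_n_ca, .PEP$a_c_n_ca, omega)
      Cn <- placeAtom(C, Nn, CAn, .PEP$b_ca_c, .PEP$a_n_ca_c, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  res
}

.strandAtoms <- function(res_list, chain, resseq0 = 1L) {
  rows <- list()
  for (i in seq_along(res_list)) {
    for (nm in names(res_list[[i]])) {
      p <- res_list[[i]][[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        serial = 0L, name = nm, element = substr(nm, 1, 1), altloc = "",
        resname = "ALA", chain = chain, resseq = resseq0 + i - 1L,
        icode = "", x = p[1L], y = p[2L], z = p[3L], occupancy = 1,
        bfactor = 0, is_hetero = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Two-chain poly-alanine scaffold
#'
#' Deterministic test scaffold: two ideal-geometry extended poly-ALA
#' strands on parallel axes (chains A and B, B rotated 180 degrees about
#' the chain axis so its carbonyl oxygens face chain A), with backbone
#' amide hydrogens added. The geometry is exactly reproducible: the seed
#' is recorded but introduces no randomness here; it exists so fixture
#' provenance is uniform across generators.
#'
#' @param nRes residues per chain (>= 2).
#' @param separation distance between the strand axes, Angstrom (> 0).
#'   The default 7.2 puts facing carbonyl oxygens about 4.4 Angstrom
#'   apart, the ideal apex geometry for a bridging water.
#' @param seed recorded seed.
#' @return a [PDBStructure-class].
#' @examples
#' makeTwoChainScaffold(nRes = 10)
#' @export
makeTwoChainScaffold <- function(nRes = 10, separation = 7.2, seed = 1) {
  if (nRes < 2) stop("nRes must be >= 2", call. = FALSE)
  if (separation <= 0) stop("separation must be > 0", call. = FALSE)
  strand <- .buildStrand(nRes)
  atA <- .strandAtoms(strand, "A")
  # align the strand axis with +x, using two Calpha atoms on the same
  # zigzag phase so the axis is the true propagation direction
  ca <- atA[atA$name == "CA", c("x", "y", "z")]
  last_odd <- if (nrow(ca) %% 2L == 1L) nrow(ca) else nrow(ca) - 1L
  if (last_odd == 1L) last_odd <- nrow(ca)
  axis_dir <- unitv(as.numeric(ca[last_odd, ] - ca[1L, ]))
  rot_ax <- vcross(axis_dir, c(1, 0, 0))
  if (vnorm(rot_ax) > 1e-9) {
    ang <- acos(max(-1, min(1, axis_dir[1L]))) * .rad2deg
    xyzA <- rotateAboutAxis(as.matrix(atA[, c("x", "y", "z")]),
                            rot_ax, ang)
    atA$x <- xyzA[, 1L]; atA$y <- xyzA[, 2L]; atA$z <- xyzA[, 3L]
  }
  atB <- atA
  atB$chain <- "B"
  xyz <- as.matrix(atB[, c("x", "y", "z")])
  xyz <- rotateAboutAxis(xyz, c(1, 0, 0), 180)
  xyz[, 2L] <- xyz[, 2L] + separation
  atB$x <- xyz[, 1L]; atB$y <- xyz[, 2L]; atB$z <- xyz[, 3L]
  at <- rbind(atA, atB)
  at$serial <- seq_len(nrow(at))
  s <- new("PDBStructure", modelId = 1L, atoms = at,
           title = sprintf("synthetic two-chain poly-ALA scaffold (seed %d)",
                           as.integer(seed)))
  validObject(s)
  addPolarHydrogens(s)
}

# --- water placement helpers -------------------------------------------

.WATER_GEOM <- list(oh = 0.957, hoh = 104.5)

# Rigid water at the apex of an isosceles triangle over acceptors A and B:
# |O-A| = |O-B| = r, O displaced along `sign` * z from the A-B midpoint;
# hydrogens split symmetrically in the (O, A, B) plane.
.placeBridgeWater <- function(pA, pB, r, sign = 1) {
  mid <- (pA + pB) / 2
  d <- vnorm(pB - pA)
  if (d >= 2 * r) return(NULL)
  h <- sqrt(r^2 - (d / 2)^2)
  ab <- unitv(pB - pA)
  zc <- c(0, 0, sign)
  u <- zc - sum(zc * ab) * ab
  if (vnorm(u) < 1e-8) return(NULL)
  O <- mid + h * unitv(u)
  ua <- unitv(pA - O)
  ub <- unitv(pB - O)
  bis <- unitv(ua + ub)
  axis <- unitv(vcross(ua, ub))
  half <- .WATER_GEOM$hoh / 2
  h1 <- O + .WATER_GEOM$oh * as.numeric(
    rotateAboutAxis(matrix(bis, 1L), axis, half))
  h2 <- O + .WATER_GEOM$oh * as.numeric(
    rotateAboutAxis(matrix(bis, 1L), axis, -half))
  list(O = O, H1 = h1, H2 = h2, bis = bis)
}

.waterRows <- function(w, resseq, chain = "W") {
  rows <- lapply(c("O", "H1", "H2"), function(nm) data.frame(
    serial = 0L, name = nm, element = substr(nm, 1, 1), altloc = "",
    resname = "HOH", chain = chain, resseq = as.integer(resseq), icode = "",
    x = w[[nm]][1L], y = w[[nm]][2L], z = w[[nm]][3L],
    occupancy = 1, bfactor = 0, is_hetero = TRUE, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Direct geometric measurement (no spatial binning, no detector code
# path): does this water hydrogen-bond to the given polar atoms under
# (dCut, thetaCut)? Returns the indices of atoms bonded to the water.
.waterPartnersDirect <- function(w, polar_xyz, polar_is_donor, donor_h_xyz,
                                 dCut, thetaCut) {
  hit <- logical(nrow(polar_xyz))
  for (i in seq_len(nrow(polar_xyz))) {
    p <- polar_xyz[i, ]
    d <- vnorm(p - w$O)
    if (d > dCut || d < 2.0) next
    ok <- FALSE
    for (hp in list(w$H1, w$H2)) {
      if (pointAngle(w$O, hp, p) >= thetaCut) { ok <- TRUE; break }
    }
    if (!ok && polar_is_donor[i]) {
      hs <- donor_h_xyz[[i]]
      if (!is.null(hs)) for (r in seq_len(nrow(hs))) {
        if (pointAngle(p, hs[r, ], w$O) >= thetaCut) { ok <- TRUE; break }
      }
    }
    hit[i] <- ok
  }
  which(hit)
}

#' Plant ground-truth water bridges (and decoys) into a scaffold
#'
#' Places `k` waters that bridge chains A and B by construction: each
#' water donates to one backbone carbonyl oxygen of each chain with
#' O...O distance 2.8 Angstrom and donor-H...acceptor angles of at least
#' 165 degrees, comfortably inside the strict criteria (margins of at
#' least 0.2 Angstrom / 15 degrees keep floating-point noise from
#' flipping the ground truth). `nDecoys` additional waters each violate
#' exactly one criterion: distance decoys sit 3.8 Angstrom from both
#' partners (and at least 3.7 from every other polar atom), angle decoys
#' sit at bridging distance but rotated so no donor-H...acceptor angle
#' exceeds 140 degrees. Every placement is re-verified by direct
#' geometric measurement before the fixture is returned; an unverifiable
#' placement is a construction error, never a silently wrong truth.
#'
#' @param scaffold a two-chain structure from [makeTwoChainScaffold()].
#'   Larger `nRes` gives more eligible sites (roughly one per facing
#'   carbonyl pair, two water slots each).
#' @param k number of true bridges.
#' @param nDecoys number of decoys (alternating distance/angle type).
#' @param seed seed for the site assignment.
#' @param dPlant planted O...O distance (<= 3.3).
#' @param dDecoy distance-decoy O...O distance (>= 3.7).
#' @return a `BridgeFixture` list: `structure`, `trueBridgeWaters`,
#'   `truePairCount`, `decoyWaters`, `seed`.
#' @export
plantWaterBridges <- function(scaffold, k, nDecoys = 0, seed = 1,
                              dPlant = 2.8, dDecoy = 3.8) {
  stopifnot(dPlant <= 3.3, dDecoy >= 3.7)
  at <- atoms(scaffold)
  oA <- which(at$chain == "A" & at$name == "O" & !at$is_hetero)
  oB <- which(at$chain == "B" & at$name == "O" & !at$is_hetero)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- crossDist(xyz[oA, , drop = FALSE], xyz[oB, , drop = FALSE])
  cand <- which(d >= 3.9 & d <= 4.9, arr.ind = TRUE)
  # one site per chain-A oxygen, nearest facing partner
  cand <- cand[!duplicated(cand[, 1L]), , drop = FALSE]
  sites <- data.frame(ia = oA[cand[, 1L]], ib = oB[cand[, 2L]])
  slots <- merge(sites, data.frame(sign = c(1, -1)))
  n_slots <- nrow(slots)
  if (k > n_slots)
    stop(sprintf("insufficient eligible sites: maximum k is %d for this scaffold",
                 n_slots), call. = FALSE)
  if (k + nDecoys > n_slots)
    stop(sprintf(
      "insufficient eligible sites for %d waters (%d slots); enlarge the scaffold",
      k + nDecoys, n_slots), call. = FALSE)

  ord <- .withSeed(seed, sample.int(n_slots))
  slots <- slots[ord, , drop = FALSE]

  # polar atoms of the protein used for verification
  polar <- which(!at$is_hetero & at$name %in% c("O", "N"))
  polar_xyz <- xyz[polar, , drop = FALSE]
  polar_is_donor <- at$name[polar] == "N"
  keys <- .atomKeys(at)
  donor_h_xyz <- lapply(seq_along(polar), function(i) {
    if (!polar_is_donor[i]) return(NULL)
    same <- which(keys == keys[polar[i]] & at$element == "H")
    if (!length(same)) return(NULL)
    xyz[same, , drop = FALSE]
  })

  waters <- list()
  true_keys <- character(0)
  decoy_keys <- character(0)
  true_pairs <- 0L
  resseq <- 0L
  slot_i <- 0L
  next_slot <- function() {
    slot_i <<- slot_i + 1L
    if (slot_i > n_slots)
      stop("fixture construction exhausted eligible slots", call. = FALSE)
    slots[slot_i, ]
  }

  for (t in seq_len(k)) {
    repeat {
      sl <- next_slot()
      w <- .placeBridgeWater(xyz[sl$ia, ], xyz[sl$ib, ], dPlant, sl$sign)
      if (is.null(w)) next
      aA <- max(pointAngle(w$O, w$H1, xyz[sl$ia, ]),
                pointAngle(w$O, w$H2, xyz[sl$ia, ]))
      aB <- max(pointAngle(w$O, w$H1, xyz[sl$ib, ]),
                pointAngle(w$O, w$H2, xyz[sl$ib, ]))
      if (min(aA, aB) < 165) next
      partners <- .waterPartnersDirect(w, polar_xyz, polar_is_donor,
                                       donor_h_xyz, 3.5, 150)
      pk <- polar[partners]
      nA <- sum(at$chain[pk] == "A")
      nB <- sum(at$chain[pk] == "B")
      if (nA < 1L || nB < 1L)
        stop("planted water failed direct re-verification", call. = FALSE)
      resseq <- resseq + 1L
      waters[[length(waters) + 1L]] <- .waterRows(w, resseq)
      true_keys <- c(true_keys, residueKey("W", resseq))
      true_pairs <- true_pairs + nA * nB
      break
    }
  }

  decoy_type <- rep(c("distance", "angle"), length.out = nDecoys)
  for (t in seq_len(nDecoys)) {
    placed <- FALSE
    while (!placed) {
      sl <- next_slot()
      if (decoy_type[t] == "distance") {
        w <- .placeBridgeWater(xyz[sl$ia, ], xyz[sl$ib, ], dDecoy, sl$sign)
        if (is.null(w)) next
        dmin <- min(crossDist(matrix(w$O, 1L), polar_xyz))
        if (dmin < 3.7) next
      } else {
        w <- .placeBridgeWater(xyz[sl$ia, ], xyz[sl$ib, ], dPlant, sl$sign)
        if (is.null(w)) next
        ax <- unitv(w$bis)
        rot <- function(p) w$O + as.numeric(
          rotateAboutAxis(matrix(p - w$O, 1L), ax, 90))
        w$H1 <- rot(w$H1); w$H2 <- rot(w$H2)
        # must fail the angle criterion (with margin) against every
        # nearby polar atom, as donor and as acceptor
        near <- which(crossDist(matrix(w$O, 1L), polar_xyz)[1L, ] <= 3.5)
        bad <- FALSE
        for (i in near) {
          p <- polar_xyz[i, ]
          if (pointAngle(w$O, w$H1, p) > 140 ||
              pointAngle(w$O, w$H2, p) > 140) { bad <- TRUE; break }
          if (polar_is_donor[i] && !is.null(donor_h_xyz[[i]])) {
            hs <- donor_h_xyz[[i]]
            for (r in seq_len(nrow(hs)))
              if (pointAngle(p, hs[r, ], w$O) > 140) { bad <- TRUE; break }
            if (bad) break
          }
        }
        if (bad) next
      }
      partners <- .waterPartnersDirect(w, polar_xyz, polar_is_donor,
                                       donor_h_xyz, 3.5, 150)
      pk <- polar[partners]
      if (sum(at$chain[pk] == "A") >= 1L && sum(at$chain[pk] == "B") >= 1L)
        stop("decoy water failed direct re-verification", call. = FALSE)
      resseq <- resseq + 1L
      waters[[length(waters) + 1L]] <- .waterRows(w, resseq)
      decoy_keys <- c(decoy_keys, residueKey("W", resseq))
      placed <- TRUE
    }
  }

  out_at <- rbind(at, if (length(waters)) do.call(rbind, waters))
  out_at$serial <- seq_len(nrow(out_at))
  rownames(out_at) <- NULL
  s <- new("PDBStructure", modelId = scaffold@modelId, atoms = out_at,
           title = scaffold@title)
  validObject(s)
  fx <- list(structure = s, trueBridgeWaters = true_keys,
             truePairCount = as.integer(true_pairs),
             decoyWaters = decoy_keys, seed = as.integer(seed))
  class(fx) <- "BridgeFixture"
  fx
}

#' Matched wild-type/variant fixture for the stability proxy
#'
#' The wild type is a plain two-chain scaffold; the "variant" shares its
#' backbone exactly, carries `bridgeDelta` additional planted interchain
#' water bridges (removed from the variant when negative), and its
#' elastic network differs by the listed spring-constant factors. The
#' pair exercises the stability proxy with known ground truth: stiffened
#' springs plus gained bridges must score stabilizing, softened springs
#' without bond gain destabilizing.
#'
#' @param nRes residues per chain.
#' @param springEdits data.frame with `key_i`, `key_j`, `factor`
#'   (residue keys of node pairs within the network cutoff).
#' @param bridgeDelta bridges planted into the variant (negative: into
#'   the wild type).
#' @param seed fixture seed.
#' @param cutoff,gamma network parameters for the prebuilt models.
#' @return an `EnmFixturePair` list: `wt`, `mut` (structures), `enmWt`,
#'   `enmMut`, `springEdits`, `bridgeDelta`, `seed`.
#' @export
makeEnmFixturePair <- function(nRes = 12, springEdits = NULL,
                               bridgeDelta = 0, seed = 1,
                               cutoff = 13, gamma = 1) {
  base <- makeTwoChainScaffold(nRes, seed = seed)
  wt <- base
  mut <- base
  if (bridgeDelta > 0) {
    mut <- plantWaterBridges(base, k = bridgeDelta, nDecoys = 0,
                             seed = seed)$structure
  } else if (bridgeDelta < 0) {
    wt <- plantWaterBridges(base, k = -bridgeDelta, nDecoys = 0,
                            seed = seed)$structure
  }
  enmWt <- buildENM(wt, cutoff, gamma)
  enmMut <- buildENM(mut, cutoff, gamma, springEdits = springEdits)
  fx <- list(wt = wt, mut = mut, enmWt = enmWt, enmMut = enmMut,
             springEdits = springEdits, bridgeDelta = as.integer(bridgeDelta),
             seed = as.integer(seed))
  class(fx) <- "EnmFixturePair"
  fx
}

#' Pseudo-trajectory with planted per-frame bridge counts
#'
#' Builds a multi-model PDB trajectory over a fixed scaffold in which
#' frame i contains exactly `counts[i]` valid interchain water bridges
#' (plus constant decoys). Topology is identical across frames: waters
#' whose bridge is absent in a frame are displaced far along z rather
#' than deleted, so per-frame analyses see one consistent atom set.
#'
#' @param counts non-negative integer bridge count per frame.
#' @param seed fixture seed.
#' @param nRes scaffold size per chain.
#' @param nDecoys decoys present in every frame.
#' @param saveInterval frame spacing in ns used for labelling.
#' @return list with `text` (multi-model PDB), `frames` (list of
#'   [PDBStructure-class]), `counts` (the planted truth), `seed`.
#' @export
makePseudoTrajectory <- function(counts, seed = 1, nRes = 30, nDecoys = 5,
                                 saveInterval = 2) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  kmax <- max(counts, 1L)
  scaffold <- makeTwoChainScaffold(nRes, seed = seed)
  fx <- plantWaterBridges(scaffold, k = kmax, nDecoys = nDecoys, seed = seed)
  base_at <- atoms(fx$structure)
  keys <- .atomKeys(base_at)
  frames <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    at <- base_at
    if (counts[i] < kmax) {
      off <- fx$trueBridgeWaters[seq((counts[i] + 1L), kmax)]
      sel <- keys %in% off
      at$z[sel] <- at$z[sel] + 50
    }
    s <- new("PDBStructure", modelId = i, atoms = at, title = scaffold@title)
    frames[[i]] <- s
  }
  list(text = writePDB(frames), frames = frames, counts = counts,
       seed = as.integer(seed), saveInterval = saveInterval)
}
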