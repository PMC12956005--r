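#' @include AllClasses.R topology.R structure-utils.R hydrogens.R
NULL

# Donor heavy atoms (atom-row indices). In strict mode a donor counts only
# when a hydrogen is attached (checked by the caller); in heavy mode the
# chemistry table alone decides, except histidine ring nitrogens and
# hetero atoms, which only donate with an explicit hydrogen.
.donorIndices <- function(at, config) {
  water <- at$resname %in% config@waterResnames
  protein <- !at$is_hetero & !water
  idx <- logical(nrow(at))
  idx[protein & at$name == "N" & at$resname != "PRO"] <- TRUE
  for (rn in names(.SC_DONORS))
    idx[protein & at$resname == rn & at$name %in% .SC_DONORS[[rn]]] <- TRUE
  idx[water & at$element == "O"] <- TRUE
  idx[at$is_hetero & !water & at$element %in% c("N", "O")] <- TRUE
  which(idx)
}

# Requires an attached hydrogen even in heavy mode (protonation-dependent
# donors).
.conditionalDonor <- function(at, i) {
  (at$resname[i] == "HIS" & at$name[i] %in% c("ND1", "NE2")) | at$is_hetero[i]
}

# Map each heavy atom index to the indices of hydrogens within 1.25 A in
# the same residue.
.attachedHydrogens <- function(at, heavy_idx) {
  h_idx <- which(at$element == "H")
  out <- vector("list", length(heavy_idx))
  if (!length(h_idx)) return(out)
  keys <- .atomKeys(at)
  hxyz <- as.matrix(at[h_idx, c("x", "y", "z"), drop = FALSE])
  for (k in seq_along(heavy_idx)) {
    i <- heavy_idx[k]
    same <- h_idx[keys[h_idx] == keys[i]]
    if (!length(same)) next
    d <- crossDist(as.matrix(at[i, c("x", "y", "z"), drop = FALSE]),
                   as.matrix(at[same, c("x", "y", "z"), drop = FALSE]))
    out[[k]] <- same[d[1L, ] <= 1.25]
  }
  out
}

# Cell-list neighbour search: for each query point, candidate target
# indices within `cut` (superset; exact distances filtered by caller).
.cellNeighbours <- function(qxyz, txyz, cut) {
  cell <- function(m) floor(m / cut)
  tc <- cell(txyz)
  tkey <- paste(tc[, 1L], tc[, 2L], tc[, 3L])
  buckets <- split(seq_len(nrow(txyz)), tkey)
  qc <- cell(qxyz)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(nrow(qxyz)), function(i) {
    ks <- paste(qc[i, 1L] + offs[, 1L], qc[i, 2L] + offs[, 2L],
                qc[i, 3L] + offs[, 3L])
    unlist(buckets[ks], use.names = FALSE)
  })
}

.emptyHBonds <- function() {
  data.frame(donor_idx = integer(0), hydrogen_idx = integer(0),
             acceptor_idx = integer(0),
             donor_key = character(0), donor_resname = character(0),
             donor_atom = character(0), donor_chain = character(0),
             acceptor_key = character(0), acceptor_resname = character(0),
             acceptor_atom = character(0), acceptor_chain = character(0),
             donor_is_water = logical(0), acceptor_is_water = logical(0),
             distance = numeric(0), angle = numeric(0),
             stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds under geometric criteria
#'
#' Enumerates donor/acceptor pairs satisfying the heavy-atom
#' donor--acceptor distance cutoff (default 3.5 Angstrom, inclusive) and,
#' in `strict` mode, a donor-H...acceptor angle at the hydrogen of at
#' least the angle cutoff (default 150 degrees, inclusive). Donor and
#' acceptor chemistry comes from a residue-topology table (backbone amide
#' N and carbonyl O, polar side-chain N/O/S, water O, ligand N/O).
#' In strict mode each qualifying donor-hydrogen-acceptor triple is one
#' row; in `heavy` mode angles are not evaluated (for structures without
#' hydrogens) and each donor-acceptor pair is one row. Neighbour search
#' uses spatial binning but the result equals exhaustive enumeration.
#'
#' @param structure a [PDBStructure-class].
#' @param config an [AnalysisConfig-class].
#' @return data.frame with one row per bond: atom indices, residue keys,
#'   atom names, chain ids, water flags, `distance` (Angstrom) and
#'   `angle` (degrees; `NA` in heavy mode).
#' @examples
#' fx <- plantWaterBridges(makeTwoChainScaffold(8), k = 2, nDecoys = 0)
#' nrow(findHBonds(fx$structure))
#' @export
findHBonds <- function(structure, config = analysisConfig()) {
  at <- atoms(structure)
  if (!nrow(at)) return(.emptyHBonds())
  strict <- config@hbondMode == "strict"
  if (strict && !any(at$element == "H"))
    stop(paste("strict H-bond mode but the structure contains no hydrogens;",
               "run addPolarHydrogens() or use hbondMode = 'heavy'"),
         call. = FALSE)

  don <- .donorIndices(at, config)
  acc <- .acceptorIndices(at, config)
  if (!length(don) || !length(acc)) return(.emptyHBonds())

  hyd <- .attachedHydrogens(at, don)
  has_h <- lengths(hyd) > 0L
  cond <- .conditionalDonor(at, don)
  keep <- if (strict) has_h else (has_h | !cond)
  don <- don[keep]
  hyd <- hyd[keep]
  if (!length(don)) return(.emptyHBonds())

  keys <- .atomKeys(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  nb <- .cellNeighbours(xyz[don, , drop = FALSE], xyz[acc, , drop = FALSE],
                        config@dCut)

  rows <- list()
  for (k in seq_along(don)) {
    i <- don[k]
    cand <- acc[nb[[k]]]
    cand <- cand[cand != i]
    if (!length(cand)) next
    d <- crossDist(xyz[i, , drop = FALSE], xyz[cand, , drop = FALSE])[1L, ]
    ok <- d <= config@dCut & d >= 2.0  # lower bound excludes covalent pairs
    cand <- cand[ok]
    d <- d[ok]
    if (!length(cand)) next
    for (m in seq_along(cand)) {
      j <- cand[m]
      if (strict) {
        for (h in hyd[[k]]) {
          ang <- pointAngle(xyz[i, ], xyz[h, ], xyz[j, ])
          if (ang >= config@thetaCut)
            rows[[length(rows) + 1L]] <-
              list(i = i, h = h, j = j, d = d[m], a = ang)
        }
      } else {
        rows[[length(rows) + 1L]] <-
          list(i = i, h = NA_integer_, j = j, d = d[m], a = NA_real_)
      }
    }
  }
  if (!length(rows)) return(.emptyHBonds())
  di <- vapply(rows, `[[`, numeric(1), "i")
  hi <- vapply(rows, function(r) as.integer(r$h), integer(1))
  ai <- vapply(rows, `[[`, numeric(1), "j")
  water <- at$resname %in% config@waterResnames
  out <- data.frame(
    donor_idx = as.integer(di), hydrogen_idx = hi,
    acceptor_idx = as.integer(ai),
    donor_key = keys[di], donor_resname = at$resname[di],
    donor_atom = at$name[di], donor_chain = at$chain[di],
    acceptor_key = keys[ai], acceptor_resname = at$resname[ai],
    acceptor_atom = at$name[ai], acceptor_chain = at$chain[ai],
    donor_is_water = water[di], acceptor_is_water = water[ai],
    distance = vapply(rows, `[[`, numeric(1), "d"),
    angle = vapply(rows, `[[`, numeric(1), "a"),
    stringsAsFactors = FALSE)
  ord <- order(out$donor_idx, out$acceptor_idx, out$hydrogen_idx,
               na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate water-mediated interchain bridges
#'
#' A bridge is a single water simultaneously hydrogen-bonded (under the
#' configured criteria) to a protein atom of each of the two chains.
#' Ligand atoms are never bridge endpoints, and only first-order bridges
#' (one water, no water-water chains) count. One row is returned per
#' (water, chain-A partner, chain-B partner) combination; deduplicate by
#' water with [countBridges()].
#'
#' @param structure a [PDBStructure-class].
#' @param chainA,chainB the two protomer chain ids (must differ).
#' @param config an [AnalysisConfig-class].
#' @param hbonds optional precomputed result of [findHBonds()] on
#'   `structure` under the same `config`.
#' @return data.frame with columns `water`, `a_key`, `a_atom`, `b_key`,
#'   `b_atom`.
#' @export
findWaterBridges <- function(structure, chainA = "A", chainB = "B",
                             config = analysisConfig(), hbonds = NULL) {
  if (identical(chainA, chainB))
    stop("chainA and chainB must differ", call. = FALSE)
  hb <- if (is.null(hbonds)) findHBonds(structure, config) else hbonds
  empty <- data.frame(water = character(0), a_key = character(0),
                      a_atom = character(0), b_key = character(0),
                      b_atom = character(0), stringsAsFactors = FALSE)
  if (!nrow(hb)) return(empty)

  at <- atoms(structure)
  protein <- !at$is_hetero & !(at$resname %in% config@waterResnames) &
    !(at$resname %in% config@ligandResnames)

  # water-protein bonds only, partner on one of the two chains
  wp <- hb[xor(hb$donor_is_water, hb$acceptor_is_water), , drop = FALSE]
  if (!nrow(wp)) return(empty)
  water_key <- ifelse(wp$donor_is_water, wp$donor_key, wp$acceptor_key)
  part_idx <- ifelse(wp$donor_is_water, wp$acceptor_idx, wp$donor_idx)
  ok <- protein[part_idx] & at$chain[part_idx] %in% c(chainA, chainB)
  wp <- wp[ok, , drop = FALSE]
  water_key <- water_key[ok]
  part_idx <- part_idx[ok]
  if (!nrow(wp)) return(empty)

  rows <- list()
  for (w in unique(water_key)) {
    sel <- water_key == w
    pa <- unique(part_idx[sel & at$chain[part_idx] == chainA])
    pb <- unique(part_idx[sel & at$chain[part_idx] == chainB])
    if (!length(pa) || !length(pb)) next
    keys <- .atomKeys(at)
    for (ia in sort(pa)) for (ib in sort(pb))
      rows[[length(rows) + 1L]] <- data.frame(
        water = w, a_key = keys[ia], a_atom = at$name[ia],
        b_key = keys[ib], b_atom = at$name[ib], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count water bridges
#'
#' @param bridges result of [findWaterBridges()].
#' @param metric `"waters"` counts distinct bridging waters; `"pairs"`
#'   counts (water, partner A, partner B) combinations.
#' @return integer count.
#' @export
countBridges <- function(bridges, metric = c("waters", "pairs")) {
  metric <- match.arg(metric)
  if (metric == "waters") length(unique(bridges$water)) else nrow(bridges)
}

#' Canonical bond signatures for network comparison
#'
#' Hydrogen bonds are keyed by donor and acceptor residue + atom names;
#' water residue keys are canonicalised to `"WAT"` so that differently
#' numbered (or relocated) waters with the same protein partners compare
#' equal. Bridges are keyed by their two protein partners.
#'
#' @param hbonds result of [findHBonds()] (may be `NULL`).
#' @param bridges result of [findWaterBridges()] (may be `NULL`).
#' @return character vector of unique signatures.
#' @export
hbondSignatures <- function(hbonds = NULL, bridges = NULL) {
  sig <- character(0)
  if (!is.null(hbonds) && nrow(hbonds)) {
    dk <- ifelse(hbonds$donor_is_water, "WAT",
                 paste0(hbonds$donor_key, "/", hbonds$donor_resname, "/",
                        hbonds$donor_atom))
    ak <- ifelse(hbonds$acceptor_is_water, "WAT",
                 paste0(hbonds$acceptor_key, "/", hbonds$acceptor_resname,
                        "/", hbonds$acceptor_atom))
    sig <- c(sig, paste0(dk, ">", ak))
  }
  if (!is.null(bridges) && nrow(bridges)) {
    sig <- c(sig, paste0("bridge:", bridges$a_key, "/", bridges$a_atom,
                         "~", bridges$b_key, "/", bridges$b_atom))
  }
  sort(unique(sig))
}

#' Compare two hydrogen-bond networks
#'
#' Set difference over canonical signatures ([hbondSignatures()]):
#' bonds conserved in both structures, gained by the variant, and lost by
#' the variant. Both inputs must have been computed under the same
#' configuration.
#'
#' @param wtSignatures,mutSignatures character signature sets, or the
#'   data.frames returned by [findHBonds()] (converted automatically).
#' @return list with character elements `conserved`, `added`, `removed`
#'   (pairwise disjoint).
#' @export
diffHBonds <- function(wtSignatures, mutSignatures) {
  norm <- function(x) {
    if (is.data.frame(x)) hbondSignatures(hbonds = x) else sort(unique(x))
  }
  wt <- norm(wtSignatures)
  mut <- norm(mutSignatures)
  list(conserved = intersect(wt, mut),
       added = setdiff(mut, wt),
       removed = setdiff(wt, mut))
}
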