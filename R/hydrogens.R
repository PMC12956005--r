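#' @include AllClasses.R topology.R structure-utils.R
NULL

# Acceptor heavy atoms of the whole structure (used to orient hydroxyl
# hydrogens and by the H-bond detector). Returns atom-row indices.
.acceptorIndices <- function(at, config) {
  water <- at$resname %in% config@waterResnames
  idx <- logical(nrow(at))
  # backbone carbonyl / terminal oxygens of protein residues
  protein <- !at$is_hetero & !water
  idx[protein & at$name %in% c("O", "OXT")] <- TRUE
  for (rn in names(.SC_ACCEPTORS))
    idx[protein & at$resname == rn & at$name %in% .SC_ACCEPTORS[[rn]]] <- TRUE
  # water oxygen
  idx[water & at$element == "O"] <- TRUE
  # hetero/ligand N and O accept
  idx[at$is_hetero & !water & at$element %in% c("N", "O")] <- TRUE
  # a protonated His nitrogen no longer accepts
  if (any(idx)) {
    his <- which(idx & at$resname == "HIS")
    if (length(his)) {
      hxyz <- as.matrix(at[at$element == "H", c("x", "y", "z"), drop = FALSE])
      if (nrow(hxyz)) {
        d <- crossDist(as.matrix(at[his, c("x", "y", "z"), drop = FALSE]), hxyz)
        idx[his[apply(d, 1L, min) < 1.25]] <- FALSE
      }
    }
  }
  which(idx)
}

# Orient an O-H (or S-H) on its rotation cone as close as possible to the
# target direction: H-bond geometry by cone projection.
.hydroxylH <- function(p_parent, p_sup, target, len, bond_angle = 109.0) {
  a <- unitv(p_parent - p_sup)
  # pick perpendicular frame
  ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(vcross(a, ref))
  e2 <- vcross(a, e1)
  half <- (180 - bond_angle) * .deg2rad  # angle between H direction and axis a
  t <- unitv(target - p_parent)
  phi <- atan2(sum(t * e2), sum(t * e1))
  dir <- cos(half) * a + sin(half) * (cos(phi) * e1 + sin(phi) * e2)
  p_parent + len * dir
}

#' Add missing polar hydrogens at ideal geometry
#'
#' Places the hydrogens needed by the strict hydrogen-bond criterion:
#' backbone amide H in the peptide plane (every residue with a preceding
#' peptide partner, prolines excepted), and side-chain hydroxyl, thiol,
#' amide, ammonium and guanidinium hydrogens at ideal geometry. Hydroxyl
#' and thiol torsions are oriented toward the nearest acceptor within the
#' configured distance cutoff, otherwise anti to the preceding heavy atom.
#' Only hydrogens that are absent are added, so the operation is
#' idempotent; waters without hydrogens are left heavy-atom-only (the
#' `heavy` bond mode handles them), and histidine ring nitrogens are left
#' unprotonated so that both act as acceptors.
#'
#' @param structure a [PDBStructure-class].
#' @param config an [AnalysisConfig-class]; `dCut` bounds the hydroxyl
#'   acceptor search.
#' @return a new [PDBStructure-class] with hydrogens appended within each
#'   residue block.
#' @export
addPolarHydrogens <- function(structure, config = analysisConfig()) {
  at <- atoms(structure)
  if (!nrow(at)) return(structure)
  keys <- .atomKeys(at)
  rt <- residueTable(structure)
  acc_idx <- .acceptorIndices(at, config)

  unknown <- character(0)
  new_rows <- vector("list", nrow(rt))

  hrow <- function(template, name, p) {
    r <- template
    r$name <- name
    r$element <- "H"
    r$altloc <- ""
    r$occupancy <- 1
    r$bfactor <- 0
    r$x <- p[1L]; r$y <- p[2L]; r$z <- p[3L]
    r
  }

  for (ri in seq_len(nrow(rt))) {
    rn <- rt$resname[ri]
    if (rt$is_hetero[ri] || rn %in% config@waterResnames) next
    if (!rn %in% names(.AA_3TO1)) {
      unknown <- c(unknown, rn)
      next
    }
    res_at <- at[keys == rt$key[ri], , drop = FALSE]
    have <- res_at$name
    pos <- setNames(lapply(seq_len(nrow(res_at)), function(i)
      as.numeric(res_at[i, c("x", "y", "z")])), res_at$name)
    template <- res_at[1L, , drop = FALSE]
    added <- list()

    # backbone amide H
    if (rn != "PRO" && !"H" %in% have &&
        all(c("N", "CA") %in% have)) {
      prev_ok <- ri > 1L && rt$chain[ri - 1L] == rt$chain[ri] &&
        !rt$is_hetero[ri - 1L]
      if (prev_ok) {
        prev_at <- at[keys == rt$key[ri - 1L], , drop = FALSE]
        pC <- .atomPos(prev_at, "C")
        if (!is.null(pC)) {
          dir <- -unitv(unitv(pC - pos[["N"]]) + unitv(pos[["CA"]] - pos[["N"]]))
          added[["H"]] <- pos[["N"]] + 1.01 * dir
        }
      }
    }

    for (rule in .POLAR_H[[rn]] %||% list()) {
      if (is.null(pos[[rule$parent]])) next
      missing_h <- setdiff(rule$h, have)
      if (!length(missing_h)) next
      p <- pos[[rule$parent]]
      if (rule$type == "hydroxyl") {
        if (is.null(pos[[rule$sup]]) || is.null(pos[[rule$anti]])) next
        # nearest acceptor outside this residue within dCut
        cand <- acc_idx[keys[acc_idx] != rt$key[ri]]
        target <- NULL
        if (length(cand)) {
          d <- crossDist(matrix(p, ncol = 3L),
                         as.matrix(at[cand, c("x", "y", "z"), drop = FALSE]))
          j <- which.min(d)
          if (d[j] <= config@dCut)
            target <- as.numeric(at[cand[j], c("x", "y", "z")])
        }
        hp <- if (!is.null(target)) {
          .hydroxylH(p, pos[[rule$sup]], target, rule$len)
        } else {
          placeAtom(pos[[rule$anti]], pos[[rule$sup]], p, rule$len, 109.0, 180)
        }
        added[[rule$h]] <- hp
      } else if (rule$type == "sp2_bisector") {
        if (any(vapply(rule$nb, function(n) is.null(pos[[n]]), logical(1))))
          next
        dir <- -unitv(unitv(pos[[rule$nb[1L]]] - p) +
                        unitv(pos[[rule$nb[2L]]] - p))
        added[[rule$h]] <- p + rule$len * dir
      } else if (rule$type == "sp2_pair") {
        if (is.null(pos[[rule$sup]]) || is.null(pos[[rule$ref]])) next
        tors <- c(180, 0)  # first H trans to the reference oxygen/nitrogen
        for (k in seq_along(rule$h)) {
          if (!rule$h[k] %in% have)
            added[[rule$h[k]]] <- placeAtom(pos[[rule$ref]], pos[[rule$sup]],
                                            p, rule$len, 120, tors[k])
        }
      } else if (rule$type == "sp3_three") {
        if (is.null(pos[[rule$sup]]) || is.null(pos[[rule$anti]])) next
        tors <- c(180, 60, -60)
        for (k in seq_along(rule$h)) {
          if (!rule$h[k] %in% have)
            added[[rule$h[k]]] <- placeAtom(pos[[rule$anti]], pos[[rule$sup]],
                                            p, rule$len, 109.5, tors[k])
        }
      }
    }

    if (length(added))
      new_rows[[ri]] <- do.call(rbind, lapply(names(added), function(nm)
        hrow(template, nm, added[[nm]])))
  }

  if (length(unknown))
    warning("skipping hydrogen placement for unknown residue name(s): ",
            paste(sort(unique(unknown)), collapse = ", "), call. = FALSE)

  if (all(vapply(new_rows, is.null, logical(1)))) return(structure)

  # splice hydrogen rows at the end of each residue block
  blocks <- split(seq_len(nrow(at)), factor(keys, levels = unique(keys)))
  pieces <- list()
  for (bi in seq_along(blocks)) {
    pieces[[length(pieces) + 1L]] <- at[blocks[[bi]], , drop = FALSE]
    ri <- match(names(blocks)[bi], rt$key)
    if (!is.null(new_rows[[ri]]))
      pieces[[length(pieces) + 1L]] <- new_rows[[ri]]
  }
  out <- do.call(rbind, pieces)
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  s <- structure
  s@atoms <- out
  validObject(s)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
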