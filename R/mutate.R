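#' @include AllClasses.R topology.R structure-utils.R
NULL

#' Specify a point mutation
#'
#' @param chain chain identifier.
#' @param resseq residue number (PDB author numbering).
#' @param fromAa,toAa one-letter amino-acid codes; `fromAa` guards against
#'   off-by-one numbering and is checked against the structure.
#' @param icode insertion code, `""` when absent.
#' @return a `MutationSpec` list.
#' @examples
#' mutationSpec("A", 518, "A", "T")
#' @export
mutationSpec <- function(chain, resseq, fromAa, toAa, icode = "") {
  fromAa <- toupper(fromAa); toAa <- toupper(toAa)
  if (!fromAa %in% names(.AA_1TO3) || !toAa %in% names(.AA_1TO3))
    stop("fromAa and toAa must be canonical one-letter amino-acid codes",
         call. = FALSE)
  structure(list(chain = chain, resseq = as.integer(resseq), icode = icode,
                 fromAa = fromAa, toAa = toAa),
            class = "MutationSpec")
}

#' @export
print.MutationSpec <- function(x, ...) {
  cat(sprintf("MutationSpec: %s%d%s %s>%s\n", x$chain, x$resseq, x$icode,
              x$fromAa, x$toAa))
  invisible(x)
}

# Heavy-atom context for clash scoring of one residue: all heavy atoms of
# other residues plus the per-name peptide 1-2/1-3 exclusion sets.
.clashContext <- function(structure, key) {
  at <- atoms(structure)
  keys <- .atomKeys(at)
  rt <- residueTable(structure)
  ri <- match(key, rt$key)
  if (is.na(ri)) stop("residue not found: ", key, call. = FALSE)
  neighbour_key <- function(j) {
    if (j < 1L || j > nrow(rt)) return(NA_character_)
    if (rt$chain[j] != rt$chain[ri] || rt$is_hetero[j]) return(NA_character_)
    rt$key[j]
  }
  oth <- at[keys != key & at$element != "H", , drop = FALSE]
  oth_keys <- .atomKeys(oth)
  list(xyz = as.matrix(oth[, c("x", "y", "z")]),
       vdw = .vdwRadius(oth$element),
       names = oth$name,
       keys = oth_keys,
       prev_key = neighbour_key(ri - 1L),
       next_key = neighbour_key(ri + 1L))
}

.clashOfResidue <- function(res_names, res_elem, res_xyz, ctx) {
  if (!nrow(ctx$xyz) || !nrow(res_xyz)) return(0)
  d <- crossDist(res_xyz, ctx$xyz)
  rsum <- outer(.vdwRadius(res_elem), ctx$vdw, "+")
  overlap <- pmax(rsum - d, 0)
  # drop covalently constrained contacts with the flanking residues
  # (bond-graph distance <= 4 across the peptide bond)
  if (!is.na(ctx$prev_key)) {
    sel <- ctx$keys == ctx$prev_key
    if (any(sel)) {
      excl <- outer(.depthToLink(res_names, "N"),
                    .depthToLink(ctx$names[sel], "C"), "+") <= 3
      overlap[, sel][excl] <- 0
    }
  }
  if (!is.na(ctx$next_key)) {
    sel <- ctx$keys == ctx$next_key
    if (any(sel)) {
      excl <- outer(.depthToLink(res_names, "C"),
                    .depthToLink(ctx$names[sel], "N"), "+") <= 3
      overlap[, sel][excl] <- 0
    }
  }
  sum(overlap^2)
}

#' Steric clash score of one residue against its surroundings
#'
#' Sum over heavy-atom pairs (residue atom, atom of any other residue) of
#' `max(0, r_vdw_sum - d)^2`, with 1-2/1-3 peptide-bonded pairs to the
#' flanking residues excluded. Zero when nothing overlaps; the boundary
#' case d equal to the van der Waals sum scores zero.
#'
#' @param structure a [PDBStructure-class].
#' @param key residue key ([residueKey()]).
#' @return non-negative unitless number.
#' @export
clashScore <- function(structure, key) {
  ctx <- .clashContext(structure, key)
  res_at <- residueAtoms(structure, key)
  res_at <- res_at[res_at$element != "H", , drop = FALSE]
  .clashOfResidue(res_at$name, res_at$element,
                  as.matrix(res_at[, c("x", "y", "z")]), ctx)
}

# Build side-chain heavy atoms for residue type `to3` at the given chi
# vector, on top of named backbone positions. Returns a named list of
# positions in build order.
.buildSideChain <- function(pos, to3, chis) {
  specs <- .SIDECHAIN[[to3]]
  out <- list()
  getp <- function(nm) {
    if (!is.null(out[[nm]])) return(out[[nm]])
    p <- pos[[nm]]
    if (is.null(p)) stop("missing reference atom ", nm, call. = FALSE)
    p
  }
  for (sp in specs) {
    tors <- if (is.list(sp[[7L]])) chis[sp[[7L]]$chi] + sp[[7L]]$offset
            else sp[[7L]]
    out[[sp[[1L]]]] <- placeAtom(getp(sp[[2L]]), getp(sp[[3L]]),
                                 getp(sp[[4L]]), sp[[5L]], sp[[6L]], tors)
  }
  out
}

.wrapAngle <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

#' Apply a point mutation by ideal-geometry side-chain replacement
#'
#' Replaces the side chain of the target residue in place: backbone atoms
#' (and CB where shared) are untouched, the new side chain is built from
#' ideal bond lengths and angles, and rotatable chi torsions are chosen by
#' a coarse grid (-60, 60, 180 degrees per chi) followed by a 10-degree
#' local scan, minimising the [clashScore()] of the rebuilt residue. Ties
#' are broken deterministically by the smallest chi1, then chi2. No other
#' atom of the structure moves, so wild-type/variant comparisons are
#' strictly side-chain-local.
#'
#' @param structure a [PDBStructure-class].
#' @param spec a [mutationSpec()].
#' @param addHydrogens also run [addPolarHydrogens()] on the mutated
#'   structure.
#' @return a `SideChainBuildResult` list with elements `structure` (the
#'   mutated [PDBStructure-class]), `chiAngles` (chosen torsions, degrees),
#'   `clashScore`, and `nCandidatesTried`.
#' @examples
#' s <- makeTwoChainScaffold(nRes = 6)
#' res <- applyMutation(s, mutationSpec("A", 3, "A", "T"))
#' res$chiAngles
#' @export
applyMutation <- function(structure, spec, addHydrogens = FALSE) {
  stopifnot(inherits(spec, "MutationSpec"))
  key <- residueKey(spec$chain, spec$resseq, spec$icode)
  res_at <- residueAtoms(structure, key)
  if (!nrow(res_at))
    stop("mutation target residue not found: ", key, call. = FALSE)
  from3 <- .AA_1TO3[[spec$fromAa]]
  to3 <- .AA_1TO3[[spec$toAa]]
  if (res_at$resname[1L] != from3)
    stop(sprintf(
      "residue identity mismatch at %s: structure has %s, mutation expects %s",
      key, res_at$resname[1L], from3), call. = FALSE)
  backbone <- c("N", "CA", "C", "O")
  if (!all(backbone %in% res_at$name))
    stop(sprintf("incomplete residue %s: backbone atoms %s missing", key,
                 paste(setdiff(backbone, res_at$name), collapse = ",")),
         call. = FALSE)

  if (spec$fromAa == spec$toAa) {
    res <- list(structure = structure, chiAngles = numeric(0),
                clashScore = clashScore(structure, key),
                nCandidatesTried = 1L)
    class(res) <- "SideChainBuildResult"
    return(res)
  }

  keep_names <- c(backbone, "OXT", "H")
  if (to3 != "GLY" && "CB" %in% res_at$name) keep_names <- c(keep_names, "CB")
  kept <- res_at[res_at$name %in% keep_names, , drop = FALSE]
  kept$resname <- to3

  pos <- setNames(
    lapply(seq_len(nrow(kept)), function(i)
      as.numeric(kept[i, c("x", "y", "z")])),
    kept$name)
  if (to3 != "GLY" && is.null(pos[["CB"]]))
    pos[["CB"]] <- placeAtom(pos[[.CB_SPEC$a]], pos[[.CB_SPEC$b]],
                             pos[[.CB_SPEC$c]], .CB_SPEC$len, .CB_SPEC$ang,
                             .CB_SPEC$tors)

  ctx <- .clashContext(structure, key)
  fixed_names <- names(pos)[names(pos) != "H"]
  fixed_xyz <- do.call(rbind, pos[fixed_names])
  fixed_elem <- substr(fixed_names, 1, 1)

  specs <- .SIDECHAIN[[to3]]
  nchi <- .N_CHI[[to3]]
  scoreOf <- function(chis) {
    sc <- .buildSideChain(pos, to3, chis)
    nm <- c(fixed_names, names(sc))
    xyz <- rbind(fixed_xyz, do.call(rbind, sc))
    .clashOfResidue(nm, substr(nm, 1, 1), xyz, ctx)
  }

  n_tried <- 0L
  if (nchi == 0L) {
    best_chis <- numeric(0)
    if (length(specs)) n_tried <- 1L
  } else {
    grid <- as.matrix(expand.grid(rep(list(c(-60, 60, 180)), nchi)))
    scores <- apply(grid, 1L, scoreOf)
    n_tried <- n_tried + nrow(grid)
    # minimal score; ties broken by smallest chi1, then chi2, ...
    cand <- which(scores <= min(scores) + 1e-12)
    ord <- do.call(order, as.data.frame(grid[cand, , drop = FALSE]))
    best_chis <- grid[cand[ord[1L]], ]
    best_score <- scores[cand[ord[1L]]]
    # one pass of 10-degree coordinate refinement around the coarse optimum
    for (k in seq_len(nchi)) {
      for (off in seq(-50, 50, by = 10)) {
        if (off == 0) next
        trial <- best_chis
        trial[k] <- .wrapAngle(trial[k] + off)
        sc <- scoreOf(trial)
        n_tried <- n_tried + 1L
        if (sc < best_score - 1e-12) {
          best_score <- sc
          best_chis <- trial
        }
      }
    }
  }

  side <- .buildSideChain(pos, to3, best_chis)
  build_names <- c(intersect(c("N", "CA", "C", "O", "OXT", "H", "CB"),
                             c(kept$name, if (to3 != "GLY") "CB")),
                   names(side))
  rows <- lapply(build_names, function(nm) {
    i <- which(kept$name == nm)
    if (length(i)) {
      r <- kept[i[1L], , drop = FALSE]
    } else {
      r <- kept[1L, , drop = FALSE]
      r$name <- nm
      r$element <- substr(gsub("[^A-Za-z]", "", nm), 1, 1)
      r$altloc <- ""
      r$occupancy <- 1
      r$bfactor <- 0
      p <- if (nm == "CB") pos[["CB"]] else side[[nm]]
      r$x <- p[1L]; r$y <- p[2L]; r$z <- p[3L]
    }
    r
  })
  new_at <- do.call(rbind, rows)
  out <- .replaceResidueAtoms(structure, key, new_at)
  if (addHydrogens) out <- addPolarHydrogens(out)
  res <- list(structure = out,
              chiAngles = as.numeric(best_chis),
              clashScore = clashScore(out, key),
              nCandidatesTried = n_tried)
  class(res) <- "SideChainBuildResult"
  res
}
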