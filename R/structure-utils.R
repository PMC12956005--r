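#' @include AllClasses.R
NULL

#' Residue keys
#'
#' Canonical residue addressing used across the package:
#' `"chain:resseq"` with the insertion code appended when present
#' (`"A:518"`, `"A:100A"`). Follows PDB author numbering.
#'
#' @param chain chain id(s).
#' @param resseq integer residue number(s).
#' @param icode insertion code(s), `""` when absent.
#' @return character vector of keys.
#' @export
residueKey <- function(chain, resseq, icode = "") {
  icode <- ifelse(is.na(icode) | !nzchar(trimws(icode)), "", trimws(icode))
  sprintf("%s:%d%s", chain, as.integer(resseq), icode)
}

# Residue key per atom row.
.atomKeys <- function(at) residueKey(at$chain, at$resseq, at$icode)

#' Residue table of a structure
#'
#' @param structure a [PDBStructure-class].
#' @return data.frame with one row per residue: `key`, `chain`, `resseq`,
#'   `icode`, `resname`, `is_hetero`, in structure order.
#' @export
residueTable <- function(structure) {
  at <- atoms(structure)
  key <- .atomKeys(at)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = at$chain[first],
             resseq = at$resseq[first], icode = at$icode[first],
             resname = at$resname[first], is_hetero = at$is_hetero[first],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Identify water residues
#'
#' Returns the keys of all residues whose residue name belongs to the
#' configured water set.
#'
#' @param structure a [PDBStructure-class].
#' @param config an [AnalysisConfig-class].
#' @return character vector of residue keys.
#' @export
identifyWaters <- function(structure, config = analysisConfig()) {
  rt <- residueTable(structure)
  rt$key[rt$resname %in% config@waterResnames]
}

# Logical mask over atom rows: protein (non-water, non-hetero) heavy atoms.
.proteinHeavyMask <- function(at, config) {
  !at$is_hetero & at$element != "H" & !(at$resname %in% config@waterResnames) &
    !(at$resname %in% config@ligandResnames)
}

#' Interface residues between two chains
#'
#' Residues of either chain having any heavy atom within `cutoff` of any
#' heavy atom of the other chain. Waters and hetero residues (ligands) are
#' excluded; the result is symmetric in the two chains and monotone
#' non-decreasing in the cutoff.
#'
#' @param structure a [PDBStructure-class].
#' @param chainA,chainB chain identifiers.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 5).
#' @param config an [AnalysisConfig-class] (controls which residue names
#'   count as water/ligand).
#' @return sorted character vector of residue keys.
#' @export
interfaceResidues <- function(structure, chainA, chainB, cutoff = 5,
                              config = analysisConfig()) {
  at <- atoms(structure)
  for (ch in c(chainA, chainB))
    if (!ch %in% at$chain)
      stop(sprintf("chain '%s' not present in structure", ch), call. = FALSE)
  mask <- .proteinHeavyMask(at, config)
  ia <- which(mask & at$chain == chainA)
  ib <- which(mask & at$chain == chainB)
  if (!length(ia) || !length(ib)) return(character(0))
  d <- crossDist(as.matrix(at[ia, c("x", "y", "z")]),
                 as.matrix(at[ib, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(character(0))
  keys <- c(.atomKeys(at[ia[hit[, 1L]], , drop = FALSE]),
            .atomKeys(at[ib[hit[, 2L]], , drop = FALSE]))
  sort(unique(keys))
}

#' Extract the atoms of one residue
#'
#' @param structure a [PDBStructure-class].
#' @param key residue key as produced by [residueKey()].
#' @return data.frame of atom rows.
#' @export
residueAtoms <- function(structure, key) {
  at <- atoms(structure)
  at[.atomKeys(at) == key, , drop = FALSE]
}

# Named position lookup within one residue's atom rows; NULL when absent.
.atomPos <- function(res_at, name) {
  i <- which(res_at$name == name)
  if (!length(i)) return(NULL)
  as.numeric(res_at[i[1L], c("x", "y", "z")])
}

# Replace/append atom rows of one residue, renumbering serials so the
# structure invariants keep holding. Positions `new_at` at the residue's
# original location in the table.
.replaceResidueAtoms <- function(structure, key, new_at) {
  at <- atoms(structure)
  keys <- .atomKeys(at)
  idx <- which(keys == key)
  if (!length(idx)) stop("residue not found: ", key, call. = FALSE)
  before <- at[seq_len(min(idx) - 1L), , drop = FALSE]
  after <- if (max(idx) < nrow(at))
    at[(max(idx) + 1L):nrow(at), , drop = FALSE] else at[0L, , drop = FALSE]
  out <- rbind(before, new_at, after)
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  s <- structure
  s@atoms <- out
  validObject(s)
  s
}
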