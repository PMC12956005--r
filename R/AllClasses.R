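#' @import methods
NULL

.ATOM_COLS <- c("serial", "name", "element", "altloc", "resname", "chain",
                "resseq", "icode", "x", "y", "z", "occupancy", "bfactor",
                "is_hetero")

#' Single-model protein structure
#'
#' An ordered all-atom table for one model of a PDB entry. Atoms of one
#' residue are contiguous, residue identity follows PDB author numbering
#' (chain, residue number, insertion code), and coordinates are Cartesian
#' Angstrom.
#'
#' @slot modelId integer model number (1 for a single-model file).
#' @slot atoms data.frame with one row per atom and columns
#'   `serial`, `name`, `element`, `altloc`, `resname`, `chain`, `resseq`,
#'   `icode`, `x`, `y`, `z`, `occupancy`, `bfactor`, `is_hetero`.
#' @slot title free-text title carried over from the source file.
#'
#' @examples
#' s <- makeTwoChainScaffold(nRes = 4)
#' s
#' head(atoms(s))
#' @export
setClass("PDBStructure",
  representation(modelId = "integer", atoms = "data.frame",
                 title = "character"),
  prototype(modelId = 1L, title = ""))

setValidity("PDBStructure", function(object) {
  at <- object@atoms
  msgs <- character()
  missing_cols <- setdiff(.ATOM_COLS, names(at))
  if (length(missing_cols))
    return(paste("atom table lacks columns:",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(at)) {
    if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
      msgs <- c(msgs, "non-finite atom coordinates")
    key <- paste(at$chain, at$resseq, at$icode, at$name, at$altloc)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (chain, resseq, icode, name, altloc) atom")
    rk <- paste(at$chain, at$resseq, at$icode)
    if (length(rle(rk)$values) != length(unique(rk)))
      msgs <- c(msgs, "atoms of one residue are not contiguous")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Geometric analysis configuration
#'
#' Holds the hydrogen-bond and interface criteria used throughout the
#' package: heavy-atom donor--acceptor distance cutoff, donor-H...acceptor
#' angle cutoff, the residue names treated as water or ligand, the interface
#' contact cutoff and the bridge counting metric.
#'
#' @slot dCut heavy-atom donor--acceptor distance cutoff, Angstrom
#'   (default 3.5, inclusive).
#' @slot thetaCut donor-H...acceptor angle cutoff at the hydrogen, degrees
#'   (default 150, inclusive); ignored in `heavy` mode.
#' @slot waterResnames residue names recognised as water.
#' @slot ligandResnames residue names treated as ligand (kept in structures,
#'   excluded from bridge endpoints and elastic-network nodes).
#' @slot interfaceCutoff heavy-atom cutoff defining interface residues,
#'   Angstrom (default 5).
#' @slot hbondMode `"strict"` (distance + angle, needs polar hydrogens) or
#'   `"heavy"` (distance only).
#' @slot bridgeMetric `"waters"` (distinct bridging waters) or `"pairs"`
#'   (water-mediated partner pairs).
#' @export
setClass("AnalysisConfig",
  representation(dCut = "numeric", thetaCut = "numeric",
                 waterResnames = "character", ligandResnames = "character",
                 interfaceCutoff = "numeric", hbondMode = "character",
                 bridgeMetric = "character"),
  prototype(dCut = 3.5, thetaCut = 150,
            waterResnames = c("HOH", "WAT", "TIP3", "SOL"),
            ligandResnames = character(0), interfaceCutoff = 5,
            hbondMode = "strict", bridgeMetric = "waters"))

setValidity("AnalysisConfig", function(object) {
  if (object@dCut <= 0) return("dCut must be > 0")
  if (object@thetaCut <= 0 || object@thetaCut > 180)
    return("thetaCut must lie in (0, 180]")
  if (!object@hbondMode %in% c("strict", "heavy"))
    return("hbondMode must be 'strict' or 'heavy'")
  if (!object@bridgeMetric %in% c("waters", "pairs"))
    return("bridgeMetric must be 'waters' or 'pairs'")
  TRUE
})

#' Molecular-dynamics protocol record
#'
#' Provenance record of the simulation protocol whose saved frames the
#' trajectory analyses consume. The package does not run dynamics; the
#' record fixes frame cadence and is echoed into reports.
#'
#' @slot temperature K. @slot pressure bar. @slot timestep fs.
#' @slot friction ps^-1. @slot nvtDuration ps. @slot nptDuration ps.
#' @slot production ns. @slot saveInterval ns.
#' @slot minTolerance kJ/mol/nm. @slot minMaxIter count.
#' @export
setClass("MDProtocol",
  representation(temperature = "numeric", pressure = "numeric",
                 timestep = "numeric", friction = "numeric",
                 nvtDuration = "numeric", nptDuration = "numeric",
                 production = "numeric", saveInterval = "numeric",
                 minTolerance = "numeric", minMaxIter = "numeric"),
  prototype(temperature = 300, pressure = 1, timestep = 2, friction = 1,
            nvtDuration = 500, nptDuration = 500, production = 100,
            saveInterval = 2, minTolerance = 1.0, minMaxIter = 500))

setValidity("MDProtocol", function(object) {
  vals <- c(object@temperature, object@pressure, object@timestep,
            object@friction, object@nvtDuration, object@nptDuration,
            object@production, object@saveInterval, object@minTolerance,
            object@minMaxIter)
  if (any(vals <= 0)) return("all protocol values must be strictly positive")
  nf <- object@production / object@saveInterval
  if (abs(nf - round(nf)) > 1e-9)
    return("production / saveInterval must give an integer frame count")
  TRUE
})

#' Anisotropic elastic network model
#'
#' Calpha spring network of a (possibly dimeric) structure: nodes are the
#' Calpha positions of protein residues, springs join nodes within the
#' cutoff, and the 3N x 3N Hessian carries the standard anisotropic-network
#' super-blocks.
#'
#' @slot nodes N x 3 matrix of Calpha coordinates (Angstrom).
#' @slot keys residue keys ("chain:resseq") of the nodes, length N.
#' @slot cutoff spring cutoff R_c, Angstrom.
#' @slot gamma uniform spring constant, kcal/mol/Angstrom^2.
#' @slot hessian 3N x 3N symmetric matrix.
#' @slot warnings character vector of assembly warnings (e.g. disconnected
#'   network).
#' @export
setClass("ElasticNetworkModel",
  representation(nodes = "matrix", keys = "character", cutoff = "numeric",
                 gamma = "numeric", hessian = "matrix",
                 warnings = "character"),
  prototype(cutoff = 13, gamma = 1, warnings = character(0)))

setValidity("ElasticNetworkModel", function(object) {
  n <- nrow(object@nodes)
  if (length(object@keys) != n) return("keys length must match node count")
  if (!identical(dim(object@hessian), c(3L * n, 3L * n)))
    return("hessian must be 3N x 3N")
  if (max(abs(object@hessian - t(object@hessian))) > 1e-8)
    return("hessian must be symmetric")
  TRUE
})

#' Normal-mode spectrum of an elastic network
#'
#' @slot values eigenvalues in ascending order, units of gamma.
#' @slot vectors orthonormal eigenvectors, columns matching `values`.
#' @slot nZero number of (near-)zero rigid-body modes detected.
#' @export
setClass("ModeSpectrum",
  representation(values = "numeric", vectors = "matrix", nZero = "integer"))

#' Stability comparison of wild type and variant in one state
#'
#' @slot stateLabel `"active"` or `"inactive"` (free label).
#' @slot ddgProxy signed stability proxy, kcal/mol; positive = stabilizing.
#' @slot ddsVib vibrational-entropy difference variant minus WT,
#'   cal/(mol K).
#' @slot perResidueDds per-residue attribution of `ddsVib`, named by
#'   residue key; sums to `ddsVib`.
#' @slot deltaContacts integer change in interchain H-bonds + bridges
#'   (variant minus WT).
#' @slot params echo of the proxy parameters (epsilon, weights, T, R_c,
#'   gamma).
#' @export
setClass("StabilityReport",
  representation(stateLabel = "character", ddgProxy = "numeric",
                 ddsVib = "numeric", perResidueDds = "numeric",
                 deltaContacts = "integer", params = "list"))

setValidity("StabilityReport", function(object) {
  if (length(object@perResidueDds) &&
      abs(sum(object@perResidueDds) - object@ddsVib) >
        1e-6 * max(1, abs(object@ddsVib)))
    return("perResidueDds must sum to ddsVib")
  TRUE
})

#' Per-frame interchain water-bridge counts
#'
#' @slot frameTimes frame times in ns, strictly increasing.
#' @slot counts non-negative integer bridge count per frame.
#' @slot metric `"waters"` or `"pairs"`.
#' @slot sourceLabel condition label, e.g. `"WT-active"`.
#' @export
setClass("BridgeTimeSeries",
  representation(frameTimes = "numeric", counts = "integer",
                 metric = "character", sourceLabel = "character"),
  prototype(metric = "waters", sourceLabel = ""))

setValidity("BridgeTimeSeries", function(object) {
  if (length(object@frameTimes) != length(object@counts))
    return("frameTimes and counts must have equal length")
  if (length(object@frameTimes) > 1 && any(diff(object@frameTimes) <= 0))
    return("frameTimes must be strictly increasing")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})
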