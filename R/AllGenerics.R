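#' @include AllClasses.R
NULL

#' Atom table of a structure
#'
#' @param x a [PDBStructure-class].
#' @return data.frame with one row per atom.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)

#' Number of atoms
#' @param x a [PDBStructure-class].
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "PDBStructure", function(x) nrow(x@atoms))

#' Chain identifiers present in a structure
#' @param x a [PDBStructure-class].
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname chainIds
#' @export
setMethod("chainIds", "PDBStructure", function(x) unique(x@atoms$chain))

#' Atom coordinates as an n x 3 matrix
#' @param x a [PDBStructure-class].
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "PDBStructure", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' Eigenvalues of a mode spectrum
#' @param x a [ModeSpectrum-class].
#' @export
setGeneric("modeValues", function(x) standardGeneric("modeValues"))

#' @rdname modeValues
#' @export
setMethod("modeValues", "ModeSpectrum", function(x) x@values)

#' Per-frame counts of a bridge time series
#' @param x a [BridgeTimeSeries-class].
#' @export
setGeneric("seriesCounts", function(x) standardGeneric("seriesCounts"))

#' @rdname seriesCounts
#' @export
setMethod("seriesCounts", "BridgeTimeSeries", function(x) x@counts)

#' Frame times (ns) of a bridge time series
#' @param x a [BridgeTimeSeries-class].
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' @rdname seriesTimes
#' @export
setMethod("seriesTimes", "BridgeTimeSeries", function(x) x@frameTimes)

#' Stability proxy value (kcal/mol, positive = stabilizing)
#' @param x a [StabilityReport-class].
#' @export
setGeneric("ddgProxy", function(x) standardGeneric("ddgProxy"))

#' @rdname ddgProxy
#' @export
setMethod("ddgProxy", "StabilityReport", function(x) x@ddgProxy)

#' Vibrational-entropy difference (cal/(mol K), variant minus WT)
#' @param x a [StabilityReport-class].
#' @export
setGeneric("ddsVib", function(x) standardGeneric("ddsVib"))

#' @rdname ddsVib
#' @export
setMethod("ddsVib", "StabilityReport", function(x) x@ddsVib)

#' Per-residue vibrational-entropy attribution
#' @param x a [StabilityReport-class].
#' @return named numeric vector (residue key -> cal/(mol K)).
#' @export
setGeneric("perResidueDds", function(x) standardGeneric("perResidueDds"))

#' @rdname perResidueDds
#' @export
setMethod("perResidueDds", "StabilityReport", function(x) x@perResidueDds)

setMethod("show", "PDBStructure", function(object) {
  at <- object@atoms
  cat(sprintf("PDBStructure model %d: %d atoms", object@modelId, nrow(at)))
  if (nrow(at)) {
    ch <- table(at$chain)
    cat(sprintf(" | chains: %s",
                paste(sprintf("%s(%d)", names(ch), as.integer(ch)),
                      collapse = " ")))
    nres <- length(unique(paste(at$chain, at$resseq, at$icode)))
    cat(sprintf(" | %d residues", nres))
  }
  cat("\n")
  if (nzchar(object@title)) cat("  title:", object@title, "\n")
  invisible(object)
})

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf(
    "AnalysisConfig: d_cut=%.2f A, theta_cut=%.1f deg, mode=%s, metric=%s\n",
    object@dCut, object@thetaCut, object@hbondMode, object@bridgeMetric))
  cat(sprintf("  waters: %s | ligands: %s | interface cutoff: %.1f A\n",
              paste(object@waterResnames, collapse = ","),
              if (length(object@ligandResnames))
                paste(object@ligandResnames, collapse = ",") else "(none)",
              object@interfaceCutoff))
  invisible(object)
})

setMethod("show", "ElasticNetworkModel", function(object) {
  cat(sprintf("ElasticNetworkModel: %d nodes, R_c=%.1f A, gamma=%g\n",
              nrow(object@nodes), object@cutoff, object@gamma))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
  invisible(object)
})

setMethod("show", "ModeSpectrum", function(object) {
  cat(sprintf("ModeSpectrum: %d modes (%d near-zero), lambda range [%g, %g]\n",
              length(object@values), object@nZero,
              min(object@values), max(object@values)))
  invisible(object)
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport [%s]\n", object@stateLabel))
  cat(sprintf("  ddG proxy: %+.4f kcal/mol (positive = stabilizing)\n",
              object@ddgProxy))
  cat(sprintf("  ddS_vib (variant - WT): %+.4f cal/(mol K)\n", object@ddsVib))
  cat(sprintf("  interchain contact change: %+d\n", object@deltaContacts))
  invisible(object)
})

setMethod("show", "BridgeTimeSeries", function(object) {
  n <- length(object@counts)
  cat(sprintf("BridgeTimeSeries '%s': %d frames, metric=%s",
              object@sourceLabel, n, object@metric))
  if (n) cat(sprintf(", mean count %.2f", mean(object@counts)))
  cat("\n")
  invisible(object)
})

setMethod("show", "MDProtocol", function(object) {
  cat(sprintf(
    "MDProtocol: %g ns production at %g fs step, frames every %g ns (%d frames)\n",
    object@production, object@timestep, object@saveInterval,
    as.integer(round(object@production / object@saveInterval))))
  cat(sprintf("  NVT %g ps + NPT %g ps at %g K / %g bar, friction %g ps^-1\n",
              object@nvtDuration, object@nptDuration, object@temperature,
              object@pressure, object@friction))
  invisible(object)
})
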