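#' Create an analysis configuration
#'
#' Constructor for [AnalysisConfig-class] with the package defaults:
#' heavy-atom donor--acceptor cutoff 3.5 Angstrom and donor-H...acceptor
#' angle cutoff 150 degrees (both inclusive), waters recognised as
#' HOH/WAT/TIP3/SOL, interface contact cutoff 5 Angstrom.
#'
#' @param dCut heavy-atom donor--acceptor distance cutoff (Angstrom).
#' @param thetaCut D-H...A angle cutoff at the hydrogen (degrees).
#' @param waterResnames residue names treated as water.
#' @param ligandResnames residue names treated as ligand (e.g. `"URI"` for
#'   the uridine agonist of the active state); ligands are retained in
#'   structures but never serve as bridge endpoints or network nodes.
#' @param interfaceCutoff interface residue heavy-atom cutoff (Angstrom).
#' @param hbondMode `"strict"` (distance and angle; requires polar
#'   hydrogens) or `"heavy"` (distance only, for hydrogen-free crystal
#'   structures).
#' @param bridgeMetric `"waters"` counts distinct bridging waters,
#'   `"pairs"` counts water-mediated partner pairs.
#' @return an [AnalysisConfig-class] object.
#' @examples
#' analysisConfig(ligandResnames = "URI")
#' @export
analysisConfig <- function(dCut = 3.5, thetaCut = 150,
                           waterResnames = c("HOH", "WAT", "TIP3", "SOL"),
                           ligandResnames = character(0),
                           interfaceCutoff = 5,
                           hbondMode = c("strict", "heavy"),
                           bridgeMetric = c("waters", "pairs")) {
  new("AnalysisConfig", dCut = dCut, thetaCut = thetaCut,
      waterResnames = toupper(waterResnames),
      ligandResnames = toupper(ligandResnames),
      interfaceCutoff = interfaceCutoff,
      hbondMode = match.arg(hbondMode),
      bridgeMetric = match.arg(bridgeMetric))
}

#' Create an MD protocol record
#'
#' Provenance record of the simulation protocol behind a trajectory. The
#' defaults mirror a standard Langevin NPT production protocol: 100 ns at a
#' 2 fs timestep, 300 K, 1 bar, coordinates saved every 2 ns (50 frames).
#'
#' @param temperature K. @param pressure bar. @param timestep fs.
#' @param friction ps^-1. @param nvtDuration,nptDuration equilibration, ps.
#' @param production production length, ns.
#' @param saveInterval frame save cadence, ns.
#' @param minTolerance minimisation tolerance, kJ/mol/nm.
#' @param minMaxIter minimisation iteration cap.
#' @return an [MDProtocol-class] object.
#' @export
mdProtocol <- function(temperature = 300, pressure = 1, timestep = 2,
                       friction = 1, nvtDuration = 500, nptDuration = 500,
                       production = 100, saveInterval = 2,
                       minTolerance = 1.0, minMaxIter = 500) {
  new("MDProtocol", temperature = temperature, pressure = pressure,
      timestep = timestep, friction = friction, nvtDuration = nvtDuration,
      nptDuration = nptDuration, production = production,
      saveInterval = saveInterval, minTolerance = minTolerance,
      minMaxIter = minMaxIter)
}

#' Expected number of saved frames of a protocol
#'
#' @param protocol an [MDProtocol-class].
#' @return integer frame count (production / saveInterval).
#' @export
expectedFrames <- function(protocol) {
  as.integer(round(protocol@production / protocol@saveInterval))
}

#' Read an analysis configuration from a YAML file
#'
#' Recognised keys mirror the [analysisConfig()] arguments in snake_case:
#' `d_cut`, `theta_cut`, `water_resnames`, `ligand_resnames`,
#' `interface_cutoff`, `hbond_mode`, `bridge_metric`. Missing keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return an [AnalysisConfig-class] object.
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  map <- c(d_cut = "dCut", theta_cut = "thetaCut",
           water_resnames = "waterResnames",
           ligand_resnames = "ligandResnames",
           interface_cutoff = "interfaceCutoff",
           hbond_mode = "hbondMode", bridge_metric = "bridgeMetric")
  for (k in names(map)) if (!is.null(y[[k]])) args[[map[[k]]]] <- y[[k]]
  unknown <- setdiff(names(y), names(map))
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(analysisConfig, args)
}

# Flatten a config into a provenance list for reports.
.configProvenance <- function(config) {
  list(d_cut = config@dCut, theta_cut = config@thetaCut,
       water_resnames = config@waterResnames,
       ligand_resnames = config@ligandResnames,
       interface_cutoff = config@interfaceCutoff,
       hbond_mode = config@hbondMode, bridge_metric = config@bridgeMetric)
}
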