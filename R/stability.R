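#' @include AllClasses.R enm.R hbonds.R
NULL

# Distinct donor-acceptor pairs joining the two protomer chains, plus
# protein-ligand bonds (the agonist contributes to the contact term even
# though it is excluded from network nodes and bridge endpoints).
.interchainContactCount <- function(structure, chainA, chainB, config,
                                    hbonds = NULL) {
  hb <- if (is.null(hbonds)) findHBonds(structure, config) else hbonds
  if (!nrow(hb)) return(0L)
  at <- atoms(structure)
  lig <- at$resname %in% config@ligandResnames |
    (at$is_hetero & !(at$resname %in% config@waterResnames))
  pp <- !hb$donor_is_water & !hb$acceptor_is_water
  d_lig <- lig[hb$donor_idx]
  a_lig <- lig[hb$acceptor_idx]
  cross <- pp & !d_lig & !a_lig &
    ((hb$donor_chain == chainA & hb$acceptor_chain == chainB) |
       (hb$donor_chain == chainB & hb$acceptor_chain == chainA))
  ligb <- pp & xor(d_lig, a_lig) &
    (hb$donor_chain %in% c(chainA, chainB) |
       hb$acceptor_chain %in% c(chainA, chainB))
  sel <- cross | ligb
  length(unique(paste(hb$donor_idx[sel], hb$acceptor_idx[sel])))
}

# Per-residue squared-amplitude weights of the non-zero modes: rows =
# residues, columns = non-zero modes, each column summing to one.
.modeAmplitudes <- function(spectrum) {
  vecs <- spectrum@vectors
  nz <- spectrum@nZero
  n <- nrow(vecs) / 3L
  idx <- (nz + 1L):ncol(vecs)
  v2 <- vecs[, idx, drop = FALSE]^2
  grp <- rep(seq_len(n), each = 3L)
  rowsum(v2, grp)
}

#' Stability proxy for a variant in one conformational state
#'
#' Transparent elastic-network + contact-count stand-in for black-box
#' stability predictors: combines the change in interchain hydrogen
#' bonding (direct interchain bonds plus water bridges, variant minus
#' wild type) with the change in vibrational entropy of the Calpha
#' network,
#' `ddG_proxy = wE * epsilon * dN_contacts - T * wS * ddS_vib`,
#' in kcal/mol with the convention positive = stabilizing: gained
#' interface contacts and rigidification (negative `ddS_vib`) both raise
#' the proxy. Per-residue entropy differences attribute each mode's
#' log-eigenvalue change to residues in proportion to the mean squared
#' eigenvector amplitude, giving the per-residue profile whose sum is
#' `ddsVib`.
#'
#' @param wt,mut wild-type and variant [PDBStructure-class] sharing the
#'   same backbone (identical protein residue keys).
#' @param stateLabel free label for the conformational state
#'   (`"active"`, `"inactive"`).
#' @param config an [AnalysisConfig-class].
#' @param chainA,chainB the protomer chains of the dimer interface.
#' @param cutoff,gamma network parameters passed to [buildENM()].
#' @param epsilon contact energy increment per gained bond, kcal/mol
#'   (default 0.5).
#' @param wE,wS weights of the contact and entropy terms (default 1).
#' @param temperature K (default 300, matching the MD protocol record).
#' @param enmWt,enmMut optional prebuilt [ElasticNetworkModel-class]
#'   objects (used by fixtures that perturb springs directly).
#' @return a [StabilityReport-class].
#' @export
stateStability <- function(wt, mut, stateLabel = "active",
                           config = analysisConfig(),
                           chainA = "A", chainB = "B",
                           cutoff = 13, gamma = 1, epsilon = 0.5,
                           wE = 1, wS = 1, temperature = 300,
                           enmWt = NULL, enmMut = NULL) {
  if (is.null(enmWt)) enmWt <- buildENM(wt, cutoff, gamma, config = config)
  if (is.null(enmMut)) enmMut <- buildENM(mut, cutoff, gamma, config = config)
  if (!identical(enmWt@keys, enmMut@keys))
    stop("alignment error: wild-type and variant residue keys differ",
         call. = FALSE)

  spec_wt <- normalModes(enmWt)
  spec_mut <- normalModes(enmMut)
  if (spec_wt@nZero != spec_mut@nZero)
    stop("alignment error: differing zero-mode counts between states",
         call. = FALSE)

  s_wt <- vibrationalEntropy(spec_wt, temperature)
  s_mut <- vibrationalEntropy(spec_mut, temperature)
  dds <- s_mut$sVib - s_wt$sVib

  nz <- spec_wt@nZero
  lam_wt <- spec_wt@values[(nz + 1L):length(spec_wt@values)]
  lam_mut <- spec_mut@values[(nz + 1L):length(spec_mut@values)]
  mode_contrib <- -(.KB_KCAL / 2) * 1000 * (log(lam_mut) - log(lam_wt))
  w <- (.modeAmplitudes(spec_wt) + .modeAmplitudes(spec_mut)) / 2
  per_res <- as.numeric(w %*% mode_contrib)
  names(per_res) <- enmWt@keys

  n_wt <- .interchainContactCount(wt, chainA, chainB, config) +
    countBridges(findWaterBridges(wt, chainA, chainB, config),
                 config@bridgeMetric)
  n_mut <- .interchainContactCount(mut, chainA, chainB, config) +
    countBridges(findWaterBridges(mut, chainA, chainB, config),
                 config@bridgeMetric)
  dn <- as.integer(n_mut - n_wt)

  ddg <- wE * epsilon * dn - temperature * wS * dds / 1000

  new("StabilityReport", stateLabel = stateLabel, ddgProxy = ddg,
      ddsVib = dds, perResidueDds = per_res, deltaContacts = dn,
      params = list(epsilon = epsilon, wE = wE, wS = wS,
                    temperature = temperature, cutoff = cutoff,
                    gamma = gamma, bridge_metric = config@bridgeMetric,
                    warnings = c(enmWt@warnings, enmMut@warnings)))
}
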