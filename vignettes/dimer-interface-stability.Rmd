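---
title: "Methods: interface hydrogen bonding and elastic-network stability of homodimer point variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface hydrogen bonding and elastic-network stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerstab)
```

# The question the package answers

A receptor that functions as a preformed homodimer — Toll-like receptor
8 is the motivating case — switches between an unliganded (*inactive*)
and a liganded (*active*) arrangement of its two protomers. A point
substitution at the protomer–protomer interface can shift this
equilibrium: if the new side chain adds favourable interactions across
the interface of the active arrangement specifically, the variant is
expected to behave as a gain-of-function allele. `dimerstab` quantifies
two structural signatures of such a shift, for each conformational
state separately:

* the **hydrogen-bond network across the interface**, including
  water-mediated bridges, compared between wild type and variant; and
* a **stability proxy** combining the change in interchain contacts
  with the change in vibrational entropy of a coarse-grained elastic
  network.

Both signatures are computed on static structures and, where
trajectories are available, per saved frame.

# Hydrogen-bond model

A hydrogen bond is accepted when the heavy-atom donor–acceptor distance
satisfies d(D···A) ≤ `dCut` and, in `strict` mode, some hydrogen
attached to the donor satisfies ∠(D–H···A) ≥ `thetaCut` measured at the
hydrogen. Defaults are 3.5 Å and 150°. Both thresholds are
**inclusive**: a pair at exactly 3.50 Å with an angle of exactly 150.0°
is a bond, and boundary tests pin this convention. The distance is
deliberately heavy-atom (not H···A): 3.5 Å is the conventional
heavy-atom criterion, and it keeps `heavy` mode (distance only, for
hydrogen-free crystal structures) consistent with `strict` mode.

Donor and acceptor chemistry comes from a residue-topology table
compiled into the package: backbone amide N donates (except proline),
backbone carbonyl O and OXT accept, polar side chains donate/accept per
their chemistry (Ser/Thr/Tyr hydroxyls both ways, Lys/Arg/Trp/Asn/Gln
nitrogens donate, Asp/Glu/Asn/Gln oxygens accept), water O both
donates and accepts, and ligand N/O atoms accept (donating only when a
hydrogen is present). Histidine ring nitrogens are treated as acceptors
unless explicitly protonated; `addPolarHydrogens()` therefore leaves
them bare, a deliberate neutral-tautomer-free simplification.
Candidate pairs closer than 2.0 Å are discarded as covalent.

A **water bridge** is one water H-bonded to at least one protein atom
of each protomer chain. Only first-order (single-water) bridges count;
water–water chains are excluded because higher-order paths are
unbounded and a single bridging water is the structure such analyses
display. Ligands are never bridge endpoints. Because the number of
"water-mediated hydrogen bonds" is ambiguous between distinct waters
and water-mediated partner pairs, both metrics are computed
(`countBridges(x, "waters")` and `"pairs"`); `waters` is the default
and reports label which is used.

Neighbour search uses cell lists with cells of edge `dCut`; tests
assert exact equality with exhaustive O(n²) enumeration, so binning is
purely an optimisation.

# Side-chain replacement

The variant structure is produced by replacing the target residue's
side chain in place: backbone atoms (and Cβ when shared) keep their
input coordinates bit-for-bit, new atoms are built from ideal bond
lengths and angles via internal coordinates, and rotatable χ torsions
are chosen by a coarse grid (−60°, 60°, 180° per χ) refined by a
10°-step local scan, minimising a steric clash score. Ties break
deterministically toward the smallest χ1, then χ2, so identical inputs
give identical coordinates. This is a conscious substitute for
template-based modelling: for small substitutions (alanine to
threonine adds two heavy atoms) the scientific signal lives in the
hydrogen-bond network and the elastic network, and keeping every other
atom fixed makes the wild-type/variant comparison strictly
side-chain-local. No backbone or neighbour relaxation is performed;
instead any residual post-mutation clash is reported (`clashScore`)
and flagged in pipeline reports rather than silently minimised away.

The clash score sums max(0, r_vdw,i + r_vdw,j − d_ij)² over heavy-atom
pairs between the residue and all other residues, with one published
van der Waals radii set compiled in (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å) — reproducibility over configurability. Contacts fixed by
covalent geometry rather than rotamer choice — pairs within
bond-graph distance 4 across the peptide bond — are excluded;
with ideal peptide geometry every chain would otherwise carry a
constant, rotamer-independent overlap from its 1-4/1-5 backbone
contacts, and the score would never be zero even for a perfect
scaffold.

Polar hydrogens are placed at ideal geometry: the backbone amide H
opposite the bisector of its two heavy neighbours in the peptide
plane; amide, guanidinium and ammonium hydrogens from standard sp²/sp³
geometry; hydroxyl and thiol torsions oriented toward the nearest
acceptor within `dCut` by closed-form cone projection (verified
against a 1° torsion grid in the tests), else anti to the preceding
heavy atom. Only missing hydrogens are added, so the operation is
idempotent; waters without hydrogens are left heavy-atom-only and
handled by `heavy` mode.

# Elastic-network stability proxy

Black-box stability predictors return a single ΔΔG with no auditable
path from structure to number. The package instead uses an anisotropic
network model whose every intermediate is inspectable:

* **Nodes** are the Cα atoms of all protein residues of the dimer (both
  chains in one network); waters and ligands are excluded.
* **Springs** join nodes within R_c = 13 Å with uniform constant γ = 1
  kcal mol⁻¹ Å⁻²; the Hessian off-diagonal super-block for pair (i, j)
  is −γ/|r_ij|²·r_ij r_ijᵀ and diagonal blocks are negated row sums, so
  uniform translations are annihilated exactly. R_c = 13 Å is the
  conventional Cα anisotropic-network cutoff; γ only scales entropy
  *differences* additively and cancels in state-to-state comparisons.
* **Modes** come from a full symmetric eigendecomposition; a connected
  non-collinear network has exactly six near-zero rigid-body modes
  (tolerance 10⁻¹⁰·λ_max). Disconnection at R_c is recorded as a
  warning on the model, since it adds zero modes.
* **Vibrational entropy** over non-zero modes is the classical harmonic
  form S_vib = (k_B/2) Σ ln(k_B T/λᵢ) in cal mol⁻¹ K⁻¹ at T = 300 K;
  the additive constant of the classical oscillator is dropped because
  only differences are ever reported. Node masses are uniform (Cα
  coarse graining) and likewise cancel.
* **Per-residue attribution**: each mode's contribution
  −(k_B/2)·Δln λᵢ is distributed over residues proportionally to the
  mean of wild-type and variant squared eigenvector amplitudes. The
  mean makes the attribution exactly antisymmetric under swapping the
  two states, and the profile sums to the total ΔΔS_vib.

The reported score is

ΔΔG_proxy = w_E · ε · ΔN_contacts − T · w_S · ΔΔS_vib,

with ΔN_contacts the change (variant − wild type) in distinct
interchain donor–acceptor pairs plus water bridges, ε = 0.5 kcal/mol
per contact, w_E = w_S = 1, and the convention **positive =
stabilizing**: gained interface contacts and rigidification
(ΔΔS_vib < 0) both raise the score. The value of ε is a generic
hydrogen-bond energy scale chosen once; the proxy's purpose is signed,
reproducible comparison between states, not absolute free energies,
and all outputs label it as a proxy. Ligands are excluded from network
nodes and bridge endpoints but their hydrogen bonds to protein do enter
the contact term, so an agonist bound at the interface contributes to
the active state's contact bookkeeping.

# Trajectory statistics

Multi-model PDB is the normative trajectory container (binary formats
would add a heavy dependency the core does not need; frames can be
converted externally). Frame *i* of a production trajectory saved every
`saveInterval` ns is stamped at time i·saveInterval — the first saved
frame at one save interval, since equilibration frames are not part of
the analysed production run. The recorded default protocol — 300 K,
1 bar, 2 fs timestep, friction 1 ps⁻¹, 500 ps NVT + 500 ps NPT
equilibration, 100 ns production, frames every 2 ns (50 frames) — is a
provenance record only; the package never integrates equations of
motion, and a frame count differing from the protocol's expectation is
reported as a warning, not an error.

Per-frame bridge counts from consecutive frames are autocorrelated, so
summaries and comparisons use a **block bootstrap**: non-overlapping
blocks of 5 frames (10 ns at the default cadence) are resampled with
replacement, and 95% percentile intervals are taken over 1000
replicates. Five frames is a deliberate compromise — long enough to
absorb short-range correlation of interface solvation, short enough to
leave ≥ 10 blocks in a 50-frame trajectory; it is configurable. All
bootstrap draws run under a caller-supplied seed through a local RNG
scope, so results are bit-reproducible and the caller's random stream
is untouched. Rather than a named hypothesis test, comparisons report
the mean difference with its bootstrap interval: with no stated
aggregation convention for such figures, the full per-frame series is
also always exported so any aggregation can be recomputed.

# Synthetic study sets

The generators produce every input the analyses need, with ground
truth known by construction and re-verified by direct geometric
measurement before a fixture is returned (a failed self-check is a
construction error, never a silently wrong truth):

* `makeTwoChainScaffold()` builds two ideal-geometry extended poly-ALA
  strands on parallel axes, chain B rotated so its carbonyl oxygens
  face chain A. The default axis separation of 7.2 Å puts facing
  carbonyl pairs ~4.4 Å apart — exactly the apex geometry at which a
  water 2.8 Å from both oxygens attains its ideal 104.5° H–O–H span.
* `plantWaterBridges()` places true bridges at 2.8 Å / ≥165°, clear of
  the 3.5 Å / 150° thresholds by ≥0.2 Å and ≥15°, so floating-point
  noise cannot flip the truth; decoys violate exactly one criterion
  with the same margins (distance decoys at 3.8 Å and ≥3.7 Å from all
  other polar atoms; angle decoys at bridging distance but rotated so
  no D–H···A angle exceeds 140°). Distance decoys become detectable
  under a relaxed cutoff, which the monotonicity tests exploit.
* `makeEnmFixturePair()` yields wild-type/variant pairs with identical
  backbones, listed spring-constant factors applied to the variant's
  network and a planted bridge-count difference.
* `makePseudoTrajectory()` plants an exact per-frame bridge count
  while keeping topology constant across frames — waters whose bridge
  is absent in a frame are displaced 50 Å out of criteria, not
  deleted.

What these fixtures emulate is the *geometry* the detectors and the
network model consume: chains, interfaces, polar hydrogens, bridging
and decoy waters, eigenvalue shifts, frame series. What they do not
emulate is the physics of real data — solvation shells, water exchange
kinetics, force-field energetics, side-chain and backbone disorder,
crystallographic artefacts. Green tests therefore certify that the
algorithms compute their stated quantities exactly and reproducibly;
they do not certify that those quantities capture any particular real
protein, which is a modelling judgement outside the package.

# Numerical choices and degenerate inputs

* Thresholds are inclusive (≤, ≥) everywhere, pinned by boundary tests
  at exactly 3.50 Å / 150.0°.
* Rotamer ties break toward the smallest χ1, then χ2; altloc collapse
  keeps the highest occupancy, ties broken by altloc letter.
* Zero modes are classified at 10⁻¹⁰·λ_max; entropy on a network with
  no non-zero mode is an error (degenerate network), not a number.
* A structure whose two chains never approach within the interface
  cutoff yields an empty interface, not an error; a missing chain is
  an error naming the chain.
* Perfectly planar or collinear node sets (possible in synthetic
  scaffolds) have more than six zero modes; the elastic-network code
  counts rather than assumes them, and state comparisons require equal
  zero-mode counts on both sides.
* Parsing is strict about numeric fields (errors name the line) and
  lenient about short lines and missing element columns (inferred from
  atom names).

# Scope and limitations

* The stability score is a proxy with an arbitrary but fixed energy
  scale; its sign and state-to-state ordering are the meaningful
  outputs. No claim of numerical agreement with trained
  stability-prediction services is made.
* Side-chain construction uses ideal geometry with a coarse-plus-local
  χ search, not a rotamer library; proline ring closure is approximate
  (topology-table construction only) and pKa-dependent protonation is
  out of scope.
* Only single-water bridges are counted; bond lifetimes and
  per-bond occupancies over trajectories are not computed.
* The package consumes trajectories; running dynamics, and binary
  trajectory formats, are outside the core (multi-model PDB is the
  interchange format).
* Crystallographic water retention, chain selection and ligand residue
  names vary between depositions; they are configuration
  (`analysisConfig()`), not guesses.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic
fixtures sized for exactness rather than realism: scaffolds of 6–80
residues per chain, up to 20 planted bridges against 50 decoys,
elastic networks of up to 50 nodes checked against dense linear
algebra, and four 50-frame trajectories at the recorded 2 ns cadence.
These sizes exercise every code path (binning versus exhaustive
search, multi-chi rotamer search, block bootstrap with ≥10 blocks)
while keeping every expected value computable by an independent
oracle.
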