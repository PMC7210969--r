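---
title: "Modelling mechanical stress and redox chemistry in crosslinked collagen fibrils"
author: "colmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mechanical stress and redox chemistry in crosslinked collagen fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colmech)
```

# The scientific problem

Collagen I fibrils in tendon carry sustained mechanical load. Tension is
not borne uniformly: the covalent hydroxylysino-keto-norleucine (HLKNL)
crosslinks that join the telopeptide of one triple helix to the helical
domain of its axially staggered neighbour are mechanical bottlenecks, and
homolytic scission of backbone or crosslink bonds there produces
mechanoradicals. These radicals migrate to nearby redox-active residues
(Tyr, Phe, Met, and the DOPA formed from them), are detectable by EPR
spectroscopy, and ultimately convert into hydrogen peroxide measurable
with the ferrous oxidation-xylenol orange (FOX) assay.

`colmech` implements the computational side of this picture as a
reusable, fully synthetic-data-driven pipeline:

1. a coarse-grained **D-periodic fibril builder** (`buildTopology`,
   `placeCrosslinks`),
2. an **overdamped Langevin pulling simulator** (`simulatePulling`),
3. **force distribution analysis** over bonded terms
   (`computePairwiseForces`, `windowedProfile`, `locateMaxima`),
4. **conservation mapping** of redox-active residues onto axial fibril
   slices (`sliceCounts`, `enrichmentNearCrosslinks`),
5. **radial distribution functions** of redox residues around crosslinks
   (`computeRdf`, `firstShell`),
6. a **powder EPR simulator and spectral metrics** (`powderSpectrum`,
   `effectiveG`, `peakToPeakWidth`, `signalSize`, `spinCount`),
7. **tensile arithmetic and FOX quantification**
   (`stressFromForce`, `estimateDeltaConcentration`, `twoTailedTTest`).

# The fibril model

## Geometry

The segment spans exactly one axial D-period, `D = 67` nm, with a
D-stagger of 234 residues (axial rise `D/234 ≈ 0.2863` nm per residue)
and the Hodge–Petruska overlap fraction 0.46: five staggered molecules
cross the overlap region, four cross the gap. Each triple helix is one
collagen molecule of `round((4 + 0.46) × 234) = 1044` residues (two α1
chains and one α2), placed with its N-terminus at `−s·D` for stagger
class `s ∈ {0..4}`; residues outside `[0, D]` are truncated. 37 helices
sit on a centred-hexagonal lattice with 1.3 nm spacing; the three chains
of a helix wind about the helix axis (radius 0.3 nm).

## Crosslinks

HLKNL crosslinks are rule-driven: an N-telopeptide lysine (default
sequence position 9) donates to the helical hydroxylysine at position
`9 + 4·234 = 945` of the partner staggered by 4 D (exact axial register),
and a C-telopeptide lysine (1041) to position `1041 − 4·234 = 105`. With
the default adjacency list — six lattice-neighbour helix pairs whose
stagger classes differ by four — the default segment contains exactly 12
HLKNL crosslinks, six N-terminal and six C-terminal, across six helix
pairs. The exact residue numbering of the crosslink sites is a documented
convention (the biochemical literature places the helical acceptors near
positions 87 and 930 of the mature chain; any numbering can be supplied
through `crosslinkRules`).

The packaged chain sequences are *synthetic* collagen-like chains
(Gly-X-Y repeats, collagen-typical composition, `o` = 4-hydroxyproline,
`k` = hydroxylysine at the acceptor sites, Tyr/Phe/Met enrichment near
the acceptors), generated deterministically by
`syntheticChainSequence()`; they stand in for real rat α1(I)/α2(I)
sequences, which the package deliberately does not redistribute.

## Bonded topology

Three bond types connect the beads (one bead per residue):

* **backbone** bonds between consecutive residues of one chain,
* **crosslink** bonds for each HLKNL,
* **interchain** bonds — soft diagonal springs from chain *c* residue
  *j* to chain *c+1* residue *j+1* (cyclically over the three chains),
  the coarse analogue of the one-residue interchain stagger and hydrogen
  bonding of the triple helix.

The diagonal interchain geometry is load-bearing by design: an untilted
lateral spring transmits axial force only through third-order geometric
tilting, so without the built-in stagger a molecule that terminates
inside the segment could never hand its three-chain load over through a
crosslink that sits on a single chain. Force profiles and windowed
analyses still restrict to backbone and crosslink terms.

# The pulling simulation

`simulatePulling` integrates overdamped (inertia-free) Langevin dynamics,

$$ \mathrm{d}x = \frac{F}{\gamma}\,\mathrm{d}t +
   \sqrt{2 k_\mathrm{B} T\,\mathrm{d}t/\gamma}\; \xi, $$

with harmonic bond forces and a constant external load. The observable of
interest — the time-averaged bond tension at steady state — does not
depend on inertial dynamics, which is why the overdamped integrator was
chosen over velocity-Verlet MD.

**Loading scheme.** The total load `perChainForce × nChains` enters at
the non-telopeptide chain-end beads lying at the segment's axial
boundaries (+z at the top, −z at the bottom). These are exactly the
artificially truncated molecule ends, where force would flow in from the
rest of an infinite fibril; real molecule ends (telopeptides) inside the
segment receive no direct load and are loaded only through crosslinks. A
free single chain degenerates to ±F at its two end beads. Shear loading
(`loadingMode = "shear"`) scales the per-helix share by user weights with
mean 1; the heterogeneous weight distribution itself is a user input.

**Defaults and units.** Internal units are nm, nN, ns, K. Spring constant
300 nN/nm for backbone and crosslink bonds — the covalent bond-stretching
scale (≈300–500 N/m), appropriate because these springs stand for the
covalent connections whose rupture is at issue; 50 nN/nm for the soft
interchain springs. Friction 1 nN·ns/nm per bead, 300 K, timestep
2×10⁻⁴ ns (stability ratio `k·dt/γ = 0.06`), 5×10⁵ steps = 100 ns with a
frame every 0.2 ns and the first 10 % of frames excluded as
equilibration — the 10/100 ns equilibration-to-production split of the
pulling protocol this emulates. On the 20-bead single-chain oracle these
defaults give a blocked standard error of the mean bond force of ≈1.5 %
of the applied 1 nN, below the 2 % design target.

**A finite-temperature subtlety.** The scalar bond force is
`k(|r| − r₀)`, and `|r|` exceeds the axial projection whenever the bond
fluctuates transversely. The resulting anharmonic (Jacobian) excess is
about `2k_BT/r₀ ≈ 0.03` nN for an unloaded bond and ≈0.01 nN under 1 nN
tension — *independent of the spring constant* and well below the thermal
force noise `√(k_BT·k) ≈ 1.1` nN at covalent stiffness. The tests treat
it as a documented bound: a pulled chain reproduces the applied force
within three standard errors, and the unloaded control is negligible
(<0.05 nN) on the applied-force scale rather than identically zero. At a
soft residue-level spring constant (≈50 nN/nm) the excess would rival the
standard error and these statements would fail; this motivated the
covalent-scale default.

**Rupture checking.** No bond scission is modelled (kinetic Monte Carlo
approaches are out of scope); instead any recorded frame in which a bond
exceeds `ruptureLength` (default 3 nm) raises a flag on the trajectory
without aborting the run.

# Force distribution analysis

`computePairwiseForces` evaluates, for every bond and retained frame, the
signed scalar force `k(|r_i − r_j| − r₀)` (tension positive, compression
negative — the sign convention is a package choice) and records its mean,
standard deviation and frame count. Newton-pair symmetry is structural:
`pairForce(x, i, j)` and `pairForce(x, j, i)` read the same entry.
`diffForceTables` subtracts a control table entrywise with variance
propagation.

`windowedProfile` averages backbone bond forces in overlapping windows of
`w = 10` consecutive residues (step 1) along the reference chain of each
crosslink-connected helix pair — the chain spanning the full D-period
(the N-crosslink donor side) — and places each crosslink bond force at
its attachment residue so that it enters the covering windows. The
aggregate mean carries a standard error computed across the pairs, not
across frames. `locateMaxima` ranks window centres by force (ties broken
by ascending position) and reports each centre's distance to the nearest
crosslink of a chosen terminal.

**What the coarse model does and does not reproduce.** On the packaged
fixture simulation the profiles show (i) telopeptide bonds off the
crosslink path carrying a small fraction of the helical-backbone force,
and (ii) window maxima adjacent to crosslink attachments exceeding the
gap-region window level — the qualitative signature of stress
concentration at crosslinks. The model does *not* reproduce the stronger
N-terminal (versus C-terminal) concentration seen in atomistic work: in
the bead-spring segment the N-side hand-over runs through the soft
telopeptide arm, which takes less flux than the C path; recovering the
N-preference appears to require atomistic lateral packing. Analyses
comparing crosslink-proximal and gap-region forces therefore do so along
the same profile.

**Fixture sizes.** Trajectory-based tests run on a geometrically scaled
segment (`miniFibrilTopology`: 40-residue stagger, 7-helix bundle, two
crosslink-eligible pairs, 12→4 crosslinks) simulated for 60 ns with the
final third averaged — the scaled segment needs ≈40 ns to take up
crosslink and telopeptide slack before the bond-force flow is
quasi-steady. The full 37-helix default segment is used for the
topology-level checks and for the force-monotonicity sign check at short
simulation times.

# Conservation mapping

`sliceCounts` divides the fibril axis into slices spanning ten residues
of axial extent, advancing one residue at a time (a moving average), and
for each slice sums the occurrences of each residue class (Tyr = {Y},
Phe = {F}, Met = {M}, and their union) across all sequences of the MSA at
the columns mapping into the slice, over all chains crossing the slice,
divided by the number of sequences. Residues are assigned to slices by
axial coordinate from the topology, so all three chains of each helix and
all helices in the cross-section contribute. Raw mean counts are
reported without density correction for the gap region (counts, not
densities, are the observable). With non-overlapping slices the counts
conserve total class mass exactly, which the tests verify against a
direct tally.

`enrichmentNearCrosslinks` is a quantification device of this package
(not a published test): the ratio of mean counts in slices within a
radius of any crosslink site to the mean elsewhere, with a circular-shift
permutation p-value. By default every circular shift is enumerated, so
the null is exact and deterministic; a seeded random subset is used only
when `nPerm` is smaller than the number of shifts.

Synthetic MSAs (`generateMsa`) emulate the vertebrate COL1A1/COL1A2
alignments: gapless sequences of the reference length, a planted residue
class appearing at chosen positions with a set enrichment probability,
and background substitutions elsewhere. They do not emulate gaps,
phylogenetic correlation between sequences, or rate variation — so
passing tests demonstrate correct counting and localisation, not
robustness to alignment artefacts.

# Radial distribution functions

`computeRdf` histograms centre–target distances and normalises by the
ideal-gas expectation `g(r) = n(r) / (N_c · V_shell(r) · ρ)`, with the
target density ρ taken in a normalisation volume defaulting to the
coordinate bounding box inflated by `r_max` (no periodic boundary — the
fibril is laterally finite). Defaults: 0.05 nm bins to 3 nm. Because the
reference-density convention is a choice, only the shape and the onset of
the first shell (`firstShell`, strict `g(r) > threshold`) are asserted,
not absolute g values. Site positions are bead (residue-centroid)
coordinates, a documented fidelity gap relative to side-chain atom
positions.

# EPR simulation and metrics

The resonance condition `B = hν/(gμ_B)` uses CODATA constants kept in one
internal table; fields are mT internally, linewidths accepted and
reported in Gauss (1 mT = 10 G).

`powderSpectrum` averages the resonance field of
`g(θ,φ) = √(g_x²sin²θcos²φ + g_y²sin²θsin²φ + g_z²cos²θ)` over a
deterministic Gauss–Legendre product grid in `(cosθ, φ)` on one octant
(default 64×64; doubling the grid changes the spectrum by <1 % of peak,
which a test enforces), bins the weighted sticks onto the field axis,
and convolves with a Gaussian (σ = ΔB_pp/2) or Lorentzian
(HWHM = √3·ΔB_pp/2) lineshape; derivative mode convolves with the
analytic kernel derivative. Spectra are normalised to unit maximum
absolute intensity. Hyperfine structure is omitted throughout — the
observed signals resolve none — and field modulation is treated as an
ideal derivative (0.2 mT modulation amplitude ≪ linewidth).

Metrics: `signalSize` (max − min intensity, the cw-EPR amplitude
measure), `effectiveG` (zero-crossing field between the derivative
extrema, linearly interpolated), `peakToPeakWidth` (extrema separation in
G), `spinCount` (double-integral ratio against a reference of known spin
count), and `smoothSeries` (cubic smoothing spline, `spar` stiffness).
Round-trip recovery — simulate an isotropic line at the non-stressed
tendon parameters (g = 2.007, ΔB_pp = 10 G, 9.4 GHz) and re-measure
g ± 0.001 and width ± 0.5 G — is part of the acceptance suite.
`dopaAnionGTensor()` ships a representative axial placeholder
(g⊥ = 2.0050, g∥ = 2.0023) in the phenoxy-radical range; it is
user-supplied by design and no test asserts agreement with a published
tensor.

# Tensile arithmetic and FOX quantification

`stressFromForce` is `F/A` (N over mm² is MPa). `forceFromMass` uses
g = 9.8 m/s², the rounding that makes 350 g correspond to 3.43 N exactly
as printed (9.80665 gives 3.432 N, identical at that precision).

`generateFoxPlate` builds paired pulled/untreated absorbance wells at
595 nm from a linear calibration `A = intercept + slope·c + ε` with the
pulled concentration offset by a planted Δ. Defaults: slope 0.03 A₅₉₅/μM
and intercept 0.04 (a kit-like sensitivity; the real calibration curve is
instrument-specific and not redistributed), untreated baseline 2 μM,
well noise σ = 0.001 A₅₉₅. The noise models plate-reader replicate
precision only — biological spread between samples, which dominates real
error bars, is deliberately absent, so recovery tests demonstrate
correct inversion and error propagation, not assay-level power.
`estimateDeltaConcentration` inverts the calibration per time point and
propagates well-level variance; the estimate is invariant to a common
absorbance offset. `twoTailedTTest` wraps the pooled-variance two-sample
t-test with the plate star convention (** p<0.01, *** p<0.001) and
defines the degenerate zero-variance cases explicitly (equal means:
t = 0, p = 1; unequal: p = 0 sentinel with infinite t).

# Numerical choices and degenerate inputs

* Boundary sites exactly on a slice or bin edge belong to the following
  slice/bin, with a 10⁻⁹ tolerance absorbing floating-point error in the
  axial coordinates.
* `windowedProfile` with `w = 1` returns the raw per-bond series; `w`
  longer than the chain is a validation error; flat profiles break ties
  by ascending position.
* `firstShell` uses strict inequality: a profile exactly at the
  threshold returns the none-sentinel (`NULL`).
* `enrichmentNearCrosslinks` reports `Inf` when all class mass lies
  within the radius and the outside mean is zero.
* Empty topologies write valid (zero-record) PDB and table files and
  round-trip to zero counts.
* The Langevin integrator raises an error naming the timestep when
  coordinates diverge to non-finite values.

# Known limitations

* One bead per residue: no side chains, no solvent, no electrostatics,
  no bond scission chemistry; crosslink and backbone mechanics are
  harmonic.
* The boundary-loaded single-period segment reproduces crosslink-proximal
  force concentration and telopeptide shielding but not the N-over-C
  crosslink asymmetry (see above), and absolute force levels at the
  segment boundary depend on the anchor bookkeeping.
* Synthetic MSAs and plates are idealised generators; they validate the
  analysis code, not field data quality.
* The EPR module simulates g-tensor powder patterns only: no hyperfine,
  no pulse-sequence physics, no temperature dependence or saturation.

# Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` rebuilds the default
fibril (crosslink count and axial span), simulates and re-measures the
X-band line (effective g and width), runs the 20-bead 1 nN pulling oracle
through the force-distribution module, and recovers the planted 1 μM
offset from a fresh synthetic FOX plate, writing all values as JSON. All
randomness derives from `--seed`.
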