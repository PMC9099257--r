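---
title: "The gREST/REUS protocol on bead-model binding systems: models, tuning, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gREST/REUS protocol on bead-model binding systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and intent

`grestreus` implements two-dimensional replica exchange — solute tempering
(gREST) crossed with umbrella sampling along a protein–ligand distance
(REUS) — together with the practical protocol around it: collective-variable
design, pulling-based initialization, automatic ladder tuning, window tuning,
and sampling diagnostics.  Production applications of this method are
all-atom, solvated, hundreds-of-replicas affairs; this package deliberately
replaces the molecular mechanics with smooth analytic bead-model potentials
so that the *protocol machinery* — exchange criteria, schedulers, tuners,
diagnostics — can be validated end to end against closed-form expectations on
a desk.  Nothing in the exchange or tuning layer knows it is driving a toy
engine.

# The energy model

A system is a set of beads with roles (`protein`/`ligand`) and the following
terms, all smooth and analytic everywhere:

* harmonic tethers on protein beads, E = k·d² (default k = 1 kcal/mol/Å²) —
  the protein is elastic rather than frozen, so anchor-site fluctuations and
  pulling-induced deformation are meaningful observables;
* bonds E = k_b (r − r₀)², angles E = k_a (θ − θ₀)², and cosine dihedrals
  E = k_d (1 + cos(mφ − δ)) for multi-bead ligands;
* nonbonded pair terms: an attractive Gaussian well −ε·exp(−r²/2w²) plus a
  soft-core repulsion A·(σ²/(r²+σ²))⁶, finite (= A) at r = 0.  Both are
  functions of r², so forces need no cutoff bookkeeping and stay exact under
  differentiation;
* half-harmonic box walls (k = 10 kcal/mol/Å²) starting at the wall planes,
  standing in for a periodic solvent box.

**Harmonic convention.** Every harmonic term uses E = k·x² with *no* factor
½.  Both conventions circulate in MD codes; this one is stated on each help
page and in `inst/FORMAT.md` because force constants quoted here (pulling
k = 4, windows k = 2–4, protein restraints k = 1 kcal/mol/Å²) are meaningful
only relative to it.  Under this convention an umbrella at force constant k
has stationary CV variance k_B·T/(2k) — at 310 K and k = 2 kcal/mol/Å²,
0.15401 Å² (σ ≈ 0.392 Å), the closed form the oracle tests lean on.

**Units.** Å, kcal/mol, ps, K, amu; k_B = 0.0019872041 kcal·mol⁻¹·K⁻¹;
1 kcal/mol = 418.4 amu·Å²/ps².

## The solute partition

gREST scales a "solute" region: each energy term is classed `uu` if all its
beads are solute-flagged, `vv` if none are, `uv` otherwise, and the scaled
Hamiltonian is λ·E_uu + √λ·E_uv + E_vv + E_restraint with λ = T₀/T_m (REST2
convention for cross terms).  Two boundary cases needed a decision:

* *Tethers* are single-bead terms and follow their bead's flag: a tether on a
  binding-site (solute) bead scales as λ·k, so heated replicas genuinely
  loosen the pocket — the point of solute tempering.
* *Box walls* are always `vv`: they model the container, and the oracle
  system below relies on a solute whose energy is identically zero.
* *Restraints* (umbrella, pulling, positional) are never scaled and are
  reported separately; they cancel exactly in the gREST exchange criterion.

Dihedral and nonbonded solute terms are scaled identically — the partition is
defined by term membership, not term type.

# The synthetic systems

`build_system()` provides four deterministic presets.

`pocket_small` is the workhorse: two anchor/base beads (the protein end of
the CV), two 4-bead binding-site rings (the gREST solute) forming a pocket
around a channel, one off-axis trap bead, and a single-bead ligand.  The
minimized bound pose sits on the channel axis at CV ≈ 3.0 Å with a well
≈ 4.6 kcal/mol (≈ 7.5 k_BT at 310 K) deep relative to the unbound plateau; a
shallow metastable trap sits near CV ≈ 9; interactions are negligible beyond
CV ≈ 11.  The preset's `cv_range` of 3–12 Å is therefore its designed
bound-to-unbound span, while the box admits CV values above 20 Å.  One
geometric subtlety: a ring of Gaussian wells has an on-axis minimum only if
the ring radius is below about √2·w; the rings use radius 2 Å at w = 2 Å so
the designed pose is a true axial minimum (`verify_bound_pose()` checks the
analytic gradient, and a steepest-descent oracle confirms it in the tests).

`pocket_flexible` replaces the ligand with a 4-bead bonded chain (bonds,
angles, one 3-fold dihedral) whose tail can reorient at fixed CV — the
stand-in for a large flexible inhibitor, used by the CV-scoring experiments.

`flat_channel` is the exactly solvable oracle: one free ligand bead, two
*frozen* anchor beads (fixed reference sites, the standard fixed-atom device;
they carry no potential), zero interaction terms, and a box that is
degenerate (lo = hi) in y and z.  The interior potential is identically zero
and the CV is |x − x_anchor| up to O(10⁻³ Å) corrections — small enough that
a Kolmogorov–Smirnov test at n = 10⁴ cannot see them, which is what makes the
closed-form window Gaussians an honest oracle.  A fully 3D distance CV would
carry an r² Jacobian that the same test *would* detect; the degenerate
channel is a design choice, not an accident.

`double_well_1d` puts two frozen attractor sites of unequal depth along the
channel, for two-state experiments.

The generator emulates: a designed bound pose, a binding funnel with an
intermediate trap, a solute region, elastic anchor sites, and bound/unbound
geometry on the scale typical of kinase–inhibitor setups (bound ≈ 3 Å, box
supporting CV ≈ 20 Å).
It does **not** emulate: explicit solvent and friction anisotropy,
electrostatics, rugged all-atom energy landscapes, slow protein
conformational gating, or ligand internal barriers of realistic height.
Passing tests therefore certify the *machinery* (exchange correctness,
tuner contracts, diagnostic bookkeeping) and the protocol's behavior on
funnel-like landscapes — not quantitative transferability of any tuned
parameter to a real kinase system.

# Dynamics

`propagate()` integrates BAOAB Langevin dynamics (default dt = 0.01 ps,
γ = 1 ps⁻¹), chosen for its accuracy in *configurational* averages at coarse
time steps.  The thermostat temperature is T₀ = 310 K for every replica;
solute temperature enters only through λ.  Equipartition and the umbrella
variance law are asserted in the tests at 3-standard-error/5% tolerance.

Noise streams are counter-based: each propagation segment draws from a
splitmix64 stream seeded by hash(master seed, replica id, segment counter),
with Box–Muller normals.  Exchanges swap parameter indices and never touch
streams, so a replica's noise sequence is reproducible regardless of the
exchange history, and velocities need no rescaling (all replicas share T₀;
the kinetic term cancels in both exchange criteria).

# The exchange layer

Attempts follow a period-4 schedule — (gREST, even), (REUS, even),
(gREST, odd), (REUS, odd) — one concrete realization of alternating
dimensions; 1D runs alternate parity with period 2.  Within a phase, even
parity attempts pairs (1,2), (3,4), … and odd parity (2,3), (4,5), … along
the active dimension at every fixed index of the other dimension.  A pair's
"attempted" count increments only when its parity phase is active; this
denominator convention is recorded here because acceptance ratios depend on
it.  Every attempt is logged with its (Δ, u) pair, so any acceptance
statistic can be replayed exactly from the serialized log — the tests assert
bit-exact replay, which makes the scheduling convention auditable.

# Tuning protocols

## Solute temperatures

`retarget_ladder()` implements cost-density equalization: pair cost
c_m = −ln max(a_m, ε) (ε = 10⁻³ keeps dead pairs finite), spread as a
piecewise-constant density over ln T; the new total range satisfies
Σc = (M−1)(−ln target), extrapolating the last density when the ladder must
grow (growth capped at 3× the log-range per call), and new temperatures sit
at equal-cost quantiles.  The bottom temperature and the replica count never
change; a ladder is a fixed point exactly when every pair meets the target.
An all-but-bottom and a top-only mode are both provided (default:
all-but-bottom, which is what the equal-cost quantiles naturally give).

For near-harmonic solute energy the cost is close to *quadratic* in the
log-spacing, which makes the raw update a neutrally stable map (of the form
x → A/x): iterating it oscillates around the target instead of settling.
`tune_temperatures()` therefore applies the proposal with a
stochastic-approximation step schedule (fraction 1/(r+1) of the proposed
log-step in round r): for exactly quadratic cost the first half-step lands on
the fixed point, and the shrinking steps damp measurement noise in later
rounds.  Each round runs 1D-gREST at a fixed umbrella (defaults: bound,
intermediate, and unbound centers; k = 2 kcal/mol/Å²) with the attempt period
ramping 0.21 → 2.1 ps over five rounds; by default every round gets a
constant number of attempt phases (150), so late rounds — which decide the
final ladder — are not starved of statistics.  The final ladder is the
element-wise mean over the tuned states.  At desk-scale statistics the
per-round acceptance estimates carry ~0.04 standard error, so the last rounds
still jitter the top rung by ~10–25%; the *contract* (validation acceptance
within ±0.05 of the 0.2 target) is nonetheless met robustly, because the
acceptance surface is flat near the optimum and the three-state average
cancels much of the noise.

## Umbrella windows

`tune_windows()` consumes a 1D-REUS trial at one solute temperature and
applies three rules: (a) adjacent pairs with histogram overlap < 0.03 or
acceptance < 0.05 get a midpoint window inserted at their neighbors' maximum
force constant; (b) CV intervals where the pooled ("united") density falls
below 10% of its mean are flagged as gaps — there the force constant
escalates along {2, 3, 4} kcal/mol/Å² (a continuous ×1.5 mode exists behind
`continuous_k`), both for inserted midpoints and for existing windows inside
the gap, since stiffer umbrellas are the tool against the free-energy
gradient that empties a region, while on gap-free terrain they would only
narrow distributions and hurt overlap; (c) windows are never removed.
Histogram binning is 0.1 Å throughout.  Thresholds are deliberately
conservative: the tuner fires on clearly broken pairs and leaves marginal
ones to the second dimension of the 2D run.

# Pulling initialization

`pull()` drags the ligand through an ordered list of CV targets (equidistant
by default) with a stiff umbrella (k = 4 kcal/mol/Å², 30 ps per step at desk
scale), storing each step's final frame as that window's initial structure;
`dual_pull()` runs forward (out of the pocket) and reverse (back in, starting
from the last forward frame — the default answer to an otherwise open
choice), giving two distinct initial pathways.  Positional restraints
(k = 1 kcal/mol/Å²) on the non-frozen protein beads prevent the pull from
deforming the protein; with tether + restraint each protein coordinate has
variance k_BT/(2(k_t+k_r)), so the instantaneous protein RMSD stays near
√(3k_BT/4) ≈ 0.7 Å, the bound asserted in the tests.  A step that ends more
than 1 Å from its target records a warning in the result rather than
failing — exactly the situation the force constant was raised to avoid.

# Diagnostics

`acceptance_profile()` (cumulative and windowed variants; undefined — never
zero — for unattempted pairs), `visitation()` (per-replica occupancy with
Shannon entropy normalized by ln of the index count so 1 = uniform),
`round_trips()` (full end-to-end-and-back traversals),
`reus_distribution_report()` (per-window and united histograms, overlap
coefficients Σ min(p_a, p_b), flagged gaps), and `hit_ratio()` (percentage of
replicas whose ligand RMSD to the bound pose drops strictly below 1 Å at
least once; the 1.5 Å sensitivity variant is a parameter).  Ligand RMSD uses
mass-weighted Kabsch superposition on all protein beads before an unfitted
RMSD over the ligand selection — the fitting convention is configurable
because the field does not standardize it, but this default is applied
consistently everywhere.

# CV candidate scoring

`score_cv_candidates()` quantifies what makes a distance CV good for a
flexible ligand: (a) the conditional spread of ligand RMSD given the CV
(mean interquartile range over 1 Å CV bins — narrow means the CV resolves
the pose), (b) the bound-pose probability (replicas reaching RMSD < 1 Å at
least once), (c) the anchor-COM RMSF (a floppy anchor degrades the CV).
Candidates are ranked by hit probability, ties broken by conditional spread.
On the flexible preset the all-bead ligand COM beats a single terminal bead
on conditional spread, the qualitative finding the protocol builds on.

# Numerical choices and degenerate inputs

* Metropolis accepts Δ ≤ 0 unconditionally; u is drawn from a dedicated
  hashed counter stream, independent of R's global RNG.
* CV gradient at coincident COMs (ξ < 10⁻⁸ Å) is defined as zero.
* Angle forces guard sin θ ≥ 10⁻⁶; dihedral forces skip degenerate
  (collinear) geometries.
* `retarget_ladder` floors acceptances at 10⁻³, caps them just below 1, and
  enforces strict monotonicity with a 10⁻⁶ log-spacing floor.
* Histogram overlap requires identical breaks; mismatches are errors, not
  silent rebinning.
* The reference-pose minimizer is L-BFGS-B on the analytic gradient
  (pgtol 10⁻⁸); `verify_bound_pose` reports the Euclidean gradient norm with
  a 10⁻³ kcal/mol/Å pass threshold.

# Problem sizes

The shipped experiments are sized for a single CPU: tuning rounds of 150
attempt phases (≈ 30–315 ps per round per replica), validation segments of
2000 attempt phases (5000 pair attempts), window trials of 400–800 phases,
and 2D runs of 90 replicas × 160–1600 phases.  These sizes were chosen so
that acceptance estimates carry standard errors well below the ±0.05
contract bands while the whole suite stays desk-scale.

# Known limitations

* The toy landscape's barriers (≈ 7.5 k_BT) are tunable constructions, not
  fits to any real complex; hit ratios and round-trip counts here are far
  more favorable than all-atom values.
* The cost-density tuner assumes exchange cost accumulates smoothly over
  ln T; systems with phase-transition-like acceptance cliffs would need more
  rounds or manual per-round targets (supported via a target schedule).
* No reweighting (WHAM/MBAR) or free-energy estimation is included — the
  package measures sampling efficiency, not thermodynamics.
* Exchanges are neighbor-only and synchronous; no global or asynchronous
  exchange schemes.
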