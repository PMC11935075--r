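---
title: "Methods: coarse-grained ligand egress, channel statistics and permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained ligand egress, channel statistics and permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A quinol-like redox carrier bound inside a ring of light-harvesting
subunits must cross that ring to reach the membrane pool.  The crossing is
rare on plain molecular-dynamics timescales, so egressr combines three
layers: (1) an enhanced-sampling controller (S-RaMD-MD) that drives egress
and identifies *which* inter-subunit channel the ligand uses and in which
orientation (head-first or tail-first); (2) umbrella sampling along an
xy-projected reaction coordinate, combined with WHAM, to quantify the free
energy of the favoured route; and (3) the inhomogeneous solubility-diffusion
model turning a potential of mean force (PMF) and a diffusion profile into a
permeability coefficient.  Everything runs on coarse-grained toy systems
generated by the package itself, so each layer can be validated against
closed forms and unbiased Boltzmann statistics.

# The toy systems

`build_quinol_chain()` builds the ligand: a hexagonal six-bead "aromatic"
head ring plus a linear tail (default 24 beads, free parameter since only
the group roles matter).  One bead represents a cluster of heavy atoms
(12 amu, carbon-like); the bonded model is harmonic bonds and harmonic
angles only — enough to give the chain its elongated, flexible
phenomenology without any force-field machinery.  Three groups are
labelled: the head ring, the last six tail beads (`tail_tip`), and a
five-bead `mid_tail` window at the middle of the tail whose centre of mass
defines the dissociation criterion.  The window is centred because the
tracked segment sits in the middle of the real molecule; it is shifted
head-wards when it would overlap `tail_tip`, and tail lengths below 11
are rejected because no disjoint placement exists.

`build_ring_system()` arranges `n_subunits` (default 16) repulsive sites on
a circle (default radius 15 Å) inside a membrane slab (default z in
[-12, 12] Å).  Subunit sites act as smooth Gaussian rods in the xy plane
(strength 6 kcal/mol, range 2 Å), so the gaps between them are pores; a
Gaussian binding well (default depth 3 kcal/mol, width 3 Å) sits at the
centre.  Flat-bottom harmonic walls (10 kcal/mol/Å²) confine beads to the
slab — free motion inside, a linear restoring force outside.  The open
variant removes two adjacent subunits and merges the freed arc into a
single pore labelled `"Gap"`, a minimal stand-in for the
protein-W-mediated opening; with 16 subunits this leaves 13 ordinary
pores plus the Gap.  For channel assignment every azimuth is owned by
exactly one pore: a subunit sector belongs to the pore counterclockwise of
it, which is also the documented boundary tie-break.

Units are Å, kcal/mol, amu and ps throughout; thermal energy enters as
`k_B T` with `k_B = 0.0019872041` kcal/mol/K.

# Dynamics engine

`run_md()` integrates Langevin dynamics with the BAOAB splitting, chosen
for its accurate configurational sampling at moderate timesteps; at zero
friction it reduces to velocity Verlet, which gives the energy-conservation
oracle used in the tests.  Defaults: 300 K, friction 1 ps⁻¹, timestep
0.001 ps.  There is no constraint algorithm; bonds are soft
(50 kcal/mol/Å²) and integrated directly.  Forces are computed in
compiled code; all noise flows from R's RNG, so a `(seed, configuration)`
pair reproduces a trajectory bitwise on one platform.

Durations are expressed in *engine nanoseconds*, mapped to steps through
the single `steps_per_ns` constant (default 10⁶ steps, i.e. 1 ns of
0.001 ps steps).  Toy kinetics are not atomistic kinetics, so studies are
free to choose a coarser mapping; the package's own tests and the
acceptance script use 10³–10⁵ steps per engine-ns, which keeps every
statistical check well-converged on one CPU in minutes while exercising
identical code paths.

# The S-RaMD-MD controller

Conventional random-acceleration MD pulls a ligand's centre of mass away
from a protein reference and switches the force off beyond a distance
threshold.  For an elongated amphiphilic ligand in a ring that design
stalls: the whole molecule cannot be accelerated through a narrow pore.
The self-referenced variant implemented here changes three things:

* the force group is one *end* of the molecule — the head ring or the tail
  tip — selecting head-first or tail-first egress;
* the reference is the ligand's **own** centre of mass, and the distance
  bound `D` must exceed the molecular length.  Since the force group is
  part of the ligand it can never reach `D`, so the force never
  self-terminates; the chosen end is driven persistently away from the
  molecular centre.  `D` is validated against the built chain and kept as
  an audited no-op bound;
* flat-bottom membrane walls keep the accelerated group from escaping
  through the slab faces, so egress can only happen through the ring.

The force has magnitude `a · m_group` (with `a` in kcal Å⁻¹ g⁻¹ read as a
per-mass acceleration on the per-mole energy scale, so the force in
kcal/mol/Å is `a` times the group mass in amu) and is distributed over the
group beads proportionally to mass.  Progress is evaluated every
`eval_window` steps (default 100): the default metric is the change of the
force-group-COM-to-ligand-COM distance, the only reading under which a
self-COM reference participates in the stall test; the full 3D group-COM
displacement is available behind `displacement_metric = "absolute"`.
Below the threshold `d` the direction is redrawn uniformly on the unit
sphere (normalised Gaussian triples).  Biased windows alternate with
`md_relax_steps` (default 400) of unbiased relaxation; the stall test is
applied at every phase boundary, which keeps the audit invariant
"redrawn ⇔ displacement < d" exact across the whole log.  The precise
alternation cadence of the original hybrid scheme is not publicly
specified, so both knobs are configurable and `md_relax_steps = 0`
recovers pure RaMD.

A dissociation event is the first time the `mid_tail` centre of mass lies
radially outside the subunit ring while still inside the slab, within the
event window (default 10 engine-ns); leaving through a slab face does not
count.  `plan_campaign()` expands the acceleration grid
{0.3, 0.35, 0.4, 0.45, 0.5} × threshold grid {0.3, 0.4, 0.5} × 3 starting
snapshots into 45 runs per mode (90 for both modes; adding an open-ring
tail-only campaign gives 135 runs and 1350 planned engine-ns), with
deterministic per-run seeds.  `channel_probabilities()` turns events into
per-channel percentages (one-decimal rounding, descending counts);
undissociated runs are tallied separately and never enter the denominator,
and an externally supplied denominator that disagrees with the counts is
surfaced as a warning rather than corrected.

On the default bound toy system the controller reproduces the qualitative
dose response expected of the method: no escapes at the bottom of the
acceleration grid and certain escape at the top, with a monotone
probability in between — the property the test suite checks with twenty
seeds per grid point.

# Umbrella sampling, WHAM and convergence

The reaction coordinate is `project_xy()`: the xy-plane distance between
the head-ring centroid and a fixed anchor, ignoring z entirely, because
lateral motion along the membrane plane carries the egress.  Windows hold
a harmonic bias `½ k (ξ - ξ₀)²`; on the toy system the bias acts on the
head-ring COM through the chain rule with mass weighting.  Each window
discards a leading equilibration fraction (default 1/6) and reports
adjacent-window histogram overlaps, warning below 5 %.  For a flat
landscape the window histograms are Gaussians of width `sqrt(kT/k)`, so
the expected neighbour overlap has the closed form `2Φ(-Δ/(2σ))`; the
tests pick `k = 4` kcal/mol/Å² at 1 Å spacing (≈ 19 % overlap) for the
positive control and `k = 10⁴` for the guaranteed-failure control.

`wham_solve()` is a standard self-consistent WHAM: bin the window samples
(default 0.2 Å bins), iterate the window free-energy constants until the
largest change falls below 10⁻⁷ kcal/mol (cap 10⁵ iterations; failure to
converge is an error, not a silent return), assemble the unbiased
probability and `F = -k_B T ln p`, min-normalised.  Empty bins interior to
the sampled range are reported by position.  Pointwise standard errors
come from a block bootstrap over contiguous sample blocks (default 10
replicates × 10 blocks).  A single window with zero spring constant
degenerates to the plain Boltzmann histogram, which is also the
independent oracle: the central validation property is that WHAM from
biased sampling on an analytic double well matches the long unbiased
Boltzmann estimate of the same engine to well under 0.3 kcal/mol.

`check_convergence()` recomputes the PMF on cumulative time slices and
reports successive deviations; the default "converged" threshold is
0.5 kcal/mol on the final deviation.  `apply_endpoint_offset()` re-anchors
a profile by a rigid linear tilt so that `F(end) - F(start)` equals an
externally computed two-end-state free-energy difference (for example
-13.70 kcal/mol from an MM/GBSA-style calculation, which is an *input*
here, not something the package computes); interior curvature is
preserved exactly and the operation is idempotent.  `barrier_height()` is
the forward definition: the largest climb from any preceding minimum
within the range.

# Diffusion and permeability

`estimate_diffusion()` uses the positional-autocovariance estimator on
stationary biased-window samples, `D = var(ξ)² / ∫⟨δξ(0)δξ(t)⟩dt`, with
the integral truncated at the first zero crossing of the autocovariance —
equivalently `var/τ_int`.  The estimator is validated against the
Einstein relation `D = k_B T/(mγ)` in a strongly overdamped harmonic well
(20 % tolerance) and against a discrete-sum oracle on white noise.
Non-decaying autocorrelation and constant series give an
unreliable-estimate warning, never a silent number.  The method is a
deliberate, pluggable choice: the original methodology is cited rather
than specified, and the positional-autocovariance form is the standard
reading for restrained-window data.

`permeability()` evaluates `P = [∫ exp(βF(ξ))/D(ξ) dξ]⁻¹` by trapezoidal
quadrature with the PMF first referenced to zero at the bulk end of the
range — the step that makes the result exactly invariant to additive
constants in F.  With grids in Å and D in Å²/ns the conversion is
1 Å/ns = 10 cm/s.  Closed-form checks: a flat profile gives `D/L` to
0.1 %, and a square barrier gives `D/((L-w) + w·e^{βB})` to 0.5 % at the
default grid density.  `percent_increase()` is the small ratio utility
used to compare two routes (for the published pair 0.043 and
0.060 cm/s it reports a 39.5 ≈ 40 % increase).

# Interaction detectors

The geometric detectors operate on any labelled coordinate trajectory
(toy frames, or multi-MODEL PDB / XYZ read by the package), so they are
useful beyond the toy engine.  No cutoffs are canonical in the source
material, so the defaults follow common structural-analysis practice and
are all configurable: hydrogen bonds at donor-acceptor ≤ 3.5 Å and
donor-H-acceptor ≥ 150° (with the hydrogen inferred along the
donor→acceptor axis when not explicit); π-stacking at centroid ≤ 5.5 Å,
inter-plane angle ≤ 30° and lateral offset ≤ 2.0 Å, with 60–90° flagged
separately as T-shaped; single-water bridges with both legs ≤ 3.5 Å
(two-water chains are deliberately out of scope).  Ring planes come from
an SVD; near-collinear ring atoms are a geometry error.  All detectors
are rigid-motion invariant (tested to 10⁻⁹ under random rotations and
translations) and occupancy of a contact present in k of n frames is
exactly k/n.  Occupancy classification thresholds ("stable" versus
"low-occupancy") are left to the user; the package reports raw fractions.

# Numerical and design choices

* Harmonic energies are `½ k x²` everywhere (bonds, angles, walls, bias);
  the wall force at 1 Å beyond a 10 kcal/mol/Å² boundary is therefore
  -10 kcal/mol/Å.
* Channel labels are plain ASCII `"i-j"`; the boundary tie-break assigns a
  subunit-edge azimuth to the pore counterclockwise of the subunit.
* The open-ring pore count follows the merge rule: removing two adjacent
  subunits of a 16-ring leaves 13 pair pores plus the Gap.  The Gap is by
  construction the widest sector.
* WHAM profiles are evaluated wherever samples fall; flat-landscape
  recovery is assessed across the window-centre span, where sampling is
  dense by design.
* Displacements under the radial stall metric may be negative (the group
  moved inward); a negative displacement is always below threshold and
  triggers a redraw, and the signed value is kept in the audit log.
* Per-run campaign seeds are `base_seed + 7919·run_id` reduced modulo
  2³¹ - 1: deterministic, distinct, and safely inside R's integer range.

# What the toy generator does and does not emulate

The generator reproduces the *structural logic* of the problem — an
elongated two-ended ligand, a ring of subunits with pores, a binding
well, a membrane slab with soft walls, an opening that merges pores — and
therefore lets every algorithmic claim (force accounting, redraw
semantics, channel partitioning, WHAM self-consistency, permeability
quadrature) be tested exactly.  It does not emulate atomistic
interactions, solvent, lipid chemistry, or the real ring's asymmetric
subunit contacts; absolute barrier heights, event times and channel
preferences of the toy are properties of the toy.  Passing tests
therefore certify the correctness of the machinery, not the biology:
applying the pipeline to a real system requires supplying realistic
coordinates and interaction models through the same interfaces.

# Problem sizes used by the shipped checks

The test suite and the acceptance script run, per invocation: biased
double-well sampling of 17 windows × 2×10⁵ steps plus a 5×10⁶-step
unbiased oracle; a 100-run controller dose-response sweep at 10⁴ steps
per engine-ns with a 10-ns window; and 4×10⁵-step thermostat checks.
These sizes were chosen so each stochastic assertion sits several
standard errors away from its threshold while the whole suite completes
in a few minutes on a single CPU.

# Known limitations

* No electrostatics, no pressure coupling, no constraint algorithm; the
  engine is serial.
* WHAM only (no MBAR generalisation); bootstrap errors assume block
  lengths long compared to the correlation time.
* The diffusion estimator needs well-resolved autocovariance decay;
  strongly underdamped coordinates bias it.
* The two-end-state endpoint offset is a user-supplied constant; the
  package deliberately contains no implicit-solvent free-energy method.
* One-bead-per-cluster coarse-graining has no chemical specificity; head
  versus tail asymmetry enters only through geometry and group labels.
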