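---
title: "Methods: well-tempered metadynamics on toy binding landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: well-tempered metadynamics on toy binding landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtmetad)
```

# Scope and model

`wtmetad` reimplements, at desk scale, the computational chain used in
enhanced-sampling studies of ligand binding to four-fold-symmetric
receptors such as parallel G-quadruplex DNA: biased sampling along
geometric collective variables (CVs), recovery of the free-energy
surface (FES) from the accumulated bias, reweighting onto CVs that were
not biased, and extraction of basin depths, barriers and the binding
free energy. The molecular dynamics layer of such studies (all-atom
force fields, explicit water, ions) is replaced by overdamped Langevin
dynamics on analytic landscapes, and the DNA/ligand pair by a bead
model. Everything downstream of the sampler is the same machinery a
practitioner would apply to real simulation output, which is the point:
on synthetic systems every estimator can be compared against an exact
quadrature oracle.

Units are fixed package-wide: energies kcal/mol, lengths Å, times ps,
angles rad, temperatures K, with the Boltzmann constant
`kB = 0.0019872041` kcal/(mol·K).

# Well-tempered bias

The engine alternates Brownian-dynamics segments of length `tau` with
Gaussian deposits at the current position of the biased CVs. A hill
dropped where the bias has already reached $V$ gets the tempered height

$$w = w_0\, e^{-V/(k_B \Delta T)},$$

and the FES estimate is read from the final bias as

$$\hat F(s) = -\frac{T+\Delta T}{\Delta T}\,V(s,t),$$

anchored to zero at its minimum. Defaults follow the conditions of the
quadruplex study this package models: $T = 300$ K, $\Delta T = 2700$ K
(bias factor $\gamma = 10$), Gaussian widths 0.23 Å for distance CVs
and 0.05 rad for torsions, and an initial deposition rate of
0.5 kcal/mol/ps. The rate is stated in the source as a single number;
its split into height and pace is a convention, fixed here as
$w_0 = 0.5$ kcal/mol every $\tau = 1$ ps, both configurable. A
half-harmonic upper wall (default limit 27.0 Å on the distance CV) caps
the unbound excursions; the wall belongs to the sampled system, not to
the recovered FES, so its energy is bookkept separately from the bias,
and hills may legitimately be centered beyond the wall as long as the
grid covers them (the default grid extends three widths past the
domain).

Two further conventions are deliberate. First, the FES is taken from
the *final* bias rather than a time average; the convergence profile
(below) is the tool for judging whether that estimate has settled.
Second, the bias is stored twice — an ordered hill list (the reference
path, summed directly with minimum-image wrapping on periodic CVs) and
an incrementally updated grid cache used during dynamics. The cache is
exact at grid nodes up to an 8-width truncation of each hill
($e^{-32} \approx 10^{-14}$ per hill); off-node reads through
`bias_energy(..., method = "grid")` use Catmull–Rom cubic
interpolation, which at the default spacing of one tenth of a Gaussian
width keeps the fast path within $10^{-4}$ kcal/mol of direct
summation. The dynamics inner loop itself interpolates the cached
force grids linearly — a per-step force error orders of magnitude below
the thermal noise, which the sampler-correctness tests bound
statistically.

# The sampler

Sampling is overdamped (Brownian) Euler–Maruyama in the landscape
coordinates — for the analytic systems the coordinates *are* the CVs:

$$x \leftarrow x - \frac{D}{k_BT}\,\nabla(U + V + W)\,\Delta t +
  \sqrt{2D\,\Delta t}\,\eta,$$

with $D = k_BT/(m\gamma_f)$ from the particle mass and friction. The
scheme has the Boltzmann distribution as its stationary law, which is
all the analysis requires; inertial dynamics would add parameters
without adding testable content. Mass and friction only set the
exploration time scale. Defaults (40 amu, 50 ps⁻¹, $\Delta t$ 0.02 ps)
keep the drift-stability product $\beta D\,\Delta t\,U''$ well below
one on the steepest default landscape; the two-dimensional acceptance
runs lower the friction to 15 ps⁻¹ (the landscape is wider and its
curvature smaller), trading nothing but wall-clock time. Non-periodic
coordinates reflect at the domain bounds — reflection preserves the
stationary law, and every excursion is counted in the trajectory's
`reflections` field — while periodic (angle) coordinates wrap.

All randomness flows from one integer seed; identical inputs rerun to
bit-identical trajectories and byte-identical output files, which the
test suite asserts literally.

# Synthetic systems: what they emulate and what they do not

`make_double_well()` pins its two minima exactly `separation` apart
with an energy gap exactly `asymmetry`, by adding a C¹ sigmoid that is
flat at both minima — so generator parameters are recovered, not merely
approximated, by a perfect estimator. `make_hopping_landscape()`
builds the three-basin topology of a hopping binder: basins `Aa`, `Ab`,
`B` with offsets 0.9 and 1.4 kcal/mol above the global minimum and a
channel whose saddle sits 1.5 kcal/mol above `Ab` — the free-energy
gaps the source study reads off its reweighted surfaces, reused here as
*generator* parameters whose recovery is the test. Wells and channels
are Gaussian; a deterministic fixed-point calibration (local
minimisation per basin, line search per channel, eight rounds) places
minima within 0.1 Å and 0.05 kcal/mol of specification. Because only
the `Ab`↔`Aa` barrier is specified, the second channel `Ab`↔`B` gets
its own default (2.0 kcal/mol above the higher minimum), chosen so all
three basins stay mutually reachable below the 6 kcal/mol plateau; with
zero offsets and equal channel barriers the landscape is mirror
symmetric, which the tests exploit as an exact oracle. Basin centers
default to (0,0), (4,1.5), (8,0) Å with unit widths: far enough apart
that basin masses are well separated, close enough that a desk-scale
run crosses between them thousands of times.

The bead quadruplex is four parallel strands of stacked beads on a
square cross-section (defaults: 6 beads per strand, rise 3.4 Å, side
8 Å — the proportions of a [d(TGGGGT)]₄-like stack). Its 5′ and 3′
terminal beads carry distinct labels and masses (90/100/110 amu), so
the structure, like the real molecule, is not symmetric under
end-swap, and the oriented receptor axis can distinguish the 3′ face —
the side the real ligand prefers. The two-bead rigid ligand stands in
for a planar aromatic scaffold plus flexible charged tail only as far
as CV anchor groups are concerned. None of this emulates sequence,
base pairing, electrostatics or solvent; passing tests demonstrate the
*estimators* are correct, not that the toy model predicts G-quadruplex
thermodynamics. For the same reason the study's printed numbers
(ΔG_bind = −9.4 ± 1.4 kcal/mol and the microsecond-scale convergence)
are not reproduction targets here: they require explicit-solvent
simulation of the real complex, which is out of scope by design. Pose
*dynamics* of the ligand are also out of scope: the geometry layer
evaluates and differentiates CVs on static configurations, and all
sampling happens on analytic landscapes.

# Collective variables

The CV layer implements center-of-mass distance $d$, the torsion
between two groups' major inertia axes ($\varphi$, $\psi$), and the
projection on / distance from the receptor axis (POA/DFA). Three
conventions the source leaves open are fixed as follows:

* **"Major inertia axis" means the long axis** — the eigenvector of
  the smallest inertia-tensor eigenvalue. For an elongated stack this
  is the stacking axis; the largest-eigenvalue alternative is
  perpendicular to it. A degenerate smallest eigenvalue (relative gap
  below $10^{-6}$, e.g. a flat two-layer stack or a spherical top)
  raises an explicit error rather than silently picking a direction.
* **The axis is oriented** by a user-named bead pair, defaulting to
  5′-end → 3′-end of strand A, so POA's sign is deterministic and the
  3′ side is positive. The axis-torsion uses the oriented axes.
* **The torsion is a four-point dihedral** over
  (com₁+axis₁, com₁, com₂, com₂+axis₂) — the COM–COM vector as central
  bond — returning values in $(-\pi, \pi]$, and POA's origin is the
  axis-owner's center of mass.

CV gradients are central finite differences with step $10^{-5}$ Å
(accuracy $O(h^2)$), applied uniformly to every CV kind. Analytic
derivatives of inertia-axis eigenvectors are laborious and easy to get
subtly wrong; at 26 beads the finite-difference cost is irrelevant and
the tests pin the result against analytic formulas where those are
simple (COM distance, POA at fixed axis).

# Reweighting

The source names its reweighting method only by citation. This package
implements the standard time-dependent-bias weight

$$w(t) \propto e^{\beta\,[V(s(t),t) - c(t)]},\qquad
  c(t) = \frac{1}{\beta}\ln\frac{\int ds\, e^{-\beta F(s,t)}}
  {\int ds\, e^{-\beta[F(s,t)+V(s,t)]}},$$

with $F(s,t)$ from the well-tempered relation and the integrals by
trapezoidal quadrature on the bias grid, replaying the hill history at
each checkpoint; $c(t)$ is interpolated linearly in time between
checkpoints (every 50 deposits in the acceptance runs). This is a
published, equivalent route to the same Boltzmann distribution; whether
it is numerically identical to the cited algorithm on these runs is
not determinable from the text, and equivalence is claimed only at the
distribution level. Two practical conventions: new-CV values are taken
from stored trajectory frames (no new biased run), and the first
quarter of each trajectory is discarded before weighting — while the
bias is still growing fast the weights are dominated by a transient
the $c(t)$ interpolation cannot fully absorb. Histogram bins never
visited are reported as `NA` ("unvisited"), not imputed.

# FES analysis

Basins are found by watershed flooding in order of increasing free
energy with deterministic tie-breaking; minima above a depth cutoff are
merged into their lowest-saddle neighbour. Basin ΔΔG defaults to
minimum-to-minimum — the way depths are read off a plotted surface —
with a basin-integrated mode ($-kT\ln(P_a/P_b)$) for thermodynamic
consistency; the integrated mode is the one that converges cleanly on
noisy surfaces, as the README example shows. Barriers come from
threshold flooding (union-find over bins sorted by F), which returns
exactly the lowest saddle on the grid, reported relative to the higher
minimum. The binding free energy integrates $e^{-F/kT}$ over the bound
(7.0–14.0 Å) and unbound (24–26 Å) distance regions, clipping bins by
overlap length so a flat surface yields $-kT\ln(7/2)$ exactly; no
standard-state volume correction is applied unless requested, matching
the direct FES-difference definition. The convergence profile
re-evaluates ΔG from the bias replayed at each checkpoint and counts
bound↔unbound recrossings — the precondition for trusting the final
number. The ±-uncertainty is a block standard error over contiguous,
independently reweighted trajectory blocks; the source does not state
its error method, so a declared substitute is used.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: $5\times10^5$ steps
× 3 seeds for the one-dimensional gap recovery (tolerance
0.3 kcal/mol against quadrature); $10^6$ steps × 3 seeds, friction
15 ps⁻¹, hill width 0.4 Å for the two-dimensional runs — reweighting
onto the unbiased CV within 0.5 kcal/mol on all bins below 4 kcal/mol,
and basin offsets/barrier within 0.3/0.4 kcal/mol; $2\times10^5$ steps
for the harmonic variance check (three block standard errors). The
convergence-profile demonstration runs on a compact 12-Å binding
landscape with a gentler bias factor ($\Delta T = 900$ K): the
slow $\sim 1/t$ tail of the well-tempered transient grows with domain
size and bias factor, and a fixture chosen to actually converge in a
minute of sampling demonstrates the property honestly, where a 26-Å
domain at $\gamma = 10$ would merely demonstrate the transient.
Quadrature oracles use 801 trapezoid nodes per axis (doubling changes
results by under $10^{-6}$ relative).

Known limitations: minimum-to-minimum depth differences inherit the
single-bin ripple of the final bias (use the integrated mode when that
matters); the watershed on strongly noisy reweighted surfaces can seed
spurious shallow basins (raise the depth cutoff or smooth by running
longer); barrier estimates are grid-resolution-limited by construction;
and the hill list is summed directly when tempering each deposit, so
extremely long runs (≫10⁵ hills) would benefit from a compiled kernel
that this desk-scale package does not need.
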