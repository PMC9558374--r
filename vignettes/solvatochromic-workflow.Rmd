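---
title: "From explicit-solvent trajectories to solvatochromic shifts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From explicit-solvent trajectories to solvatochromic shifts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cybospec)
```

# Scope and model

`cybospec` computes the solvent-induced displacement of an electronic
absorption band of a rigid solute from explicit-solvent configurations.
The physical model has three layers:

* a **geometric layer**: spherical, non-periodic solvation boxes; radial
  distribution functions; a continuous hydrogen-bond score;
* a **statistical layer**: an interaction-distance feature space, PCA,
  k-medoids partitioning of trajectory frames, and representative-subset
  selection;
* an **electronic layer**: the Perturbed Matrix Method (PMM), in which
  the solvent enters a fixed reference eigenstate basis purely through
  the electrostatic potential it creates at the solute atoms.

The molecular dynamics engine and all quantum-chemical computations are
outside the package. QM data (eigenstate energies, atomic transition
charges, transition dipoles, reference potentials) enter through a
structured text format (`read_qm_reference()`); band positions that
require explicit-QM-solvent or vibronic calculations enter as numbers in
the workflow config.

## Units

Internally: hartree, ångström, elementary charge. Coulomb sums convert
Å to bohr with the factor 1.8897259886 at a single site
(`site_potentials()`), preventing unit drift. Wavelengths are reported
in nm, broadening widths in cm⁻¹; `nm_to_wavenumber()` and its inverse
are exact mutual inverses.

# Geometric layer

## Sphere construction

`build_solvation_sphere()` composes three steps. *Replication*: the
replica range of the (generally non-orthogonal) solvent cell is obtained
from the fractional coordinates of the sphere's circumscribing box, with
one extra replica per axis — simple and provably sufficient for any
non-degenerate cell. *Carving* keeps whole molecules whose unweighted
centroid lies within `r_max` (boundary inclusive). *Pruning* removes any
molecule with an atom strictly closer to a (physical) solute atom than
`overlap_scale` × the sum of their van der Waals radii; a pair exactly
at the threshold survives. The strict-`<` convention is a deliberate
deterministic tie-break; the default radius set is Bondi, overridable per
atom in the topology. Lone-pair virtual sites have zero radius and are
excluded from the overlap test.

The builder reports the solvent count and implied density rather than
enforcing a target count: matching a particular liquid's count inside a
20 Å sphere depends on the unit cell supplied, so only density-level
agreement is a meaningful check (the test suite verifies a ±5 %
agreement with ρ·(4/3)πr³ for a water-density lattice).

## Hydrogen-bond score

The donor geometry is scored by a separable function of the donor-H to
acceptor distance R and the angle θ at the donor heavy atom between its
hydrogen and the acceptor:

$$F_{HB}(R,\theta) = f(R)\,g(\theta), \qquad
f(R) = \begin{cases}1 & R \le R_0\\
\exp\left(-\frac{(R-R_0)^2}{2(\sigma_R R_0)^2}\right) & R > R_0\end{cases},
\qquad g(\theta) = \exp\left(-\frac{(\theta-\theta_0)^2}{2\sigma_\theta^2}\right)$$

with defaults R₀ = 1.85 Å, σ<sub>R</sub> = 0.20, θ₀ = 0°,
σ<sub>θ</sub> = 10°, and values below 10⁻⁴ returned as exact zeros.
The parameter values are the empirical ones established for this score;
the *algebraic* form above is this package's rendering — it satisfies
the defining properties ([0,1] range, maximal on the plateau, Gaussian
fall-offs on the stated scales, zero floor) and is isolated behind
`hb_params()`/`f_hb()` so an alternative expression can be swapped in
without touching any caller. σ<sub>R</sub> is treated as dimensionless
(a fraction of R₀, i.e. a 0.37 Å scale): the parameter is printed
without a unit, and this reading keeps f scale-covariant in R₀.

## Finite-sphere RDFs

Non-periodic spheres are not homogeneous near the wall, so the reference
density ρ<sub>B</sub> for g(r) is estimated from the B sites inside a
concentric sub-sphere (`r_norm`, default ¾ of the sphere radius). Bin
width defaults to 0.05 Å and extremum location smooths g with a 5-bin
centred moving average. Coordination numbers integrate
4πρ<sub>B</sub> g(r) r² by trapezoid; the default upper limit is the
first *minimum after* the first peak. The phrase "up to the first peak"
sometimes used for this integral cannot reproduce observed coordination
numbers (integrating only half the first shell); it is treated as
shorthand for the first-shell boundary, and both cutoff choices are
available in `find_first_extremum()`.

# Statistical layer

## Feature space

Per frame, the two candidate solvent atoms nearest the N–O bond midpoint
define A₁ and A₂, and the features are the six distances N–A₁, N–A₂,
O–A₁, O–A₂, LP1–A₁, LP2–A₂. A single shared A₁/A₂ anchor keeps the six
coordinates geometrically coherent (they describe one or two actual
solvent molecules); `per_site_neighbors = TRUE` provides the per-site
alternative. Ties in the neighbour ranking break by lowest atom index,
making the features invariant to file order. Features are *not*
standardized before PCA — they share the Å unit, and standardizing would
inflate low-variance directions. PCA retains the fewest components whose
cumulative explained variance reaches the target (default 0.90).

## Clustering and choosing k

Partitioning Around Medoids runs in the reduced space with Euclidean
distance: greedy BUILD seeding, then best-improvement SWAP to
convergence. One deliberate strengthening: the single-swap neighbourhood
has genuine local optima even for n < 10 points (instances exist where
BUILD+SWAP — ours and the reference `cluster::pam` — converge 2 % above
the exhaustive optimum), so `pam_cluster()` restarts SWAP from nine
additional seeded random medoid sets and keeps the lowest-cost solution.
The procedure stays fully deterministic given its seed, and on every
small instance we have enumerated (n ≤ 10, k ≤ 3) it attains the
exhaustive optimum.

k is selected over a range (default 2–20) by a 3-of-4 vote: Silhouette,
Dunn and Calinski–Harabasz each vote for their maximizer; WSS votes for
the elbow, defined as the interior k maximizing the discrete second
difference WSS(k−1) − 2·WSS(k) + WSS(k+1) — the simplest defensible
"break-even" criterion. If no k collects three votes, the smallest k
among the most-voted is returned with a low-confidence flag, a
conservative tie rule (fewer clusters = fewer QM reference
computations).

## Representative frames

The total budget is a user parameter (default ≈ 5 % of the clustered
frames): published per-cluster counts arise from stopping rules that are
not uniquely recoverable, so the package adopts transparent
largest-remainder (Hamilton) apportionment — exact integer arithmetic on
budget·sizeᵢ mod Σsize, remainder ties to the larger cluster then lower
index, every cluster floored at one frame. This reproduces, for example,
(425, 343, 173) with budget 46 → (21, 17, 8) and (702, 548) with budget
62 → (35, 27).

Within a cluster, GRASP minimizes
J(S) = ‖mean<sub>f∈S</sub> φ(f) − mean<sub>cluster</sub> φ(f)‖² over
subsets S of the requested size, φ being the PCA-reduced feature vector
(an electrostatic-potential φ is a config option). Each restart draws
the *first* member uniformly from the whole cluster, then repeatedly
picks uniformly from the restricted candidate list of the best
⌈α·remaining⌉ marginal improvements (α default 0.3, 50 restarts), and
polishes with first-improvement swaps. The uniform first pick is the one
diversification added to the textbook scheme: with the RCL applied from
the first step, all restarts start near the cluster mean and the swap
search strands in shallow local optima (on 12-choose-3 enumeration
instances it missed the optimum in 16 % of cases); with it, the
enumerated optimum was found on every instance tried. α = 0 still
collapses to the fully deterministic pure greedy.

## Collective frames

`build_collective_frame()` concatenates the solvent atoms of the N
selected frames, scaling every charge by exactly 1/N, with the rigid
solute taken once from the reference frame. Because the Coulomb sum is
linear in the charges, the collective frame's potential at any point
equals the arithmetic mean of the per-frame potentials — an algebraic
identity the test suite verifies to 10⁻¹⁰ relative on 100 random
instances, not an approximation.

# Electronic layer

## Perturbed Hamiltonian

With reference eigenstate energies E<sub>i</sub> and atomic transition
charges q<sub>a</sub><sup>ij</sup>, the perturbed Hamiltonian is

$$\tilde H_{ij} = E_i\,\delta_{ij} + \sum_a q_a^{ij}\,
\left(V_a - V_a^{\mathrm{ref}}\right)$$

where V<sub>a</sub> is the solvent potential at solute atom a. This is
the first-order atom-site expansion of the perturbation operator; higher
multipole corrections are an explicit extension point in
`build_perturbed_hamiltonian()` but are not implemented. The default
basis is 11 states (ground + 10 excited).

Diagonalization sorts eigenvalues ascending; no state tracking or
diabatization is attempted across frames (sorting is deterministic, and
for the well-separated visible band the ordering is stable). Perturbed
transition dipoles are obtained by rotating the reference dipole matrix
with the eigenvectors; dipole blocks between excited states default to
zero when not supplied, which affects intensities (borrowing only
ground-state couplings) but not band positions. Oscillator strengths are
f = (2/3)·ΔE·|μ|² in atomic units.

## Broadening, averaging, composition

Stick spectra are convolved with Gaussians of HWHM 600 cm⁻¹ (the
workflow default), each transition normalized so its band area is
f/4.319×10⁻⁹ in the molar-absorptivity convention. Spectra average
pointwise with cluster weights; λ<sub>max</sub> is recomputed on the
averaged curve. Per-cluster band positions compose as

```
total = λ_cf + (λ_c2qm − λ_c0qm) + (λ_pmm_vib − λ_pmm)
```

i.e. the collective-frame position, corrected by the explicit-QM-solvent
effect at the centroid, and by the vibronic effect at the centroid. Full
precision is kept internally; `compose_total()` and
`weighted_average()` round to 0.1 nm only at reporting. Final shifts are
differences of per-solvent weighted averages against a chosen reference
solvent.

# Synthetic fixtures

`gen_trajectory()` emulates the study conditions geometrically: a rigid
nitroxide-like solute fixed at the origin with two lone-pair virtual
sites (0.3 Å from O, ±55° off the N–O axis in the plane bisecting the
C–N–C frame — exposed parameters, as lone-pair geometries are
model-specific), and solvent molecules either planted as donors at
truncated-Gaussian (R, θ) geometries along the lone-pair directions or
placed uniformly in a sphere with a 4.5 Å keep-out around the solute.
Regimes (0/1/2 bonds, distance and angular spreads, dwell fractions)
occupy contiguous frame blocks, mimicking the slow exchange between
solvation patterns that makes clustering meaningful. Defaults for the
planted geometries (r_mean 1.8 Å, r_sd 0.1 Å, θ_sd 5°) sit inside the
plateau/fall-off region of F<sub>HB</sub> so planted bonds score near 1.

What the generator does **not** emulate: force-field energetics, solvent
structure beyond minimum-distance packing, polarization, finite
temperature kinetics, or vibronic structure. Passing the recovery tests
therefore demonstrates that the analysis stack recovers *planted
geometric regimes with realistic spacings and noise* — not that it would
resolve arbitrarily subtle solvation substates in real trajectories.

`gen_qm_reference()` produces consistent PMM inputs: ascending energies
with a 0.098 hartree first gap (a ~465 nm visible band), symmetric
transition-charge blocks whose diagonals sum to the total molecular
charge and whose off-diagonals carry no monopole, and random dipoles.
`gen_solvent_cell()` packs molecules at a mass density converted to
number density with a 2.4 Å center–center cutoff. All generators are
pure functions of their seeds.

# Numerical choices and degenerate inputs

* Problem sizes in the shipped tests: trajectories of 80–120 frames with
  3–6 solvent molecules, clustering ranges k = 2–6, PMM sweeps over
  10³ random references of 6 states — sizes chosen so the full suite
  runs in about a minute while every oracle (enumeration, brute-force
  double loops, Monte-Carlo volume checks) remains exact or
  statistically sharp.
* RDF bins with zero expected counts simply contribute g = 0; empty
  transition lists broaden to a zero spectrum with a warning; a
  zero-variance feature matrix yields zero PCA components with a
  warning rather than an error.
* Charge sites within 0.1 Å of a solute site raise a singularity error
  (a physical overlap upstream data should never produce).
* `subsample()` matches target times t₀ + k·stride to nearest frames,
  tolerating irregular stamps; a stride below the native spacing is an
  error, not a silent no-op.
* Remainder ties in the frame allocation, neighbour ties in feature
  extraction, and RCL ties in GRASP all break deterministically
  (documented in the respective help pages).

# Known limitations

* The PMM operator is strictly first order in the atomic-site potential
  difference; strongly polarizable or charge-transfer states need the
  explicit-QM-solvent correction channel.
* Intensities with incomplete dipole input are approximate (positions
  are not affected).
* The workflow is non-periodic by construction; no minimum-image
  conventions anywhere.
* Cluster populations and representative-frame counts depend on the
  user's budget and stride; the package reproduces allocation *rules*,
  not any particular published count that depends on unstated stopping
  criteria.
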