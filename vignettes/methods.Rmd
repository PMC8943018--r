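---
title: "Self-consistent learning of long-range electrostatic response in water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-consistent learning of long-range electrostatic response in water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scfnn)
```

This vignette is the package's own account of its model and the choices
behind it: what is computed, under which assumptions, with which defaults,
and what the synthetic validation does and does not demonstrate.

## The model

### Interaction split

The Coulomb interaction is split with a Gaussian screening length
$\sigma$ = 4.2 Å (8 Bohr):

$$ v_0(r) = \mathrm{erfc}(r/\sigma)/r, \qquad v_1(r) = \mathrm{erf}(r/\sigma)/r .$$

$v_0$ decays faster than any power beyond $\sim 2\sigma$ and defines the
*Gaussian-truncated* short-range system; $v_1$ is long-ranged but varies
slowly on the scale of $\sigma$, so the response it induces is linear to an
excellent approximation. This is the local-molecular-field picture: local
structure is short-range physics, while long-range Coulomb effects act
through a slowly varying effective field

$$ \mathbf E(\mathbf r) = \mathbf E_\mathrm{ext}(\mathbf r)
   - \int d\mathbf r'\, \rho(\mathbf r')\, \nabla v_1(|\mathbf r-\mathbf r'|), $$

where $\rho$ is the instantaneous charge density: valence nuclear charges
(+6 e₀ on O, +1 e₀ on H — the only choice consistent with four doubly
occupied Wannier centres per molecule) plus the four centres at −2 e₀ each.
Because the Fourier transform of $v_1$ carries the factor
$e^{-k^2\sigma^2/4}$, the field is evaluated by a *small* reciprocal-space
sum alone (all shells with damping below $10^{-12}$ dropped; no real-space
Ewald term is needed). The $k=0$ term is excluded: tinfoil boundary
conditions under constant E, while under constant displacement field the
uniform component is closed on the instantaneous polarization,
$\mathbf E_\mathrm{unif} = \mathbf D - 4\pi k_e \mathbf P$. All
electrostatic formulas are carried in the Gaussian convention adapted to the
internal units (Å, e₀, eV, fields in V/Å): every $4\pi$ multiplying a
polarization or dipole-fluctuation term carries one factor of the Coulomb
constant $k_e$ = 14.399645 eV·Å/e₀², the single conversion between the
SI-style printed forms of the dielectric relations and the internal ones.
Fields are evaluated at nuclei only; the field-weighted descriptors
reference atoms, not centres.

### Networks

Each molecule carries a local frame: origin on the oxygen, $y$ along the
O–H1 bond (H1 = bonded hydrogen of smaller atom index — the convention is
arbitrary but must match between training targets and inference), $z$ along
$\mathrm{OH_1}\times\mathrm{OH_2}$, $x = y \times z$. Four networks act in
these frames:

* **1S** — 36 scalar symmetry functions (radial Gaussians split by
  neighbour species, plus axis-projected angular functions) →
  24 → 16 → 12 outputs (tanh): the local coordinates of the four centres of
  the short-range system.
* **1L** — 36 field-weighted inputs (12 radial shapes × 3 local axis
  components of $\sum_j \mathbf E_j e^{-\eta r_{ij}^2} f_c(r_{ij})$, the
  central atom included so its own field is the leading term) → 12 outputs,
  strictly linear with no bias: zero field gives exactly zero displacement.
* **2S** — per-element networks (30 inputs for O, 27 for H) → 25 → 25 →
  local force components (tanh).
* **2L** — per-element linear maps of the 36 field-weighted inputs to local
  force components. Hydrogen-centred descriptors reuse the parent molecule's
  axes with the origin moved to the H.

The cutoff function is the cosine form $f_c(r) = \tfrac12[\cos(\pi r/r_c)+1]$
with $r_c$ = 12 Bohr; value and slope vanish at $r_c$, so all descriptors
are $C^1$ across the cutoff. The $(\eta, r_s, \zeta, \lambda)$ grids are
data, not code (`inst/extdata/descriptor_params.yaml`): $\eta$ log-spaced
over [0.01, 2] Bohr⁻², $\zeta \in \{1,4\}$, $\lambda = \pm1$, two angular
widths. Trained models carry a hash of the parameter file and refuse to
evaluate descriptors generated from a different one. The widest grids were
fixed once; they are deliberately generic rather than optimized.

### Self-consistency

Centres source the field; the field moves the centres. `scf_solve()`
iterates $w \mapsto w_\mathrm{GT} + \mathrm{1L}(\mathbf E[w])$ by plain
fixed-point iteration (optional linear mixing, default 1) until the largest
centre displacement between iterations falls below 2.6 × 10⁻⁴ Å, starting
from the short-range centres. The maximum norm over centres is used as the
metric. Convergence is fast because the loop gain is the electronic
susceptibility: for constant E, a handful of iterations; for constant D the
uniform-field feedback has gain $\approx 1 - 1/\varepsilon_\infty$, so more
iterations are allowed (`max_iter`). Divergence (three consecutive growing
steps) raises with the displacement history attached and a suggestion to
reduce the mixing fraction.

### Two-stage training

Field-induced perturbations are never available in isolation from a single
reference calculation, but their *differences* between two applied fields
are: the short-range contribution cancels. For every unordered pair of
samples sharing a nuclear configuration, the centre-position (and force)
differences are regressed on the differences of the field-weighted
descriptors. For a linear bias-free network that loss is an ordinary
least-squares problem and is solved directly (QR); rank-deficient columns
get zero weights. The zero-field anchor is structural — no bias term exists.
Effective fields during training are computed from the reference centres
directly; no self-consistent loop is needed because the reference centres
*are* the self-consistent electronic state of the reference system.

The fitted linear networks then predict the field contribution for every
sample (including the internal long-range field present even at zero
applied field); subtracting it exposes short-range targets on which 1S/2S
are trained by full-batch Adam (learning rate 2 × 10⁻³ by default, early
stopping on the held-out groups, inputs and outputs standardized; linear
networks are never standardized so their homogeneity stays exact). The
within-group spread of the short-range targets is reported: a large spread
flags an under-fitted long-range stage. Splitting is always by group, so no
nuclear configuration leaks between training and test.

## The synthetic oracle

Everything above is validated against a classical surrogate with a known
ground truth: rigid water molecules (r(OH) = 0.9572 Å, 104.52°) carrying
four reference centres in the molecular frame — bond centres 0.52 Å along
each O–H bond, lone-pair centres 0.3 Å from the O tilted tetrahedrally out
of the plane. This geometry gives a rigid molecular dipole of 2.84 D, close
to liquid water's. Each centre responds to the local effective field at its
oxygen as $\Delta r = -\alpha/(2k_e)\,\mathbf E$, solved self-consistently
with the same $v_1$ interaction the model uses, which makes the molecular
polarizability volume exactly $4\alpha$ and — crucially — makes the learning
target *exactly representable* by the linear network: the narrowest O-channel
descriptor is the centre atom's own field to within $e^{-50}$ contamination
from neighbouring oxygens. Parameter recovery is therefore a sharp test:
any residual is implementation error, not model error. The default
$\alpha$ = 0.48 Å³ per centre gives a molecular polarizability of 1.92 Å³
and a high-frequency dielectric constant near 1.8 at water density, the
regime of real water. Reference forces are Lennard-Jones (common water
values on O) plus the full periodic Coulomb sum over all point charges,
with centre forces attributed to the parent oxygen.

Configurations are rigid molecules on a jittered lattice with random
orientations, rejected until no O–O pair is closer than 2.4 Å and no
intermolecular atom pair closer than 1.5 Å (64 molecules at 0.997 g/cm³
give a 12.42 Å box).

### The dynamics engine

Molecular dynamics needs three things the static oracle does not: flexible
molecules (harmonic bonds and angle, roughly the stiffness of common
flexible water models), a conservative centre rule, and protection against
charge fusion. For dynamics the centres are fixed linear combinations of
the nuclei — bond centres along the O–H bonds, the two lone centres
combined on the back bisector at the position that preserves the rigid
dipole — so centre forces redistribute to the nuclei exactly through the
(constant) combination coefficients and the force field is conservative;
attributing centre forces wholesale to the oxygen would discard torque and
bias the sampled ensemble that the dielectric estimators assume. Bare
±(1–6) e₀ sites are far more strongly coupled than the effective charges of
classical water models, and an H of one molecule will fuse with a bond
centre of another if nothing repels it: the engine therefore adds
intermolecular $B/r^{12}$ walls between O–H and H–H site pairs (a classical
stand-in for Pauli repulsion; O–O is already guarded by Lennard-Jones).
Velocity-Verlet with a 0.5 fs step and Berendsen velocity rescaling
($\tau$ = 100 fs default; the target-temperature rescale factor is clamped
to [0.8, 1.25]) integrates the equations of motion; Maxwell–Boltzmann
initial velocities with the centre-of-mass motion removed; generated
packings are first relaxed by capped gradient descent. With
`long_range = FALSE` the engine drops the reciprocal-space part and all
uniform-field coupling: the purely short-range control used to demonstrate
missing screening.

## Study conditions of the validation runs

The sizes below are the package's chosen study conditions for desk-scale
validation; they were set by pilot-stage power analysis before the
acceptance runs were scored.

* **Field-response recovery** — 30 groups of 64 molecules at
  {0, 0.1, 0.2} V/Å, two-thirds/one-third group split, induced polarization
  predicted at a held-out 0.3 V/Å field on unseen configurations. Because
  the oracle response is inside the model class, the observed error is
  ~10⁻⁵ relative, far inside the 2 % acceptance band.
* **Dielectric consistency** — a *weakly polar* variant of the fluid
  (lone-pair offset 0.080 Å, rigid dipole 0.40 D, $\alpha = 0$): 32
  molecules, 6 ps runs (12 000 steps, 1 ps equilibration) at E = 0, D = 0
  and D = 0.45 V/Å. The weak coupling makes $\varepsilon \approx 1.4$, so
  both routes — the P–D slope $(1 - 1/\varepsilon)/(4\pi k_e)$ and the
  composite Kirkwood factor
  $G_{Kc} = \tfrac13(2 G_K^{E=0} + G_K^{D=0})$ through
  $4\pi k_e \beta N \mu^2 g_K/V =
  (\varepsilon-1)(2\varepsilon+1)/\varepsilon -
  (\varepsilon_\infty-1)(2\varepsilon_\infty+1)/\varepsilon_\infty$ —
  converge within a few percent in these short trajectories. A strongly
  polar fluid would need nanosecond sampling.
* **The k→0 longitudinal check** — in a 9.9 Å box the smallest nonzero
  wavevector (0.64 Å⁻¹) sits *above* the screening crossover: the
  longitudinal correlation $\chi_{zz}(k)$ there is still near its
  unscreened level, a finite-box fact, not an estimator failure (verified
  directly: the constant-D homogeneous fluctuation agrees with the
  screening limit while $\chi(k_1)$ does not). The constant-D ensemble's
  homogeneous longitudinal fluctuation $\langle M_z^2\rangle/V$
  (`chi_zero()`) *is* the $k\to 0$ member of the same correlation — the
  depolarization field that quenches it at constant E is absent at constant
  D — so the plateau check anchors there, with block-averaged errors and the
  propagated slope uncertainty (which enters the limit with relative weight
  one). The curve-plateau mode remains available and is the right choice
  when the box is large enough. The short-range-only control shows the
  expected contrast: its low-k level exceeds the limit.
* **Interfacial screening** — 48 molecules, full-strength (2.84 D) fluid,
  slab with 9 Å vacuum per side, 7 ps runs. The discriminant is the
  density-weighted outward-orientation score: the mean of
  $\cos\theta \cdot \mathrm{sign}(z - z_\mathrm{com})$ over molecules in
  bins with density ≥ 0.3 g/cm³. With the long-range coupling the
  interfacial dipole layer is screened and the score is ~0.01; the
  short-range-only control keeps orientational order through the whole
  liquid and scores ~0.14.

## Numerical choices

* Minimum-image displacements map to $(-L/2, L/2]$; orthorhombic cells only.
* Reciprocal sums enumerate integer shells inside the damping cutoff;
  phase factors are built by recursion (compiled code), so costs scale as
  (number of k-vectors) × (number of charges).
* The centre-ordering matcher minimizes total squared distance to the
  four reference sites over all 4! assignments, with a deterministic
  first-minimum tie-break; centres farther than 1 Å from their oxygen are
  rejected as non-water-like.
* Slab electrostatics reuse the 3-D periodic reciprocal sum (no 2-D
  correction); with ≥ 9 Å vacuum per side this is a documented
  approximation, adequate for the qualitative screening contrast.
* Degenerate inputs: parallel O–H bonds (no molecular plane), hydrogens
  equidistant between two oxygens, and oxygens with ≠ 2 bonded H all raise
  errors rather than guessing.
* Seeds: every random operation (configuration generation, splits, weight
  initialization, initial velocities) takes an explicit seed; trajectories
  are bit-reproducible on one thread.

## What the synthetic validation does and does not show

The oracle emulates the *structure* of the real problem — grouped reference
data at several field strengths, centres responding linearly and
self-consistently through the same screened interaction, realistic dipole
and polarizability scales — so it sharply tests the machinery: descriptors,
field evaluation, the two-stage fit, the self-consistent loop, the
finite-field ensembles and the dielectric estimators. It does not emulate
real water's electronic structure: the short-range targets are rigid
reference geometry rather than configuration-dependent Wannier centres, the
force field is classical, and quantitative water properties
(g(r), $\varepsilon \approx$ 100, mean dipole 2.9 D at the reported
reference level) require training on quantum-mechanical reference data and
production-scale simulations of ~1000 molecules. Passing the desk-scale
suite therefore demonstrates correctness of the implementation, not
accuracy of any particular trained water model.

## Known limitations

* Forces are predicted directly per atom (not as an energy gradient), so
  dynamics are not exactly energy-conserving: thermostatted ensembles only,
  and centre-of-mass drift is monitored rather than assumed zero.
* Intact water topology is assumed; bond breaking is out of scope.
* Fixed-point iteration only (no Anderson/DIIS acceleration); under
  constant D with a strong electronic response the loop converges linearly
  with gain $1 - 1/\varepsilon_\infty$.
* The descriptor grids are generic; reproducing published benchmark errors
  of any reference dataset would additionally require that dataset and its
  (unpublished) descriptor parameters.
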