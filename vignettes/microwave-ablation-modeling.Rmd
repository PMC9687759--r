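---
title: "Modeling microwave tumor ablation with mwablate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microwave tumor ablation with mwablate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

Microwave ablation (MWA) destroys liver tumors by driving 2.45 GHz power
through an interstitial coaxial antenna. The treatment chain this package
simulates is

1. the antenna radiates an electromagnetic field into lossy tissue;
2. dielectric losses convert the field into a volumetric heat source
   (the specific absorption rate, SAR);
3. the tissue heats according to a bioheat equation, with blood perfusion
   as a distributed sink and water vaporization as a heat-capacity effect;
4. heat exposure accumulates into irreversible thermal damage
   (the Arrhenius integral $\Omega$);
5. damage geometry is summarized as tumor coverage, collateral damage to
   healthy tissue, and the 60&nbsp;°C lethal isotherm — and inverted to find
   the smallest input power that ablates the whole tumor.

Every stage feeds back on earlier ones: permittivity and conductivity
collapse sigmoidally as tissue desiccates, which reshapes the field, and
perfusion shuts down ($\beta$: 1 → 0) where tissue is destroyed.

## Electromagnetic model

In the axisymmetric domain the field of a coaxial antenna is transverse
magnetic, with a single azimuthal magnetic component $H_\varphi(r,z)$. The
frequency-domain field equation

$$\nabla \times \left(\tilde\varepsilon^{-1}\, \nabla\times \mathbf H\right)
  - k_0^2 \mu_r \mathbf H = 0, \qquad
  \tilde\varepsilon = \varepsilon_r - j\,\sigma/(\omega\varepsilon_0),$$

is discretized in the scaled unknown $w = r H_\varphi$. The scaling is a
deliberate numerical choice: the coax TEM mode is $H_\varphi \propto 1/r$,
i.e. $w = \text{const}$, which linear elements represent *exactly*. A
direct $H_\varphi$ discretization must integrate $uv/r$ terms whose
quadrature error breaks the positivity of the radial operator and, in our
experiments, produced a spurious near-singular mode that reflected the
entire port wave. In $w$ the weak form is a plain weighted
stiffness/mass pair with weight $1/r$ and the problem is benign.

Boundary conditions:

* **Port** (coax cross-section at the feed): incident TEM mode
  $H_0 = C/r$ with $C = \sqrt{P_{in} / (\pi Z_d \ln(b/a))}$, imposed as a
  first-order matched port; peak-phasor convention, so the dissipated
  power density is $\sigma |E|^2/2$ and SAR $= \sigma|E|^2/(2\rho)$.
* **Outer boundary**: first-order absorbing condition. The tissue is so
  lossy at 2.45 GHz (penetration depth ≈ 18 mm at 37 °C) that the
  boundary, placed ≈ 2.5–3 penetration depths out, sees almost nothing; a
  PML is unnecessary. The small outward flux is part of the reported
  power balance, which closes within 2% on the default mesh.
* **Metal** (conductors, slotted outer shield, tip short): the natural
  do-nothing condition of the $H$ formulation, i.e. a perfect conductor.
* **Axis**: $w = 0$.

The complex system is solved as an equivalent $2N$ real block system
(the sparse solver stack is real-only). Element order is linear (P1) with
mesh grading near the slots; the energy-norm convergence rate of 1
expected for P1 is verified on a plane-wave benchmark, and the 1D lossy
attenuation constant is reproduced to 0.01%. Second-order elements were
considered and rejected: grading recovers the needed accuracy at lower
cost and keeps the assembly fully vectorized.

Port reflection $S_{11}$ is computed by projecting the solution onto the
TEM mode; it is a *diagnostic only* (the parametric antenna is not
impedance-optimized; matched-load and short-circuit transmission-line
toys verify the port at $|S_{11}| \approx 0$ and $\approx 1$).

## Dielectric and thermal property models

Relative permittivity and conductivity follow sigmoidal collapse models

$$\varepsilon_r(T) = s_1\!\left(1 - \frac{1}{1+e^{s_2 - s_3 T}}\right),
\qquad
\sigma(T) = r_1\!\left(1 - \frac{1}{1+e^{r_2 - r_3 T}}\right).$$

The coefficients are not package inventions but carry external
provenance: healthy-liver values come from published sigmoidal fits to
measured liver dielectrics at 2.45 GHz
($s = (48.391,\ 6.286,\ 0.0764\ \mathrm{°C^{-1}})$,
$r = (2.173\ \mathrm{S/m},\ 5.324,\ 0.0607\ \mathrm{°C^{-1}})$), and the
tumor set scales the plateaus by the reported ~24% permittivity and ~11%
conductivity excess of tumoral over healthy liver at 37 °C.

Tissue water content by mass follows the three-branch model

$$W(T) = \begin{cases}
0.778\,(1 - e^{(T-106)/3.42}) & 70 \le T < 100\\
7.053 - 0.064096\,T & 100 \le T < 104\\
0.778\, e^{-(T-80)/34.37} & T \ge 104
\end{cases}$$

which is continuous at both joins (verified to $10^{-3}$) and is extended
as the constant steady-state value 0.778 below 70 °C, where the model is
otherwise undefined. Vaporization enters the heat equation in one of two
selectable ways:

* **Effective specific heat** (default): $c' = c - \alpha\, \partial W /
  \partial T$ with $\alpha = 2.26\times 10^6$ J/kg. The typeset source of
  this relation is dimensionally ambiguous about a density factor; the
  package implements the dimensionally consistent mass-fraction reading
  (units J/(kg·°C)) and exposes the $\alpha/\rho$ reading as the
  `per_density` option. At branch joins the *left-limit* derivative is
  used, keeping $c'$ finite and deterministic.
* **Enthalpy spike**: volumetric heat capacity jumps to
  $h_{fg} C_w / \Delta T$ across 99–100 °C and drops to the gas-phase
  product $\rho_g c_g$ above, per phase (tissue and blood separately).

Static constants (density, conductivity, specific heat) for healthy
liver (1079 kg/m³, 0.52 W/(m·°C), 3540 J/(kg·°C)), tumor
(1040, 0.57, 3960) and blood (1060, 0.50, 3600; core temperature 37 °C)
are tabulated in `material_lookup()`.

## Bioheat backends

Three transient solvers share one discretization (P1 elements, lumped
heat capacity, implicit Euler, Picard iteration on $T$-dependent
coefficients to $10^{-3}$ °C):

* **Pennes** (default): conduction + perfusion sink
  $\beta \rho_b \omega_b c_b (T_b - T_t)$ + microwave source.
* **LTNE**: two-temperature porous-media model; tissue and blood phases
  weighted by porosity $\varepsilon$, coupled by the interfacial term
  $h_c a (T_t - T_b)$ and the perfusion exchange, blood advection
  $\beta\,\mathbf u\cdot\nabla T_b$, blood-phase vaporization as an
  enthalpy spike.
* **LTE**: the single-temperature combination of the two phases. The
  printed form of the combined equation carries an extra $(1-\varepsilon)$
  factor on the conduction term that is inconsistent with simply summing
  the two phase equations — and only the summed form reproduces the LTNE
  solution in the stiff-coupling limit $h_c a \to \infty$ (verified to
  1%). The consistent form is the default; the printed variant remains
  available as `lte_conductivity_form = "as_printed"`.

Lumped capacity is chosen deliberately: it makes a uniform 37 °C state
exactly stationary, conserves total enthalpy exactly under insulated
boundaries (verified), and preserves the discrete maximum principle on
the right-triangle meshes the generator produces. Advection, when a blood
velocity is configured, is streamline-upwinded and a cell-Péclet warning
is raised when it dominates.

Degenerate inputs are handled explicitly: at $\varepsilon = 0$ with no
exchange terms the blood equation has empty rows and the blood phase is
pinned inert; perfusion parameters are validated
($0 \le \varepsilon < 1$, $\omega_b, h_c a \ge 0$).

Perfusion values not fixed by the tissue table are literature defaults,
exposed in the configuration: $\omega_b = 6.4\times10^{-3}$ 1/s,
$\varepsilon = 0.2$, $h_c a = 2\times10^4$ W/(m³·°C), $\mathbf u = 0$,
and metabolic heating $Q_m = 0$ (negligible against microwave
deposition during ablation). Every acceptance-level property is either
independent of these values or phrased as a model limit.

## Damage, coverage, optimal power

Damage follows first-order Arrhenius kinetics,
$\Omega(t) = \int_0^t A e^{-\Delta E/(R T_K)}\,dt$, accumulated with the
rectangle rule at the thermal step — exact for the piecewise-constant
temperatures the implicit stepper produces. The default liver kinetics
$A = 7.39\times10^{39}$ 1/s, $\Delta E = 2.577\times10^5$ J/mol are the
standard literature set (external provenance): 600 s at 60 °C gives
$\Omega \approx 174$ (deeply necrotic — the basis of the 60 °C lethal
isotherm), while 600 s at 37 °C gives $\Omega \approx 0.18 < 1$.

"Complete ablation" is interpreted as the $\Omega \ge 1$ super-level set
(necrotic fraction $1 - e^{-\Omega} \approx 63.2\%$), the conventional
threshold; the smooth necrotic-fraction map is also exported so
intermediate iso-damage levels (0.3, 0.5, 0.75) are reproducible.
Perfusion shutdown $\beta(\Omega)$ is a step at $\Omega = 1$ by default,
with $e^{-\Omega}$ (surviving-cell fraction) selectable.

Isocontours are extracted by linear interpolation on triangles; enclosed
volumes integrate the super-level indicator element-by-element with exact
sub-triangle cuts and are revolved ($2\pi \int r\,dA$) in axisymmetric
runs. Because the indicator volume of a linearly interpolated field is
monotone in its nodal values, tumor coverage and collateral volume are
provably non-decreasing in time — the property underwriting the
optimal-power bisection, which returns the smallest power (within a
tolerance) whose end-of-run coverage reaches the target.

## Geometry, meshing and the synthetic-data generator

The antenna is a parametric multi-slot coax: 10 slots of width 0.6 mm at
0.8 mm pitch by default (slotted span $10w + 9s = 13.2$ mm), shorted at
the tip, inside a catheter. Coax radii are not dictated by the modeled
design and default to a ≈50 Ω PTFE line (outer/inner radius ratio ≈ 3.3);
the tip is wrapped in a 2 mm dielectric cap, as on real trocar-tipped
applicators, which also keeps the shorted-tip corner singularity out of
direct tissue contact. A note on that corner: the *pointwise* SAR maximum
in tissue sits at the catheter surface beside the tip (corner fringing,
mesh-dependent), while SAR-versus-depth profiles at radial offsets of
2 mm and beyond peak mid-slot-span — the slot-localized pattern expected
of this antenna class. Tests assert the profile, not the corner.

Tumors are either analytic triaxial ellipsoids or closed triangulated
surfaces (STL/OFF/PLY import with closed-manifold validation).
Axisymmetric runs revolve the volume-equivalent ellipse with semi-axes
$(\sqrt{ab}, c)$, preserving volume exactly. The fixture generator
writes ellipsoid surfaces at the emulated patient-tumor extents
(1.64 × 1.71 × 3.81, 1.74 × 1.53 × 2.10, 1.78 × 1.97 × 2.27 cm) plus
seeded "lumpy" spherical-harmonic perturbations of each (labelled
`_synthetic` — stand-ins for segmented patient geometry, byte-reproducible
for a fixed seed).

The mesh is a graded tensor-product triangulation: coordinate lines are
forced onto every material interface (coax radii, slot edges, tip cap,
tumor extents), so no element straddles a discontinuity, with element
size at most `h_fine` (0.5 mm default, halved across the slots) near the
antenna and tumor boundary and at most `h_coarse` (4 mm) far away. This
is simpler than an unstructured Delaunay mesh and satisfies every
contract the solvers need: complete region tagging, exact area
partition, axis/port edge identification, and a meshed tumor volume
within 1% of the analytic ellipsoid at the default resolution.

What the generator deliberately does **not** emulate: patient-specific
lobulated 3D geometry, heterogeneous perfusion fields, discrete large
vessels, and non-axisymmetric antenna placement. Passing tests therefore
demonstrate correctness of the numerical chain and its internal physics
limits on idealized geometry — not clinical predictive accuracy on real
anatomy.

## Coupled loop and problem sizes

The driver alternates EM solves with thermal stepping, re-solving the
field when any node has drifted more than 5 °C since the last solve or
after 30 s of simulated time, whichever comes first — the dielectric
sigmoids change slowly outside the vaporization band. Damage accumulates
every step; $\beta$ is updated from the current $\Omega$. Reports carry
the coverage time series, final fields, configuration echo and solver
diagnostics, and can be exported as legacy-VTK time snapshots and CSV.

Default desk-scale problem sizes, also used by the test suite: mesh of
roughly 9000 triangles (4700 nodes) for single runs and the power sweep,
a reduced ~4000-triangle mesh for the bisection search, `dt = 1` s and
600 s of ablation; one full coupled run performs ≈ 20–60 EM re-solves.
Sparse Cholesky factorizations are cached and updated across steps, so a
600 s run completes in well under a minute of CPU.

## Known limitations

* The axisymmetric reduction cannot represent the azimuthal lobulation
  of real tumors; coverage on revolved geometry is a documented
  approximation (the full-3D caveat of the underlying modeling
  literature applies).
* At fixed input power the sigmoid dielectric collapse shields the far
  field once the near zone desiccates. Under the study conditions this
  saturates collateral damage at high power: time-to-full-coverage
  shortens with power (reproduced and asserted), but the accompanying
  *increase* of collateral damage at very high powers reported for full
  3D patient geometry does not emerge from the revolved model — its
  driving mechanism, zone elongation along the shaft through
  asymmetric anatomy, has no axisymmetric counterpart.
* First-order absorbing boundaries and P1 elements trade formal order
  for robustness; all stated verification tolerances are met at the
  default resolutions.
* The Picard loop can stall (residual ~ a few °C) for a step or two when
  the vaporization spike sweeps through a node at `dt = 1` s; the
  implicit update remains stable and the next steps recover.

## Reproducing the numbers

`validate()` runs every closed-form oracle (water-content continuity,
constant-temperature and ramp Arrhenius, plane-wave attenuation,
uniform equilibrium, perfusion steady state, slab conduction,
LTNE→LTE) and returns a machine-readable pass/fail table. The testthat
suite covers each module plus the end-to-end monotonicity and
optimal-power properties, and `scripts/acceptance.R` recomputes the
self-contained quantitative targets from the installed package.
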