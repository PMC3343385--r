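---
title: "Modelling BAR-domain electrostatics and membrane bending with barmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling BAR-domain electrostatics and membrane bending with barmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

barmem couples two pieces of physics that together describe how a
crescent-shaped, rod-like protein (a BAR domain) binds and bends a charged
lipid membrane: the electric double layer at its charged concave face, and
the orientation-dependent elastic energetics of the rod on a curved
bilayer. This vignette is the package's account of the models, the
numerical choices, and their limits.

## 1. The electric double layer with field-dependent permittivity

### Model

Ions and water share a lattice of site density $n_s = n_{0w} + 2 n_0$,
where $n_0$ is the bulk number density of each ion species of a monovalent
salt and $n_{0w}$ that of water. Water is a point dipole of moment $p_0$
free to rotate; ions are point charges occupying lattice sites. Mean-field
statistics of this lattice give a net ionic charge density with steric
saturation,

$$\rho_{free}(\phi, E) = -\,2 e_0 n_s n_0
  \frac{\sinh(e_0\phi\beta)}{H(\phi, E)},\qquad
  H = 2 n_0\cosh(e_0\phi\beta) + n_{0w}\,\frac{\sinh(p_0 E\beta)}{p_0 E\beta},$$

and a relative permittivity that depends on the local potential and field
through the orientational ordering of the dipoles,

$$\varepsilon_r(\phi, E) = 1 + \frac{n_s n_{0w} p_0}{\varepsilon_0}
  \frac{F(p_0 E \beta)}{E\, H(\phi,E)},\qquad
  F(u) = \Big(\coth u - \tfrac1u\Big)\frac{\sinh u}{u}.$$

Both enter the Poisson equation
$\nabla\cdot(\varepsilon_0\varepsilon_r\nabla\phi) = -\rho_{free}$ with
$\phi \to 0$ far away and the surface condition
$\varepsilon_0\varepsilon_r\,\partial_n\phi = -\sigma$ at the charged face.
In the zero-field limit the permittivity reduces to the closed form
$\varepsilon_b = 1 + n_{0w} p_0^2 \beta / 3\varepsilon_0$
(`bulk_permittivity()`), which with 55 mol/l water, $p_0 = 4.79$ D and
298 K evaluates to 78.4 — the reason this effective dipole moment (larger
than the bare molecular 1.85 D, absorbing short-range dipole correlations)
is the standard choice.

Assumptions worth keeping in mind: monovalent salt only; one common
lattice constant for ions and water (no ion-specific or Stern
corrections); water treated as a freely rotating dipole or small cluster
— we expose $p_0$ as a parameter and do not model clustering explicitly;
temperature enters only through $\beta$ and defaults to 298 K (the
reference electrolyte's printed bulk permittivity 78.5 is reproduced to
0.2% at that temperature).

### Key parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `salt_mol_l` | bulk salt concentration | mol/l | 0.15 |
| `water_mol_l` | bulk water concentration | mol/l | 55 |
| `dipole_debye` | effective water dipole moment | debye | 4.79 |
| `temperature_K` | temperature | K | 298 |
| `sigma` | surface charge density | As/m² | 0.2 |
| `layer_nm` (`a`) | ordered-water layer thickness | nm | 0.32 |
| `eps_ord` | ordered-layer step permittivity | – | 54.5 |

`n_s` is always derived as `n0w + 2 n0`, never user-set; inconsistent
lattice bookkeeping is the easiest way to break this theory silently.
User-facing units are mol/l, debye, nm and As/m²; all computation is SI.

### Planar solver

`solve_planar()` uses conservative finite differences on a graded 1-D grid
(`planar_grid()`): 0.01 nm spacing at the wall growing geometrically
(factor 1.05) over 12 Debye lengths, about 80 nodes. The far boundary is a
Dirichlet $\phi = 0$ — an approximation to decay at infinity whose adequacy
is covered by a grid/domain sensitivity test (doubling resolution moves the
surface potential by under 0.1%). The nonlinear Poisson problem at fixed
permittivity profile is solved by damped Newton (analytic tridiagonal
Jacobian, Thomas algorithm, step halving on residual increase, relative
residual tolerance $10^{-10}$). Around it runs the permittivity iteration:
start from constant $\varepsilon_b$, re-solve, recompute
$\varepsilon_r(\phi, E)$ pointwise, under-relax with factor 0.5, repeat
until the sup-norm relative change falls below $10^{-6}$. The field
magnitude inside $H$ is lagged one outer iteration; at the wall the
boundary value $E(0) = \sigma / (\varepsilon_0\varepsilon_r(0))$ is used
with the current permittivity iterate, which is exactly the coupling the
surface condition prescribes.

Two switches support validation: `permittivity = "bulk"` freezes
$\varepsilon_r \equiv \varepsilon_b$ and `steric = FALSE` replaces $H$ by
$n_s$, which together reduce the model to classical Gouy–Chapman theory;
the solver then matches the analytic solution to better than 1% for
$\sigma \le 0.01$ As/m². Every converged profile is checked for
electroneutrality (the integrated space charge balances $-\sigma$ to 0.1%).

At the reference conditions ($\sigma = 0.2$ As/m², 0.15 mol/l) the
self-consistent profile drops from 78.4 in the bulk to about 55.7 at
contact. `surface_layer_permittivity()` reports both the contact value and
the average over the first `a` nanometres, because "the ordered-layer
value" can legitimately mean either; the step value 54.5 used downstream
corresponds to the near-surface plateau, and the package's acceptance test
targets the contact reading with a tolerance wide enough to cover the
read-off ambiguity.

Numerical fine print: the Langevin function and $\sinh(u)/u$ switch to
three-term series below $u = 0.01$ (series truncation $\sim 6\times
10^{-16}$ relative, versus $\sim 10^{-12}$ cancellation error for the
direct expressions at the switch), which keeps $\varepsilon_r$ smooth and
monotone across the switch; $F(u)$ is evaluated in the log domain above
$u = 600$ where $\sinh$ would overflow.

### Arc solver

`solve_arc()` treats the charged concave face of the BAR domain as a
circular arc of radius $R$ and fixed contour length $L_0$ in a 2-D
cross-section (the rod direction is translationally invariant). The
permittivity is the step function $\varepsilon_{ord}$ within distance $a$
of the face on the concave side and $\varepsilon_b$ elsewhere; the
surface charge is a flux jump, discretised by depositing each arc
segment's charge $\sigma\,ds$ on the control volume of the nearest
electrolyte node, which conserves $\sigma L_0$ exactly. Behind the face
sits an impermeable protein body (`body_nm`, default 2 nm, the scale of a
BAR-domain cross-section) excluded from the domain with a no-flux
condition, so the deposited charge drives flux only through the concave
face — the one-sided surface condition. With `body_nm = 0` the arc
degenerates to a permeable charged sheet screened from both sides, which
is not the bound-protein situation.

**Where is "point 1"?** The evaluation point sits on the symmetry axis at
distance `d` (default 0.5 nm) beyond the plane through the arc's two tips,
on the concave side — i.e. at the position of the membrane surface beneath
a protein touching it with its tips. Its distance from the charged midpoint
is therefore $\text{sagitta} + d$, and the sagitta
$R(1 - \cos(L_0/2R))$ shrinks as the arc flattens. This placement is what
produces the model's headline behaviour: at fixed $L_0$ the field at
point 1 rises strongly and monotonically with $R$, because a flatter
protein holds its charged face closer to the membrane. The obvious
alternative — a point at fixed distance from the arc's *surface midpoint* —
was implemented first and rejected: there the field *decreases* mildly
with $R$ (the interior of a concave charged cylinder focuses field lines,
as a Debye–Hückel estimate with Bessel ratios confirms), contradicting the
attraction mechanism the model exists to capture. In the flat limit
($R \to \infty$) the sagitta vanishes and point 1 approaches the planar
surface at depth `d`, which is how the arc solver is validated against the
planar one (agreement within 5% at matched parameters and `h = 0.04` nm).

The mesh is a graded tensor-product grid: uniform fine step `h_fine_nm`
(default 0.08 nm; the solver refuses anything coarser than $a/4$) in a
rectangle containing the arc, layer and point 1, growing geometrically
outside, with the outer Dirichlet boundary at least 10 Debye lengths from
the arc. The fine lattice is anchored so a grid row coincides with the
arc's bottom surface, and a grid line passes exactly through point 1 (any
line closer than half a cell is displaced rather than duplicated, to avoid
degenerate cells). The field at point 1 uses second-order three-point
derivatives that respect the locally unequal spacing. The remaining
leading error is the $O(h)$ placement uncertainty of a regularised line
charge on a grid — absolute fields at default resolution carry a few
percent of it, which is why the package's claims about the radius scan are
monotonicity claims at matched resolution, not absolute field values.

`mode = "full"` solves the complete constitutive law by damped Newton with
the field in $H$ lagged one Picard sweep (under-relaxed by 0.5; at the
charge-carrying nodes the lagged field uses the local surface-field
relation $E = \sigma_{loc}/\varepsilon_0\varepsilon_{ord}$, because the
potential spike of a regularised line charge corrupts finite differences
there). `mode = "linearized"` replaces $\sinh(e_0\phi\beta)$ by its
argument and $H$ by $n_s$ — a Debye–Hückel solve, one sparse factorisation.
Both modes show the same monotone field-versus-radius behaviour; the outer
iteration tolerance ($10^{-5}$ relative) sits just above the inner solver's
noise floor and three orders below the discretisation error.

## 2. Bending energetics of rod-like inclusions

This part works in the natural units of the problem — lengths in nm,
energies in kT — with joules reported alongside where a temperature is
available.

A rod of intrinsic curvature $C_p$, flexural rigidity $K_p$ and length
$L_0$, lying on a patch with principal curvatures $C_1, C_2$ (mean $H$,
deviator $D = |C_1 - C_2|/2$) at angle $\omega$ to the first principal
direction, samples $C(\omega) = H + D\cos 2\omega$ and, in the flexible
strong-adhesion limit, pays $E_p = \frac{K_p L_0}{2}(C(\omega) - C_p)^2$.
`protein_energy_orient()` implements the expanded form and a test asserts
to round-off that it equals the composition
`protein_energy(curvature_seen())` — the identity that makes the
orientation dependence nothing more than curvature sampling.
`optimal_orientation()` minimises it analytically: if
$H - D \le C_p \le H + D$ the rod matches its preferred curvature exactly
($\cos 2\omega^* = (C_p - H)/D$, zero energy), otherwise the optimum sits
at the boundary, $\omega^* = 0$ (for $C_p > H + D$) or $\pi/2$. Of the two
symmetric minima $\pm\omega^*$ the non-negative smaller angle is returned,
and an isotropic patch ($D = 0$) returns $\omega^* = 0$ by convention —
these tie-breaks are arbitrary but fixed, and a $10^4$-point grid search
backs the analytic optimum on randomised inputs.

In the rigid limit the membrane adapts instead:
$C_p = C_1\cos^2\omega$ inverts to $C_1 = C_p/\cos^2\omega$
(`rigid_tube_c1()`), so a rod rotated to $\pi/4$ sits on a tube of twice
its intrinsic curvature, and at $\omega = \pi/2$ the rod lies along the
tube axis and constrains nothing — the function refuses that input rather
than returning infinity.

The bilayer energy (`membrane_energy()`) is the Helfrich form plus an
orientational-ordering term of the anisotropic lipids,

$$W_b = \frac{k_c}{2}\int (2H)^2\,dA + k_G\int C_1 C_2\,dA
  - 2 m_0 kT \int \ln\!\big(2\cosh(\ell^2 D_{eff} D)\big)\,dA,$$

evaluated in closed form on cylinders and spheres. The $\cosh$ argument as
usually written ($D_{eff} D$) is dimensionally short one area; the package
carries an explicit coupling constant $\ell^2$ (default 1 nm²) making the
argument dimensionless, as published variants of this free energy do. All
equilibrium properties asserted by the tests are invariant to $\ell^2$ up
to a rescaling of $D_{eff}$.

`equilibrium_tube_radius()` minimises the per-area tube energy
$f(R) = k_c/2R^2 - 2 m_0\ln(2\cosh(\ell^2 D_{eff}/2R)) +
\text{coverage}\cdot\min_\omega E_p$ by a 400-point logarithmic grid scan
over 0.5–500 nm followed by `stats::optimize()` refinement. A minimum on
the bracket edge, or the provably minimum-free case coverage = 0 with
$D_{eff} = 0$, raises a classed error carrying the energy curve — a
degenerate landscape is a diagnosis, not a number. Under strong coupling
the equilibrium tracks $1/C_p$, reproducing the observation that
low-curvature binders widen membrane nanotubes; a ladder test asserts
$R^*$ is monotone non-increasing in $C_p$.

`packing_scenarios()` compares three stylised arrangements of rigid rods on
an adapting tube — dispersed (optimal $\omega$, tube $1/C_p$, no
contacts), circumferential rings ($\omega = 0$, one end-to-end contact per
protein) and a spiral ($\omega = \pi/4$, tube curvature $2 C_p$, two
contacts per protein). In the rigid limit the rods are unstrained in all
three, so the competition is the bilayer's excess energy over flat, paid
over the area per protein $1/\text{density}$, against the contact energy
gained. The 0/1/2 contact bookkeeping is a deliberate stylisation, and
configurational (mixing) entropy is not modelled at all — with attractive
contacts the ring can therefore win at densities where entropy would in
reality keep proteins dispersed. Ties resolve in the order dispersed,
ring, spiral, the entropically favoured order.

### Default elastic parameters are fixtures

No elastic moduli are measured quantities here: $k_c = 20\,kT$,
$k_G = -16\,kT$, $K_p = 10\,kT\,$nm, $L_0 = 20$ nm, $m_0 = 1.67$ nm$^{-2}$
(one lipid headgroup per 0.6 nm²) and $D_{eff} = 1$ nm$^{-1}$ are
field-typical magnitudes chosen once so that examples and tests run on a
realistic scale. Conclusions the package asserts are orderings and
identities robust to these choices, not absolute energies.

## 3. Reference configurations and reproducibility

`reference_fixtures()` returns the two standard scenarios:
`planar_wall` ($\sigma = 0.2$ As/m², 0.15 mol/l salt, 55 mol/l water,
4.79 D) and `arc_scan` (adds $\varepsilon_{ord} = 54.5$,
$\varepsilon_b = 78.5$, $a = 0.32$ nm and a six-radius scan at fixed
$L_0 = 20$ nm). Values that are modelling defaults rather than part of the
reference description — the temperature, the arc length, the point-1
distance — are flagged `assumed` in every manifest `run_scenario()`
writes. Solver stages are deterministic: re-running a configuration
reproduces its CSV outputs byte for byte, and the JSON manifest records
every resolved parameter, the package version and the tolerances.

These fixtures emulate a clean mean-field experiment: a uniformly charged
face, a symmetric monovalent electrolyte, a homogeneous bilayer. Real
BAR-membrane systems have discrete charge patches, multivalent ions,
lipid demixing and thermal shape fluctuations, none of which are in the
model — passing tests show the equations are solved correctly under the
stated conditions, not that those conditions capture any particular
experiment.

## 4. Problem sizes and known limitations

The test suite runs the planar solver at its default 80-node grid
(seconds), small arcs ($L_0$ = 5–6 nm, a few thousand to ~30k unknowns,
about a second each) for limits, symmetry and refinement properties, and
the full reference six-radius ladder at $L_0 = 20$ nm once (~25 s). These
sizes were chosen as the smallest at which each property is in its
asymptotic regime.

Known limitations, beyond those noted above:

* The arc problem is 2-D (an infinite rod); end effects of a real
  finite-length BAR domain and the membrane's own dielectric are absent.
* Absolute fields from the arc solver at default resolution carry a few
  percent discretisation error from the regularised line charge; refine
  `h_fine_nm` where absolute values matter.
* The planar solver's validity is capped at $|\sigma| \le 1$ As/m²; the
  lattice mean field is not trustworthy beyond.
* The deviatoric ordering term treats lipids only; a protein-orientation
  ordering term inside the bilayer energy (e.g. $\cos 2\omega$ under the
  integral) is deliberately not added.
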