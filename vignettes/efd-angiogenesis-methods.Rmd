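---
title: "Methods: EFD fields, pseudo-deformation, and matrix-guided vessel growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EFD fields, pseudo-deformation, and matrix-guided vessel growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efdangio)
```

# The model

`efdangio` simulates sprouting angiogenesis as a population of discrete
vessel tips growing through a continuum description of the collagen matrix.
The matrix at each integration point of a hexahedral grid is described by two
quantities: a collagen density $\rho$ (mg/mL) and an **ellipsoidal fibril
distribution (EFD)** — a $3\times 3$ symmetric positive-definite structure
tensor $P = \sum_i \beta_i\, n_i \otimes n_i$ whose eigenvalues
$\beta_1 \ge \beta_2 \ge \beta_3 > 0$ are the semiprincipal radii of the
orientation-distribution ellipsoid. The fractional anisotropy
$\mathrm{FA} = \tfrac{1}{\sqrt 2}\sqrt{(\beta_1-\beta_2)^2 +
(\beta_2-\beta_3)^2 + (\beta_3-\beta_1)^2} \big/
\sqrt{\beta_1^2+\beta_2^2+\beta_3^2}$ summarizes the degree of alignment.

Each active tip advances once per time step:

1. **Interpolate** the local EFD from the cell's eight Gauss points by a
   Log-Euclidean weighted mean, and the density linearly.
2. **Sample** a single contact-guidance direction $\theta$ from the
   interpolated EFD by Monte-Carlo rejection (emulating filopodial probing).
3. **Rotate** the current orientation $\psi$ partway towards $\theta$:
   $\psi_{new}$ is $\psi$ rotated about $u = \psi\times\theta/\lVert\cdot\rVert$
   by $\alpha \cdot \angle(\psi, \theta)$, with the fibril weight
   $\alpha \in [0,1]$ arbitrating between persistence ($\alpha = 0$) and
   contact guidance ($\alpha = 1$). $\theta$ is sign-aligned into $\psi$'s
   hemisphere first (fibrils are axes, not arrows), so anti-parallel guidance
   cannot occur.
4. **Extend** by $\text{rate}(t)\cdot\nu(\rho,\mathrm{FA})\cdot\Delta t$ along
   $\psi_{new}$.

Branches appear stochastically along recently grown segments; tips leaving
the domain are deactivated.

## Assumptions

* Fibrils deform independently (no fibril–fibril interaction), so an EFD
  transforms affinely under a deformation gradient.
* EFDs approximate collagen ODFs at spatial scales around 100 µm; grid cells
  default to 0.1 mm accordingly.
* Vessel segments and fibrils are axial quantities: $u$ and $-u$ are the same
  observation everywhere (sampling, ODFs, guidance).
* Matrix mechanics is prescribed, not solved: deformation enters only through
  `apply_deformation_field()`, which pseudo-deforms the stored EFD field
  under a user-supplied deformation-gradient field. Two-way mechanical
  feedback through cell tractions is out of scope (reported elsewhere to
  leave guidance insensitive at experimentally established traction levels).

# Pseudo-deformation

Under a deformation gradient $F$, unit-sphere directions map onto the
deformed distribution through the **net mapping** $F^n = F P$, which is
generally not symmetric: the deformed distribution is no longer an ellipsoid.
To keep a valid EFD after deformation we use the SPD left-stretch factor of
the polar decomposition $F^n = V^n R^n$ and take $F^p = V^n$ as the
**pseudo-deformed EFD** (`pseudo_deform()`), computed through the singular
value decomposition $F^n = U\Sigma W^T \Rightarrow V^n = U\Sigma U^T$, which
is robust near singular mappings. An earlier approach used
$\hat B = F^n (F^n)^T$ directly as the deformed tensor; its eigenvalues are
the *squares* of $V^n$'s radii, overstating physical stretch, and it is kept
only as a diagnostic (`b_hat_diagnostic()`).

## Why the verification works, and what it measures

The verification harness (`run_verification_suite()`) follows the
point-mapping protocol: every node $s^0$ of a subdivision-level-5 icosphere
(10,242 nodes) is mapped through $s = F^n s^0 / \lVert F^n s^0\rVert$ (true)
and $s^p = F^p s^0 / \lVert F^p s^0 \rVert$ (pseudo) and binned to facets.

A useful identity governs what this can show. The pushforward of the uniform
sphere measure under $u \mapsto M u / \lVert M u \rVert$ is the angular
central Gaussian distribution with parameter $A = M M^T$, with density
$f(u) \propto (u^T A^{-1} u)^{-3/2}$. Since
$F^n (F^n)^T = V^n R^n (R^n)^T (V^n)^T = (V^n)^2 = F^p (F^p)^T$, the true and
pseudo-deformed *continuous* distributions coincide exactly: removing the
rotation $R^n$ does not change the mapped orientation density at all. Every
nonzero discrepancy measured by the harness is therefore a discretization
effect — the two *finite* node sets differ (one is the other rotated by
$R^n$) even though their distributions agree.

The suite accordingly reports two kinds of comparison per load case:

* `delta_gfa`: the generalized fractional anisotropy
  $\mathrm{GFA} = \mathrm{std}(\Omega(r_i))/\mathrm{rms}(\Omega(r_i))$
  evaluated on the ODF *density values* at the mesh nodes, using the
  closed-form density of each mapping (`mapped_density()`). By the identity
  above this difference is numerical noise ($\sim 10^{-16}$); reporting it
  confirms the anisotropy-preservation property exactly.
* `delta_gfa_hist` and `fisher_rao`: the same comparison on the count-based
  facet histograms. These quantify the discretization-level disagreement of
  the finite samples: with 10,242 points in 320 facets the histogram GFA
  difference sits at a few times $10^{-3}$ and the Fisher-Rao distance
  (arccos of the Bhattacharyya coefficient, in degrees) stays below 4° over
  the moderate-strain regime — within the level attributable to finite
  sampling, and far from the 90° disjoint-support maximum.

## Histogram resolution

Mapped points are binned to the facet whose unit centroid maximizes the dot
product (ties, a measure-zero event, break to the lowest facet index). The
binning mesh is deliberately *coarser* than the mapping mesh: a histogram is
a multinomial estimate, and its per-facet noise scales as
$\sqrt{m/n}$ for $n$ points in $m$ facets. The default pairs the 10,242-node
mapping mesh with the level-2 icosphere (320 facets, ≈ 32 points per facet —
the usual threshold for a well-populated histogram). Binning the same points
on their own 20,480-facet mesh would put ~0.5 points in each facet and turn
both GFA and Fisher-Rao into pure sparsity artifacts (Fisher-Rao saturates
near 65° for *identical* distributions). Facet masses are counts without
area weighting — at level ≥ 2 the facet solid angles vary by < 7 % — with an
area-corrected density accessor (`odf_density()`) for glyph rendering.

One consequence worth stating: the point-mapped density of an EFD is
proportional to the *cube* of its radius function (the angular central
Gaussian law above), so the GFA of an EFD's histogram is systematically
sharper than its FA — for radii $(5,1,1)$, GFA ≈ 0.92 versus FA ≈ 0.77. GFA
tracks FA monotonically but equals it only at isotropy.

## Load cases

The verification sweep crosses three initial EFD families — uniform
$\mathrm{diag}(1,1,1)$, uniaxially aligned $\mathrm{diag}(5,1,1)$, planar
$\mathrm{diag}(3,3,1)$ — with four homogeneous load modes: uniaxial
$F = \mathrm{diag}(\lambda,1,1)$ and equibiaxial
$F = \mathrm{diag}(\lambda,\lambda,1)$ for $\lambda \in [0.5, 1.5]$, simple
shear $F = I + \kappa\, e_1\otimes e_2$ and pure shear
$F = \mathrm{diag}(1+\kappa, 1/(1+\kappa), 1)$ for $\kappa \in [0, 0.5]$,
each sampled at 11 evenly spaced points. These are the standard kinematic
forms consistent with the stated stretch/shear ranges; incompressibility is
not imposed on the tension modes. Every family is pre-rotated by
$R_z(45°)R_y(45°)R_x(45°)$ (a fixed extrinsic composition order, recorded
here because "45° about X, Y and Z" leaves it open) so that no load acts
along an EFD principal axis, which would make pseudo-deformation trivially
exact. The family radii are package choices anchored to the anisotropy
regimes used elsewhere in the package (the gradient endpoints); the fidelity
bounds hold for all three families, consistent with accuracy being
independent of initial anisotropy.

# Sampling and interpolation

**Fibril probing.** `sample_direction()` draws a point uniformly in the cube
bounding the ellipsoid in its principal frame, accepts it if
$\sum_i r_i^2/\beta_i^2 < 1$, normalizes, and rotates into the global frame.
Uniform-in-volume sampling followed by normalization yields a directional
density $\propto$ (radius)³ — sharper than the radius function itself. This
sharpened law *is* the package's definition of fibril probing; no
inverse-CDF sampling of ellipsoidal integrals is attempted. The acceptance
rate equals the ellipsoid-to-cube volume ratio ($\pi/6 \approx 0.524$ for a
sphere), so strongly elongated EFDs sample more slowly; a $10^6$-candidate
cap guards the loop.

**Tensor interpolation.** EFDs live at the eight Gauss points
($\xi = \pm 1/\sqrt 3$) of each cell. Interpolation uses the Log-Euclidean
weighted mean $\exp(\sum_i w_i \log P_i)$, which preserves symmetry and
positive-definiteness for any convex weights, is associative and cheap (one
$3\times3$ eigendecomposition, since the matrix logs are precomputed per
integration point). The affine-invariant (Karcher) mean is available behind
`method = "affine_invariant"` for sensitivity checks; for commuting tensors
the two coincide. To apply nodal-style trilinear weights to Gauss-point
data, the tip's natural coordinates are rescaled by $\sqrt 3$ and clamped to
$[-1,1]$ — the Gauss points are treated as a shrunken virtual hexahedron.

**Legacy vector mode.** For comparison with vector-field models, each
integration point can instead carry a single unit vector sampled from its
EFD exactly once at initialization; interpolation is then a normalized
weighted arithmetic sum (with a logged fallback to the highest-weight vector
on exact cancellation). The EFD field is retained in vector mode so the
velocity scale sees the same $(\rho, \mathrm{FA})$ inputs in both modes —
the two modes differ only in guidance, matching how growth velocities are
prescribed per matrix condition in culture comparisons.

# Growth parameters

All parameters live in `growth_config()` with these defaults:

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `alpha` | 0.5 | — | balanced persistence/guidance; scenario studies hold it fixed |
| `dt` | 0.125 | day | 8 steps/day; step length stays ≪ cell size |
| `nu$rho0`, `nu$b` | 2, 1.5 | mg/mL | Lorentzian center below the physiologic 3–5 mg/mL range so growth *decreases* with density there |
| `nu$fa0`, `nu$c` | 1.2, 1.0 | — | center above FA = 1 so growth *increases* with anisotropy on [0, 1] |
| `nu$d` | 0.05 | — | floor sustaining minimal non-negative growth |
| `nu$rho_ref`, `nu$fa_ref` | 3, 0 | mg/mL, — | calibration: unaligned 3 mg/mL collagen gives $\nu = 1$; the amplitude $a_\nu$ is rescaled at construction to enforce this |
| `sigmoid` | A = 1.5 mm, midpoint day 5, τ = 1.5 d | | culture-style growth burst peaking at ≈ 0.25 mm/day (≈ 10 µm/h), totaling ≈ 1.5 mm of tip path over 10 days |
| `linear` | 0.25 mm/day, 2-day ramp | | "linear growth after the first few days" kinetics for long-duration scenarios |
| `max_step` | 0.05 | mm | half the standard 0.1 mm cell edge — locality with respect to the *field* scale. Deliberately not tied to the local cell edge: the tumor-interface domain refines cells to 0.01 mm for geometric resolution, and a local cap there would bind before the density-dependent velocity scale does, erasing the very effect under study |
| `w_thresh` | 0.02 | — | vessel volume fraction above which extension arrests (linear mode); with 5 µm radius vessels this is a dense-plexus level |
| `vessel_radius` | 0.005 | mm | capillary-scale radius for the volume fraction |
| `branching` | mean threshold 0.5 mm, zenith N(60°, 15°) truncated to (0°, 90°], azimuth uniform | | the threshold is the exponential mean lineage growth between branches; the zenith law is a flagged stand-in (the underlying distributions are not published); azimuth is uniform by symmetry |
| `init_fibril_weight` | 0.3 | — | one guidance rotation applied to each seeded fragment orientation |
| `seeding` | 150 fragments/mm³, log-normal lengths (median 60 µm, σ_log 0.5), z-polarization β₃ᵖ = 0.3 | | fragments isotropic in XY (β₁ᵖ = β₂ᵖ = 1), flattened toward the culture plane; the length law is a flagged stand-in for the image-derived rational distribution, replaceable via `length_fn` |

The ν-coefficients, sigmoid parameters, branching distributions and seeding
density are not published quantities; they were fixed once from the
qualitative constraints above and are all config-exposed.

# Scenario generators

The builders generate the package's three study families procedurally:

* **Uniform cultures** (`build_uniform_culture()`): cubes (default 1 mm,
  0.1 mm cells) with homogeneous density (3 or 4 mg/mL) and homogeneous EFD
  aligned along X at low/med/high anisotropy
  ($\beta_1/\beta_2 \in \{1.3, 2.5, 5\}$, $\beta_2 = 1$, $\beta_3 = 0.5$ —
  the low/high anchors match the gradient endpoints below).
* **Anisotropy gradients** (`build_gradient()`): a 1.8 × 2.0 × 0.5 mm strip
  with proximal/middle/distal regions; $\beta_1$ ramps linearly 1.3 → 5.0
  (or 5.0 → 1.3) across the middle with $\beta_2 = 1$, $\beta_3 = 0.5$,
  flanks taking the adjacent end value. The baseline uses
  $(1.05, 1, 0.95)$ — "relatively isotropic" implemented with a
  non-degenerate spectrum so spectral axes stay well defined.
* **Tumor interfaces** (`build_tacs()`): periphery/interface/tumor stacked
  along Y with an 80 µm interface refined to 0.1 × 0.04 × 0.01 mm cells.
  TACS-1 raises interface density to 5 mg/mL; TACS-2 aligns interface
  fibrils in-plane along the interface; TACS-3 aligns them across it, toward
  the tumor; combinations compose. Aligned interface radii default to
  $(5, 1, 1)$.

**What the generators emulate — and what they do not.** They reproduce the
*structural* conditions of microvessel culture and tissue-interface studies:
geometry, density and anisotropy fields, fragment seeding statistics and
replicate seeding. They do not emulate matrix mechanics (no solver), cell
tractions or their feedback on fibril orientation, biochemical gradients,
anastomosis, or image-formation effects (confocal depth of field,
segmentation noise). Passing scenario tests therefore demonstrates that the
guidance and kinetics rules produce the expected *directional orderings*
under the stated structural fields — not that absolute lengths match any
particular wet-lab measurement.

# Numerical choices

* EFD symmetry is enforced by $(P+P^T)/2$ at construction; inputs that are
  not positive-definite after symmetrization are rejected, not repaired.
  Symmetry deviations above $10^{-12}$ (relative) are errors.
* Radii sort descending; for degenerate spectra any orthonormal completion
  is accepted, and all downstream operations are invariant to the choice.
* `pseudo_deform()` takes a fast path when $F^n$ is already symmetric
  (zero strain, axis-aligned affine cases): the polar factor of an SPD
  matrix is itself, returned bit-exactly. This keeps zero-strain sweep
  members at exactly 0° Fisher-Rao instead of tie-break noise at shared
  mesh vertices.
* Facet assignment ties break to the lowest index; histogram masses must sum
  to 1 within $10^{-9}$.
* The axis-ratio fit uses the length-weighted axial second-moment tensor of
  the 180-bin planar ODF (1° axial bins); the ratio of the square roots of
  its eigenvalues is the reported semiprincipal axis ratio, capped at 50 for
  degenerate single-axis histograms. The published ellipse-fitting procedure
  is not specified; the structure-tensor fit is the standard choice and is
  validated against an analytic forward oracle in the tests.
* A tip crossing a cell face finishes its step with the field of the cell it
  started in (no sub-step re-sampling); the next step uses the new cell.
  Tips touching the domain boundary are trimmed to it and deactivated —
  there is no wrapping or reflection.
* Segment length is credited to the cell where the step started (steps are
  at most half a standard cell edge), and seeded fragment length to the cell
  containing the fragment center; totals are conserved exactly.

# Study sizes used by the test suite

The test suite reproduces the headline behaviors at sizes chosen to keep a
full run near five minutes: culture polarization on 0.8 mm cubes with 3
seeds per condition (branching off, as in velocity-comparison protocols);
gradient recruitment on a half-width (y = 1 mm) strip with 10 seeds over 12
days; tumor-interface gating at x-width 0.4 mm with 10 seeds over 10 days.
Orderings — polarization increasing with anisotropy, EFD mode out-polarizing
vector mode at high anisotropy, gradients recruiting vessels to middle and
distal regions with the negative gradient strongest at short range, TACS-3
recruiting and TACS-1 blocking with TACS-1+3 canceling to baseline — are
asserted on seed-averaged metrics; no absolute lengths are asserted.

# Known limitations

* One-way coupling only: prescribed deformation fields pseudo-deform the
  matrix, but growing vessels never deform it back.
* The branching zenith law and initial-length distribution are stand-ins
  with published-shape defaults, exposed for replacement.
* Count-based histograms make GFA resolution-dependent (see above); compare
  GFA values only between histograms of identical resolution, or use
  density-based values.
* Boundary deactivation makes long simulations in small domains lose tips;
  scale the domain with the expected total tip path.
* The rejection sampler's cost grows with EFD elongation (acceptance
  $\propto \beta_2\beta_3/\beta_1^2$); extreme anisotropies
  ($\beta_1/\beta_3 \gtrsim 100$) warrant a reparameterized sampler.
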