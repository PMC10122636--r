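---
title: "Inverse bone (re)modeling with micro and homogenized FE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse bone (re)modeling with micro and homogenized FE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Bone (re)modeling is mechanosensitive: trabecular microstructure adapts so
that the local mechanical stimulus stays near a homeostatic set point.
Inverse bone (re)modeling (IBR) runs this argument backwards — given a
microstructure, it infers the loading that would keep the tissue
homogeneously at that set point. The stimulus used here is the strain
energy density (SED), $U = \tfrac12\,\sigma:\varepsilon$, in MPa.

A set of $n$ unit load cases is applied to an FE model of the bone. With
per-element SED fields $U_i(x)$ and a tissue target stimulus
$\tilde U$ (0.02 MPa by default, equivalent to
$\sqrt{2\tilde U/E} \approx 1826\,\mu\varepsilon$ at $E = 12$ GPa), IBR
finds SED scale factors $s_i \ge 0$ minimizing

$$ r(s) = \int \Big( \sum_{i=1}^n s_i U_i(x) - \tilde U \Big)^2 \, dV. $$

Discretized over elements with volumes $V_e$, this is a non-negative least
squares (NNLS) problem on the $\sqrt{V_e}$-row-weighted system; load scale
factors follow as $\alpha_i = \sqrt{n\,s_i}$, and predicted physiological
forces as $F_\mathrm{opt} = \sum_i \alpha_i F_i$ from the unit reaction
forces $F_i$. Note that $\sum_i s_i U_i$ is the method's *defined* scaled
stimulus; it is not the SED of the superposed displacement field (cross
terms are deliberately ignored — SED is quadratic, load directions are
optimized independently).

Micro-FE (µFE) models resolve the microstructure (one trilinear hexahedron
per bone voxel) and can use the tissue target directly. Homogenized FE
(hFE) models replace the microstructure by a density-mapped continuum, so
the target must move to the continuum level as well. The package uses the
density-dependent continuum target

$$ \tilde U_\mathrm{hom}(x) = \tilde U_0\, \rho(x)^d, $$

with $\tilde U_0 = \tilde U$ so the two levels agree at full density
($\rho = 1$), and $d$ calibrated on homogenized trabecular cubes: each cube
is loaded with six canonical KUBC load cases, tissue-level IBR is run, the
optimized continuum stimulus
$\langle U_\mathrm{opt}\rangle = \tfrac12\sum_i s_i \langle\sigma_i\rangle :
\langle\varepsilon_i\rangle$ is evaluated from the volume-averaged stresses,
and $d$ is fitted to the $(\rho, \langle U_\mathrm{opt}\rangle)$ cloud by
one-dimensional nonlinear least squares. The package default `d = 1.19` is
the value calibrated on a large set of real trabecular cubes under exactly
this protocol; `run_cube_study()` recalibrates it for any other generator
or boundary-condition choice (the synthetic-world value recovered by
`scripts/acceptance.R` is ≈1.3 — boundary conditions and microstructure
statistics shift the exponent, which is why recalibration is part of the
workflow rather than a constant).

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `Ustar` | 0.02 | MPa | tissue target stimulus (homeostatic SED) |
| `E`, `nu` | 12000, 0.3 | MPa, – | isotropic tissue material for µFE |
| `kubc_displacement` | −0.001 | mm | KUBC face displacement on cubes |
| `section_displacement` | 0.01 | mm | canonical section load magnitude |
| `d` | 1.19 | – | continuum stimulus density exponent |
| `hfe_element_size` | 1 | mm | homogenized element edge |
| `sphere_diameter` | 5 | mm | density sampling sphere (2.5–3 mm on small phantoms, so several spheres fit across the section) |
| `rho_threshold` | 0.01 | – | drop hFE elements below this density |

Units are fixed to mm–N–MPa, so SED is in MPa (= mJ/mm³).

KUBC uniaxial cases apply $\bar E_{kk} = -d/L$; shear cases use the tensor
convention $\bar E_{kl} = -d/(2L)$, i.e. the face tangential displacement
magnitude equals $d$ (an `engineering` flag switches to $-d/L$). Apparent
stress is averaged over the *total* cube volume with pores contributing
zero, which makes $\tfrac12\langle\sigma\rangle:\langle\varepsilon\rangle$
the apparent energy density consistent with $\rho$ as BV/TV.

Material mapping presets (power laws in relative density, and fabric for
the orthotropic model):

* cortical density-only: $E_0 = 12000$, $\mu_0 = 4615.4$ MPa, $k = 1.63$ —
  the implied Poisson ratio $E_0/2\mu_0 - 1 = 0.300$ matches the µFE tissue
  value;
* trabecular density-only: $E_0 = 8812.8$, $\mu_0 = 3536.0$ MPa, $k = 1.63$;
* trabecular density+fabric (Zysset–Curnier type): $E_0 = 10320.4$,
  $\mu_0 = 3470.7$ MPa, $\nu_0 = 0.2278$, $k = 1.62$, $l = 1.1$, with
  $E_i = E_0\rho^k m_i^{2l}$, $G_{ij} = \mu_0\rho^k (m_i m_j)^l$,
  $\nu_{ij} = \nu_0 (m_i/m_j)^l$ in the fabric eigenbasis. The *standard
  compliance parameterization* is implemented; fabric eigenvalues are
  normalized to $m_1 m_2 m_3 = 1$ (determinant-one convention). Other
  parameterizations of this model family exist; anyone calibrating their
  own constants should confirm the form matches.

## The synthetic-data world

No public µCT data accompany the methodology, so every downstream stage is
exercised on synthetic microstructures:

* **Cubes** — thresholded Gaussian random fields: white noise smoothed with
  an anisotropic Gaussian kernel ($\sigma$ per axis = correlation length ×
  anisotropy weight, weights normalized to geometric mean 1) and
  thresholded at the quantile giving the requested BV/TV. Defaults emulate
  5.3 mm trabecular cubes; the correlation length default of 0.5–0.6 mm
  matches typical human trabecular spacing. The bone phase is reduced to
  its largest **face-connected** component. (Full 26-connectivity, the
  usual image-processing choice, is *not* sufficient mechanically: voxels
  joined only through an edge or corner share too few nodes and leave
  rigid hinge modes that make the stiffness matrix singular — this was
  observed, not hypothesized.) Phantoms that do not percolate between the
  constrained faces are re-seeded a bounded number of times, then error.
* **Sections** — a prismatic GRF core percolating along axis 3, optionally
  wrapped in a fully solid cortical shell on the four lateral faces.
  Acceptance phantoms use a radius-section-like aspect ratio (wider than
  tall, e.g. 12 × 12 × 8.4 mm): slender phantoms respond to the shear load
  cases in bending, which suppresses the transverse reaction forces that
  the model comparison needs.

What the generator does **not** emulate: realistic trabecular morphometry
(plate/rod mixtures, Tb.Th distributions), image noise and PSF, grayscale
calibration, and cortical porosity. A green test therefore establishes that
the *method* behaves as specified on controllable inputs — not that any
particular biological conclusion transfers.

## Numerical choices

* Trilinear (8-node) hexahedra everywhere, including the coarse hFE grid.
  Quadratic hexahedra would be the conventional choice for coarse
  homogenized voxel models; the order reduction keeps one element
  formulation for both scales and is acceptable because IBR compares
  integrated SED fields, not local stress peaks.
* 2×2×2 Gauss integration (exact for rectangular trilinear elements);
  stress, strain and SED are reported at the element centroid.
* Direct sparse Cholesky (CHOLMOD) on the reduced system; one
  factorization is shared by all load cases with the same constrained set
  (the six KUBC cases, notably). Singular systems are reported as
  disconnection errors.
* Distal section nodes are constrained **only along the load direction**
  (transverse components free); a `fix_transverse` flag prescribes all
  three components. The fully-prescribed variant is stiffer; with the
  free-transverse default the reaction in unconstrained directions is zero
  by equilibrium.
* NNLS is a deterministic Lawson–Hanson active set (ties broken by lowest
  column index). Duplicate load cases make the optimum non-unique; the
  returned split depends on the active-set order, but the total scale is
  exact.
* The exponent fit uses bounded golden-section search on $d \in [0, 5]$
  plus a Newton polish on the stationarity condition (accepting steps only
  if the SSE decreases).
* CV is the volume-weighted *population* standard deviation over the
  volume-weighted mean of the scaled SED; at the continuum level the field
  is divided by $\rho^d$ first, so "homogeneous" means "at target
  everywhere" despite heterogeneous density.
* Mapped densities above 1 are clamped to 1 with a warning (the power law
  is calibrated for $\rho \le 1$); densities between the 0.6 calibration
  ceiling of trabecular constants and 1.0 are used as-is, a documented
  extrapolation weakness of density-only voxel hFE models.
* MIL fabric: line probing along a quasi-uniform Fibonacci direction set,
  bundles launched from every entry face so the volume is fully covered;
  $1/\mathrm{MIL}^2$ is fitted by an ellipsoid and the fabric tensor is
  $H^{-1/2}$. Because the direction set is not permutation-symmetric,
  axis-relabeling equivariance is approximate (few percent).

## Design decisions that were genuinely open

* **Stress averaging volume.** Whether apparent stress should be averaged
  over bone or total volume is not fixed by the method description;
  total-volume averaging was chosen because it makes the apparent energy
  consistent with BV/TV-based density and with the KUBC homogenization
  convention.
* **Row weighting.** The discrete residual weights rows by $\sqrt{V_e}$
  (weighting residuals, not targets), which reproduces the volume integral
  exactly for piecewise-constant fields.
* **v-hFE material constants.** The voxel hFE branch maps the trabecular
  density-only law everywhere, including shell voxels averaged into the
  coarse grid; the cortical preset is available through the
  `cortex_mask` path of `build_hfe_model()` when a shell segmentation
  exists.
* **Anisotropy direction of the generator.** Anisotropy weights *multiply*
  the per-axis correlation length, so the largest fabric eigenvalue aligns
  with the largest weight — the orientation convention fabric estimators
  expect.

## Known limitations

* Only translational load cases; moments would need rotational unit loads.
* The scalar SED target ignores orientation information at the continuum
  level (bone is orthotropic there); tensorial stimuli are out of scope.
* KUBC overestimates apparent stiffness; the calibrated exponent is
  specific to these boundary conditions.
* Transverse components of the *optimized* forces are poorly identified on
  axis-3-dominant structures — the shear scale factors are frequently
  driven to zero by the NNLS — so only unit-force correlations are a
  robust cross-model check at desk scale (the same asymmetry is seen on
  real data).
* Pure-R assembly and CHOLMOD factorization limit practical µFE sizes to
  roughly $10^5$ degrees of freedom on one CPU; the pipeline defaults are
  deliberately desk-scale.

Every empirical number quoted here (the ≈1.3 synthetic-world exponent,
R² values, CV drops) is computed by `scripts/acceptance.R` or the test
suite at run time; none is asserted as a constant.
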