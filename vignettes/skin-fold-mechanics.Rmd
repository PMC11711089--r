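---
title: "Mechanics of crocodilian head-scale self-organization with scutes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of crocodilian head-scale self-organization with scutes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scutes)
```

## The biological problem

The polygonal scales on the head of crocodilians do not arise from
placodes, the genetically patterned primordia that build most skin
appendages. Instead they emerge mechanically: the embryonic facial skin
— a stiff, fast-growing epidermis bonded to a softer dermis over rigid
jaw bone — accumulates compressive stress as it grows and buckles into a
network of folds that tile the surface into polygonal domains. `scutes`
implements, at desk scale, the full computational chain needed to study
this process quantitatively: synthetic generators standing in for
light-sheet microscopy (LSFM) data, the image-derived field estimators
(layer boundaries, collagen fiber orientations, proliferation density),
a finite-strain growth simulator for layered tetrahedral meshes, a
curvature-based fold-network quantifier, Gaussian-process Bayesian
optimization of the mechanical parameters against target metrics, and a
morphospace sweep over stiffness and growth.

Everything downstream of raw microscopy is testable against known ground
truth because the inputs are generated by the package itself.

## The mechanical model

Skin is modelled as a layered tetrahedral mesh with per-element labels
(epidermis, dermis, bone). The bone layer is treated as a rigid
substrate: its nodes are clamped. Deformation follows finite-strain
theory: current positions $x(X, t)$ relate to reference positions $X$
through the deformation gradient $F = \partial x / \partial X$, which is
decomposed multiplicatively into an elastic part and a growth part,
$F = F_e F_g$.

**Growth.** Each element carries a local orthonormal frame
$(a_+, a_-, n)$ with $n$ the layer normal (taken from the nearest free
surface facet) and $a_\pm$ the in-plane directions, $a_+$ aligned with
the dominant collagen fiber axis where one is defined. Tangential growth
is prescribed as

$$F_g(t) = g_+(t)\, a_+ \otimes a_+ + g_-(t)\, a_- \otimes a_- +
  n \otimes n, \qquad
  g_\pm(t) = 1 + s(t)\, \rho(X)\, (G_\pm - 1),$$

where $G_\pm$ are the final tangential growth factors per layer, $s(t)$
is a monotone schedule ramping from 0 to 1, and $\rho$ is the
dimensionless, mean-one spatial modulation field obtained from
proliferation densities. The interpretation of the two superscripted
growth values as the factors along the two in-plane (fiber) directions
is a modelling choice; the `growth_tensor()` contract and its tests pin
it down. Epidermal growth is tied to 80% of the dermal values in the
control parameter preset, and an EGF-like treatment adds epidermal
tangential growth $\lambda_T$ accumulating linearly over a schedule
window and retained after it (which is what makes "arrest" scenarios
expressible: the rate returns to normal, the accumulated extra growth
stays).

**Elasticity.** Element energy uses the compressible neo-Hookean split
plus a tension-only quadratic fiber reinforcement:

$$\Psi = \frac{\mu}{2}\left(J^{-2/3} I_1 - 3\right)
      + \frac{K}{2} (J - 1)^2
      + \sum_{i=1,2} \frac{k_i}{2}\left(I_{4,i} - 1\right)^2
        \,[I_{4,i} > 1],$$

with $J = \det F_e$, $I_1 = \operatorname{tr}(F_e^T F_e)$ and
$I_{4,i} = a_i \cdot (F_e^T F_e\, a_i)$. Stiffnesses are relative — the
dermal Young's modulus is the unit, because only ratios matter for the
pattern. $(\mu, K)$ derive from $(E, \nu)$ by the standard isotropic
relations, and `moduli_to_elastic()` / `elastic_to_moduli()` convert
between the two parameterizations (the morphospace axes are $K$ and
$\mu$). The exact energy-gradient consistency of the assembled nodal
forces (relative error below $10^{-6}$ against central finite
differences) is the single most important invariant in the test suite;
frame indifference is checked to $10^{-10}$ over random rotations.

**Contact and quasi-statics.** Self-contact of deep folds uses a penalty
potential between free-surface vertices and non-neighbouring triangles
closer than a margin, with the topological neighbourhood excluded by
reference-frame distance; each pair interaction is equal and opposite.
Growth is ramped in increments and the mesh relaxed to quasi-static
equilibrium (maximum free-node force below `tol`) after each increment.
Two inner solvers are provided. The default minimizes the total
potential by limited-memory BFGS with the exact assembled gradient; on a
single CPU this reaches the buckled equilibria one to two orders of
magnitude faster than damped dynamics, which matters because buckling
bifurcations flatten the energy landscape. The alternative
(`solver = "dynamic"`, and the exported `mech_step()`) is damped
explicit relaxation with adaptive step control and an energy-increase
guard — the viscous-relaxation picture — and is used for the guarded
single-step contract. Both share the identical energy and force
assembly. Buckling from a perfectly flat state needs a symmetry-breaking
seed; a single random kick at growth onset is not enough, because it
relaxes away while the ramp is still subcritical and the quasi-static
solver then rides the flat unstable branch (a zero-gradient point) to
"convergence" without ever buckling. The simulator therefore re-applies
a seeded random nodal perturbation of amplitude $10^{-3}$ element sizes
before every growth increment: it nucleates the instability as soon as
one exists and relaxes away harmlessly when none does. Runs stay fully
deterministic given the `seed` argument. A related subtlety concerns
boundary conditions: a small patch with free lateral sides relieves
growth-induced compression entirely by sliding outward over the
substrate (the shear-lag length $\sqrt{E_f t_f t_d / \mu_s}$ exceeds
the fixture size), so it never folds no matter how hard it grows. The
phenomenology fixtures therefore clamp the lateral boundary
(`clamp_sides` / `clamp_ends`), emulating a patch embedded in a
laterally confined sheet; the default constructors leave the sides
free.

**Numerical caveats.** Linear (P1) tetrahedra with one quadrature point
match the per-element-constant-$F$ formulation but are bending-stiff:
a film meshed with a single element through its thickness will not
buckle at the analytic critical strain. The wrinkling benchmark
therefore resolves the epidermis with three elements through the
thickness, and quantitative onset/wavelength statements should be read
with the classical 25% band used in the acceptance criteria. Poisson
ratios close to 0.5 additionally lock P1 elements volumetrically; the
benchmark uses $\nu = 0.3$ where the analytic comparison is made.

## The synthetic data and what it does (not) emulate

The generators define the study conditions; their defaults are fixed
once and are not tuned per test.

* `make_nuclear_volume()` renders a two-slab nuclear channel: isotropic
  Gaussian nuclei (sd 1.2 µm, truncated at 3 sd) at 0.12 nuclei/µm³ in
  the epidermis versus 0.03 in the dermis in the fixture used by the
  recovery tests — densities typical of a packed embryonic epithelium
  versus mesenchyme, and high enough that the nuclear texture smooths
  into a density field at the 5 µm detection scale. The interface can
  undulate sinusoidally; both boundary surfaces are recorded as ground
  truth.
* `make_fiber_volume()` builds band-limited oriented textures. The
  convention, fixed package-wide, is that the prescribed (sign-free)
  axis is the dominant spatial-frequency direction: a grating with
  wavevector along the axis. The texture mixes a deterministic carrier
  (60% of the power) with oriented band-pass-filtered white noise (40%),
  normalized to unit contrast per rendering block; the carrier pins the
  realized spectral centroid on the prescribed axis so that estimator
  errors measure the estimator, not generator wander. Spatially varying
  axis fields are rendered blockwise.
* `make_edu_volume()` places quasi-spherical cells (Gaussian, sd =
  radius/2) with minimum separation $2r$, plus optionally flagged
  touching pairs at $1.5 r$ for the splitting test.
* `make_bilayer_patch()` and `make_jaw_proxy()` build conforming
  Kuhn-subdivided tetrahedral meshes of a flat bilayer on a rigid
  substrate and of a half-cylindrical jaw analogue with optional dorsal
  bone ridges.
* `make_fold_surface()` carves groove patterns (honeycomb lattice,
  serpentine labyrinth, parallel bands) into height-field meshes with
  exactly known graph topology.

None of these emulate optics: no point-spread function, attenuation,
or depth-dependent noise. Passing the recovery tests therefore shows
that the estimators are correct on clean, geometrically realistic
signal, not that they are robust to every real LSFM artifact.

## Image-derived fields

**Boundaries.** 3D Canny detection: spectral Gaussian smoothing (the
volume is replicate-padded before the FFT so no wrap-around edges
appear), gradient non-maximum suppression with sub-voxel parabolic
refinement along the gradient, and 26-connected hysteresis. The edge
cloud is split into outer surface and epidermis–dermis interface by
probing the smoothed intensity on the low side of each normal against a
background level, each sheet reduced to its largest connected component,
reconstructed by an oriented-point signed-distance field (Gaussian
blend of the k nearest tangent planes, Hoppe-style) isosurfaced with
marching tetrahedra, and Laplacian-smoothed. On the nuclear fixtures the
recovered surfaces sit within about one voxel of ground truth
(Hausdorff, interior), comfortably inside the two-voxel contract, and
the thickness field (normal-ray casting with a 30° deviation guard and
nearest-point fallback) recovers the prescribed epidermis thickness.

**Fibers.** Per 50³-voxel patch (Hann-windowed), the two dominant axes
come from FFT peak-picking on the folded half-spectrum outside a
DC-centred exclusion ball, with angular non-maximum suppression. Two
numerical choices matter: the dominance floor is calibrated to the
extreme-value statistics of white-noise spectra (a peak must exceed
`dominance_factor` times the expected maximum of exponential-like bin
powers, ~median · log₂ n), because a plain multiple of the median never
rejects the maximum over tens of thousands of bins; and the exclusion
cone widens automatically to cover the window mainlobe (~2.5 frequency
bins at the peak radius), without which window leakage fabricates a
second axis ~15–20° off the first. Axis refinement iterates a
power-weighted mean of sign-folded bin directions, giving sub-bin
accuracy (2–4° on the fixtures). Smoothing minimizes the quadratic
axis-mismatch energy in outer-product space $Q = aa^T$ — sign-free by
construction — as one exact sparse linear solve; interpolation onto
meshes fits graph-Laplacian eigenmode coefficients by (ridge-guarded)
least squares.

**Proliferation.** Signal principal curvatures are eigenvalues of the
negated Hessian of the smoothed intensity (bright-blob positive),
computed in closed form per voxel; $k_s = (k_1^+ k_2^+ k_3^+)^{1/3}$
clamps at zero unless all three are positive, which is what lets two
touching cells split where a plain intensity threshold merges them.
Centroids are intensity-weighted means of 26-connected super-threshold
components (default threshold: Otsu on positive $k_s$; minimum component
8 voxels). Densities divide counts by the mask-clipped volume of an
80³-voxel box, with centroids assigned to their nearest voxel so that
disjoint boxes tile space exactly; the growth modulation field is the
spectral interpolation of these samples normalized to mean one.

## Fold networks and their metrics

The deformed free surface is quantified by: per-vertex principal
curvatures from local quadric fits (sign convention: with outward
normals, concave grooves have $\kappa_{\min} < 0$); thresholding
$\kappa_{\min}$ — the default threshold is $0.25$ divided by the mean
mesh edge length, i.e. a groove is a concave feature whose radius of
curvature is below about four mesh edges. This resolution-scaled rule
was chosen over distribution-shape rules (quantile multiples, Otsu
splits), which fail on one regime or the other: carved fixtures have a
bimodal curvature distribution with a near-zero background, while
deeply creased simulation output is unimodal with a heavy crease-tip
tail. An empty network is returned for near-flat surfaces;
topology-preserving thinning of the masked region on the mesh graph;
and graph simplification. Three cleaning passes make the skeleton
graph-theoretically honest: zigzag 3-cycles inherent to thinning on
triangle meshes are broken at their longest edge; residual short cycles
(hairpin artifacts) below 8 mean edge lengths are broken likewise; and
short spurs are pruned iteratively. Vertices within two rings of the
mesh border are excluded from the mask (one-sided quadric fits are
unreliable there) and curve ends within four mean edge lengths of the
border count as anchored, so border-crossing folds are not mistaken for
incomplete edges. An incomplete edge is connected at exactly one end —
the signature of a fold still propagating through a domain.

The metrics vector holds the means of: number of domains (cycles of the
complete-edge graph, computed as $|E| - |V| + C$), domain perimeter
(planar face traversal in the dominant plane), edge length, edge
curvature (mean absolute discrete turning per unit length, measured on
endpoint-pinned smoothed polylines so mesh zigzag does not masquerade as
curvature), and incomplete-edge length. Normalization by the
bounding-box diagonal $D$ makes every component scale-invariant: lengths
divide by $D$, curvature multiplies by $D$, and the domain count divides
by area$/D^2$ — the paper-style normalization leaves counts and
curvatures under-specified, and this completion (documented here, fixed
in code) makes the whole vector invariant under uniform rescaling to
$10^{-6}$. Cohort z-scoring and the unweighted Euclidean distance on
z-scored components complete the objective used for optimization; the
z-scoring is precisely what makes unweighted Euclidean reasonable.

## Bayesian optimization

The surrogate is a Gaussian process with anisotropic squared-exponential
kernel on inputs rescaled to the unit cube, constant mean, nugget
$10^{-8}$, and hyperparameters by marginal-likelihood maximization
(refreshed every fifth acquisition for speed; reused in between).
Acquisition is expected improvement, maximized over a seeded
Latin-hypercube candidate pool with a local L-BFGS polish of the best
candidate; batches greater than one are diversified greedily in the
unit cube. Parameter presets apply the model's ties before every
evaluation: `control6_space()` spans {E_epidermis, nu_epidermis,
nu_dermis, G_dermis+, G_dermis−, k1} with E_dermis = 1, epidermal
growth at 80% of dermal, and k2 = 0; `egf3_space()` spans the
epidermis-only {E_epidermis, nu_epidermis, lambda_T} around a control
optimum. Desk-scale defaults (initial design 5 per dimension, stall
window 50, budget 150) replace the paper-scale 500-iteration stall rule,
which remains selectable. Non-finite objective values (failed or
non-converged simulations) are recorded with a penalty and optimization
continues.

## Problem sizes

The package is calibrated for a single CPU: test fixtures use 48³–64³
voxel volumes, flat patches of 10×10 to 24×24 elements (a few thousand
tets), a 96×2-element strip with the epidermis two elements thick for
the wrinkling benchmark, and 2-D/6-D optimization runs of at most ~80
evaluations. These sizes are the package's own desk-scale choices; the
same code paths scale to larger meshes with `n_increments`, `max_iter`
and the mesh constructors.

## Worked example

```{r example, eval = FALSE}
mesh <- make_bilayer_patch(24, 24, h_epi = 1, h_derm = 4,
                           element_size = 1)
mat  <- material_params(E_epidermis = 15, nu_epidermis = 0.4,
                        nu_dermis = 0.4)
spec <- growth_spec(G_derm_plus = 1.3, epi_ratio = 0.8)
sim  <- simulate_growth(mesh, mat, spec, n_increments = 5, tol = 1e-3,
                        seed = 3)
net  <- extract_fold_network(deformed_surface(sim))
v    <- network_metrics(net)
classify_pattern(v)
```

## Known limitations

* P1 tetrahedra overestimate bending stiffness; onset strains and
  wavelengths carry a resolution-dependent bias (kept inside the
  documented 25% band at the benchmark resolution).
* The fold extractor assumes grooves a few mesh edges wide; patterns
  near the mesh resolution alias.
* Epidermal stiffness is only weakly identifiable from fold-network
  metrics at desk scale (the wrinkle wavelength scales as $E^{1/3}$ and
  a small patch holds only a few waves), so the parameter-recovery
  demonstrations target the two dermal growth factors, which the
  metrics pin down to about a percent.
* Domain perimeters use a planar (PCA) embedding of the network — exact
  for patches, approximate on strongly curved surfaces (cycle counts
  remain exact).
* The semi-automatic bone segmentation path for weak-signal channels is
  out of scope; synthetic bone geometry is supplied directly.
* No optical forward model: estimator robustness claims extend to
  geometric noise, not to scattering or anisotropic PSFs.
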