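---
title: "Methods: tetrahedral colour space and the lineage-entry convergence test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tetrahedral colour space and the lineage-entry convergence test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, numerical choices and open design
decisions behind `tetraconv`, in the spirit of a methods supplement. It
states no empirical result that the test suite or the acceptance script do
not themselves compute.

## 1. The colour-space model

A reflectance spectrum $S(\lambda)$ viewed under illuminant $I(\lambda)$
by a four-receptor visual system with sensitivities $R_i(\lambda)$
produces quantum catches, von Kries-adapted to a background $S_b$:

$$Q_i \;=\; \frac{\int_{300}^{700} R_i(\lambda)\,S(\lambda)\,I(\lambda)\,d\lambda}
                 {\int_{300}^{700} R_i(\lambda)\,S_b(\lambda)\,I(\lambda)\,d\lambda}.$$

The normalised vector $q_i = Q_i / \sum_j Q_j$ is a barycentric coordinate
in a regular tetrahedron; the colour locus is $\sum_i q_i v_i$ where $v_i$
are the vertices. Key properties (all tested): the ratio cancels any
rescaling of $S$ or $I$; a stimulus equal to the background maps to the
centroid (the achromatic point); every physical spectrum lands inside the
tetrahedron.

**Vertex convention.** Published tetrahedral colour-space tools do not share a single printed
vertex convention, so the convention here is the package's own, fixed and
documented: a regular tetrahedron with unit edge,
centroid at the origin, receptor order short→long wavelength, and the
longest-wavelength vertex on the $+x$ side, so the long-wavelength ("red")
arm of the space extends toward $+x$. All occupancy percentages are taken
relative to the volume computed from these vertices, never hard-coded.

**Quadrature.** Trapezoidal rule on the common 1-nm grid (300–700 nm, 401
points). Against a 0.1-nm Riemann oracle on smooth stimuli the relative
error is below $10^{-3}$; discontinuous stimuli are representable but
their quadrature error is first-order in the grid step, which is why the
test fixture uses a steep logistic rather than a true step.

**Spectral processing.** Loess (degree 2) with fractional span, default
0.25 — there is no field-wide standard span, so a common
spectral-processing default was chosen once. Negative reflectance (sensor
noise) is clipped to zero by default; an additive-offset mode is provided
because the minimal published description ("remove negative values") does
not distinguish the two. Resampling is linear, with constant extension
beyond the measured range.

**Packaged curves.** The shipped VS/UVS sensitivities are *synthetic
stand-ins*: Govardovskii-template pigment curves at average avian
$\lambda_{max}$ values (VS 416/478/542/607 nm, UVS 372/456/544/609 nm),
with a Planck 6500 K illuminant and a parametric leaf-green background.
They make the pipeline runnable end to end but are not measured
average curves; for that reason no correctness test depends on them — unit tests use toy Gaussian receptors throughout.

## 2. Morphospace geometry

**Convex hulls.** Incremental (beneath–beyond) 3-D hull; exact volumes via
signed tetrahedra from an interior point. Degenerate inputs (< 4 points,
or rank < 3) return volume 0 with a flag. The independent oracle in the
tests enumerates candidate facet planes by brute force over all point
triples and estimates volume by seeded Monte-Carlo membership.

**Hull overlap.** Default exact mode clips one hull's vertex polytope by
the other's facet half-spaces (Sutherland–Hodgman style, recomputing the
hull between clips); a seeded Monte-Carlo mode with standard errors serves
as cross-check and fallback.

**Minimum-volume enclosing ellipsoid.** Khachiyan's barycentric ascent
with Wolfe–Atwood *away steps*. Plain ascent converges like $d/k$ and in
practice exhausts any sensible iteration cap long before a $10^{-7}$ duality
gap; away steps restore linear convergence (tens of iterations for the
point counts used here). Default tolerance $10^{-7}$, cap $10^5$. After
convergence the shape matrix is inflated by the maximal Mahalanobis form
of the generating points (a factor of $1 + O(\mathrm{tol})$), so the
membership invariant — every generating point inside, the worst exactly
on the boundary — holds exactly. Points on the boundary count as inside;
this convention feeds directly into the convergence counts. Rank-deficient
input either errors or, on request, returns a flagged covariance-shaped
region with a small ridge.

## 3. Phylogenetic machinery

**Ancestral states.** Per-axis maximum-likelihood reconstruction under
Brownian motion, computed by exact two-pass Gaussian message passing
(upward precision-weighted means, downward combination with the
parent-side message). This equals the dense GLS predictor
$\hat x_k = \hat\mu + c_k^\top C^{-1}(x - \hat\mu\mathbf 1)$ — verified to
$10^{-8}$ against an explicitly assembled covariance oracle — but is
linear in tree size and handles polytomies natively, with no tree
resolution step. Axes are reconstructed independently (matching the
behaviour of the standard `ace`-style routine) even though the simulation
null is multivariate; this asymmetry follows the established convention for this analysis and
is deliberate.

**Rate matrix.** Standardized independent contrasts per axis, with
sequential pairing at $k$-furcations (equivalent to zero-length-edge
resolution); the estimate is $U^\top U / n_{\text{contrasts}}$, PSD by
construction. Zero-length branches are perturbed to $10^{-8}\times$ tree
depth at read time with a warning.

**BM simulation.** Each branch adds a Gaussian displacement with
covariance $\Sigma\,\ell$ (symmetric matrix square root, so PSD rate
matrices with zero eigenvalues are legal). States are returned for *all*
nodes because null convergence counting needs internal states. Replicate
$r$ of a multi-replicate run uses seed $\texttt{seed} + r$ and is
bit-identical to a standalone `simulate_bm()` call with that seed (tested),
so the vectorised null loop is purely an optimisation.

## 4. The convergence test

The convergence index counts branches whose parent endpoint state is
outside the target region and whose child endpoint state is inside.
Endpoint states only: a branch passing through the region "in flight" is
unobservable under ASR and is not counted. Diversification entirely inside
the region contributes nothing; a lineage that exits and re-enters counts
once per entering branch. If the root lies inside the region, only
exit-then-reentry can contribute — this falls out of the definition with
no special casing.

The null fixes the region *from the observed data* and scores BM
replicates against it; re-deriving a region per replicate would test a
different hypothesis. The root of the null simulations is the observed
root reconstruction, and the rate matrix is the contrasts estimate from
the observed tips — both are the minimal choices consistent with simulating neutral
evolution of the observed data on the observed tree.

Two null-scoring modes are provided, because internal states of a null
replicate can either be taken directly from the simulation or
re-reconstructed from its simulated tips, and both readings are
defensible:

* default — use simulated internal states directly. Observed internal
  states are ASR point estimates (shrunk toward the interior), while null
  internal states are raw BM draws (more variable), so this mode is
  *conservative* for regions away from the root.
* `reconstruct_null = TRUE` — re-run ASR on each replicate's tips,
  making observed and null states exactly comparable, at linear extra
  cost.

The p-value is the add-one estimator $(1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n_{\text{sim}})$, which reproduces $p = 0.001$ at 999
simulations when no null count reaches the observed index and never
returns 0. Holm's step-down correction is applied table-wide;
`stats::p.adjust(method = "holm")` serves as the independent oracle in
tests.

## 5. The synthetic world

The generator emulates the structure of the empirical inputs, not their
biology:

* **Trees** — Yule (pure birth, rate 1), rescaled to unit depth. Simple
  and parameter-light; adequate for calibration, but real angiosperm
  supertrees have polytomies, rate variation, and non-ultrametric error
  the generator does not model (polytomy handling is tested on hand-built
  trees instead).
* **Traits** — 3-D BM with isotropic rate 0.02 per unit depth, chosen
  once so tip spread (sd ≈ 0.14 per axis) occupies a realistic fraction of
  a unit-edge tetrahedron without escaping it routinely.
* **Spectra** — mixtures of logistic steps and Gaussian bumps with seeded
  noise, plus fixed flat, red-step, and leaf-background members. These are
  caricatures: no pigment chemistry, no measurement autocorrelation.
* **Planted convergence** — with pull $\pi$, each designated tip's
  terminal-branch displacement becomes $(1-\pi)\,d + \pi\,(t - x_{parent})$
  for attractor $t$; the target region is then the MVEE of the designated
  tips, mirroring how empirical targets are built from the taxa of
  interest. Keeping the alternative inside the BM family avoids endorsing
  an OU adaptive landscape the reproduced method deliberately does not
  assume.

A green calibration test therefore establishes that the test is not
anticonservative *under this stated world* (type-I ≤ 8% at nominal 5%
over 200 seeds) and has power against strong planted convergence (pull
0.8 on 10 of 100 lineages, ≥ 90% rejection over 50 seeds) — not that any
empirical convergence table is reproduced — that requires measured colour
loci and a dated phylogeny as inputs.

## 6. Known limitations

* No receptor-noise discrimination modelling (ΔS), cone abundances, or
  double cones — loci are chromaticity only.
* Geometry is 3-D by design; nothing generalises to higher-dimensional
  morphospaces.
* Exact hull overlap relies on hull recomputation between clips — robust
  for the few-hundred-point clouds intended here, not for large inputs.
* The red-arm/non-red-arm subgrouping is consumed from the species table;
  the gap-based visual definition used in the source study is not
  algorithmic and is not re-derived.
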