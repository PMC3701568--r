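---
title: "ERBLS segmentation: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERBLS segmentation: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erbls)
```

## The segmentation problem

CT-like grayscale images combine three difficulties that defeat global
two-class methods: smooth multiplicative intensity inhomogeneity (bias
fields from acquisition physics), blurred edges, and boundaries that are
locally absent — a cortical shell that fades out over part of its arc.
The ERBLS model addresses them by combining an edge force, a *local*
region force, and a regularization term that removes the classical
re-initialization step of level set methods, and by making the whole
pipeline automatic through Otsu-threshold initialization.

## Energy and evolution

The contour is the zero set of φ (φ > 0 = foreground). The energy has
three parts — a geodesic length weighted by the edge detecting function,
a signed-pressure region term, and a penalty on deviation of |∇φ| from 1:

$$E(\varphi) = \beta \int edf\,\delta_\varepsilon(\varphi)\,|\nabla\varphi|
 \;+\; \gamma \int rdf\;H_\varepsilon(\varphi)
 \;+\; \mu \int \tfrac{1}{2}\,(|\nabla\varphi| - 1)^2 .$$

Gradient descent gives the update implemented in `erbls_step()`:

$$\varphi \leftarrow \varphi + \Delta t\Big[
 \beta\,\delta_\varepsilon(\varphi)\,
   \mathrm{div}\!\big(edf\,\tfrac{\nabla\varphi}{|\nabla\varphi|}\big)
 + \gamma\,rdf\,\delta_\varepsilon(\varphi)
 + \mu\big(\Delta\varphi -
   \mathrm{div}\tfrac{\nabla\varphi}{|\nabla\varphi|}\big)\Big].$$

`H_ε` and `δ_ε` are the arctan/Cauchy pair; δ_ε has global support, so
forces act (weakly) away from the contour rather than in a hard window.
The local means c1, c2 are recomputed from the current φ at the start of
every step and held fixed within it (fully explicit scheme).

### The region force and its sign structure

`compute_rdf()` compares each **pixel's own intensity** against the
midpoint of the kernel-weighted local means:
$rdf = (I - \frac{c_1+c_2}{2}) / \max|\cdot|$. This is the signed-pressure
construction with the global region means replaced by local ones. The
design was genuinely open between this form and one that compares the
*smoothed* intensity $g_\sigma * I$ against the midpoint; we chose the
pixel-intensity form because the smoothed variant is structurally biased:
near a boundary, smoothing drags bright shell pixels toward the
background value, they get classified outside, contaminate c2, and the
contour locks into a self-consistent equilibrium 2–3 px inside the object
(DSC plateaus near 0.85 on the packaged phantoms). The pixel form places
the equilibrium where the intensity crosses the local midpoint — the true
edge — and recovers every phantom at DSC ≥ 0.99.

With a hard inside/outside partition, rdf is *positive* deep inside a
bright object (where the window sees no outside pixels, c2 falls back to
the global outside mean) and negative outside, so the +γ·rdf·δ term grows
φ inside bright structures, consistent with the φ > 0 convention.
Normalization by the image-wide max is recomputed every iteration since
c1/c2 move with the contour; a raw field at rounding-noise level
(constant images) is treated as identically zero rather than normalized,
which would amplify floating-point dust into O(1) forces.

### The two-convolution cache

Of the four convolutions in c1/c2, `g_σ∗1` and `g_σ∗I` are
contour-independent and are computed once (`build_conv_cache()`); each
iteration then performs exactly two convolutions (`g_σ∗H`, `g_σ∗(IH)`),
verified by an instrumented counter (`conv_count()`). The LBF baseline
needs the fitting functions *and* four kernel smoothings of f1, f1², f2,
f2² per step — six convolutions here — which is the mechanism behind the
roughly-halved per-iteration cost.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `beta` | 5 | – | edge (geodesic curvature) weight |
| `gamma` | 2 | – | region (signed pressure) weight |
| `eps` | 1 | φ-units | Heaviside/Dirac width |
| `sigma` | 3 | px | region kernel scale (kernel size 2·⌈2σ⌉+1 = 13) |
| `sigma_g` | 3 | px | edge-detector smoothing scale |
| `dt` | 1 | – | explicit time increment |
| `mu_reg` | 0.2 | – | distance-regularization weight |
| `max_iter` | 500 | – | iteration cap |
| `stop_tol`, `stop_window` | 0, 10 | px, iters | stopping rule (below) |
| `c0` | 2 | φ-units | initial step height |

β, γ, ε, σ and Δt are the conventional operating point for 8-bit-range
images and are the defaults throughout. `sigma` and `sigma_g` play
different roles (region window vs edge smoothing) and are exposed
separately even though both default to 3.

**Stability of `mu_reg`.** The regularization flow is an (inhomogeneous)
diffusion; its explicit Euler discretization on a unit grid requires
`mu_reg * dt < 1/4`. With `mu_reg = 1, dt = 1` the high-frequency mode
grows by a constant factor per iteration and the field overflows after a
few hundred iterations regardless of the image. The default 0.2 is the
canonical weight used with Δt = 1 in distance-regularized level set
practice; `erbls_step()` reports non-finite values as an evolution error
naming the iteration, which is the symptom of choosing `beta*dt` or
`mu_reg*dt` too large.

## Numerical choices

* Central differences with replicated-edge (Neumann) boundaries for all
  first derivatives; five-point Laplacian. These are exactly testable
  against loop-based oracles.
* |∇φ| denominators are guarded as √(|∇φ|² + η²), η = 10⁻¹⁰: flat
  plateaus contribute zero curvature instead of 0/0.
* Convolutions are separable Gaussians with symmetric (reflect) boundary
  extension, so `g_σ∗1 ≡ 1` exactly and border pixels see no dark halo
  that zero padding would inject into c1/c2.
* Local-mean denominators below 10⁻¹² (a locally empty phase) fall back to
  that phase's global weighted mean, with a warning.
* The Otsu threshold maximizes between-class variance over a 256-bin
  histogram spanning [min, max]; ties — which genuinely occur, since the
  variance is constant across any empty inter-mode gap — break toward the
  smallest threshold. With well-separated modes any near-tie splits the
  modes equally well.
* Stopping: the zero set must change by at most `stop_tol` pixels for
  `stop_window` consecutive iterations. Fixed iteration counts would not
  adapt to the image; the chosen rule is deterministic and conservative
  (reported `n_iter` includes the stability window).
* φ is initialized as a ±c₀ binary step, *not* a distance function: the
  regularization term rebuilds the slope during evolution, which is the
  point of the re-initialization-free design, and the near-band deviation
  of |∇φ| from 1 demonstrably decreases from the step initialization to
  convergence.

## Automatic initialization and volumes

`init_levelset()` thresholds with Otsu, keeps the configured polarity
(bright foreground by default — the CT bone convention), optionally drops
components below `min_region_px` (20 px; thresholded CT maps contain
speckle), and emits the ±c₀ step. `segment_stack()` segments the middle
slice first and propagates each converged mask outward in both directions
as the neighbor's initialization, falling back to Otsu if a propagated
foreground is empty. Evolution parameters are identical for every slice.

## The phantom generator

`generate_phantom()` rasterizes parametric objects (discs, rings, and a
vertebra-like body: a bright ring with three process lobes), then applies
degradations in a fixed order — boundary gap, Gaussian edge blur,
multiplicative bias, additive Gaussian noise — leaving the ground-truth
mask untouched. The bias field is a seeded sum of three low-frequency
cosine modes normalized to the requested amplitude: smooth, bounded,
analytic and platform-stable. The boundary gap replaces the sharp edge
along an arc with a wide smooth radial ramp (discs) or erases the arc
(rings): locally there is no detectable edge, while far interior/exterior
intensities are preserved. Generation is a pure function of the spec
(bit-identical for identical specs) and restores the session RNG state.

The canonical suite (`fixture_suite()`) fixes the study conditions used
by the tests: 100×100 discs of radius 25 at intensities 200/50, bias
amplitude 0.4 with noise at one tenth of the contrast for the
inhomogeneity regime, σ = 3 blur for the blurred regime, a 20% boundary
gap, two discs for topology, a 9-slice stack whose radius drifts 2 px per
slice, and a 128×128 vertebra phantom. These sizes keep every test and
the acceptance script in the tens-of-seconds range on one CPU while
leaving all structures several kernel widths wide.

What the phantoms do **not** emulate: anatomical shape statistics,
partial-volume and beam-hardening physics, structured (non-Gaussian)
noise, or neighboring distractor anatomy. Passing the suite therefore
demonstrates the mechanisms (inhomogeneity-, blur- and gap-robustness,
topology handling, propagation) rather than clinical-grade accuracy.

## Known limitations

* **Capture range.** Because c1/c2 are local means, rdf vanishes wherever
  the kernel window sees no intensity contrast: the region force exists
  only within about one kernel radius of an intensity edge. Contours
  nucleate correctly at remote edges, but a large homogeneous interior
  farther than that from any edge can neither fill nor empty — a far-off
  small-box initialization converges to an annulus around the object, and
  a near-full-frame box strands background. Initialization must
  pre-classify interiors (Otsu does) or start within the capture basin;
  robustness to initialization is real but *relative* (the LBF baseline
  fails from initializations ERBLS tolerates), not absolute.
* **Propagation efficiency is conditional.** Slice-to-slice propagation
  saves iterations when the global initializer is rough (identical-slice
  stacks show it directly); when Otsu is already near-exact, as on the
  drifting phantom, moving the front across the inter-slice drift costs
  more than thresholding anew. Accuracy is unaffected.
* The front moves at most ~1 px per few iterations (δ-localized forces),
  so corrections far from the initialization are slow; the curvature term
  shrinks spurious far-field contours at O(1/r) speed, which is why the
  topology-change demonstration uses a 2000-iteration cap.
* Two-phase model only; no multi-region extension, no narrow-band or
  semi-implicit acceleration (full-domain explicit updates are cheap at
  ≤ 512² scale).
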