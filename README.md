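# erbls

Edge- and region-based level set (ERBLS) segmentation for 2D grayscale
images and slice stacks, aimed at the kind of data where simple global
methods fail: CT-like images with smooth intensity inhomogeneity (bias
fields), blurry edges, and locally discontinuous boundaries — vertebra CT
slices being the motivating case. The pipeline is fully automatic: an Otsu
threshold builds the initial contour, the level set refines it, and for
volumes each slice's result initializes its neighbor.

## The model

A contour is the zero level set of a scalar field φ (φ > 0 inside). The
field evolves by explicit Euler steps of

    ∂φ/∂t = β δ_ε(φ) div( edf · ∇φ/|∇φ| )        (edge term)
          + γ rdf δ_ε(φ)                          (region term)
          + μ ( Δφ − div(∇φ/|∇φ|) )               (distance regularization)

with the regularized step functions

    H_ε(z) = ½(1 + (2/π) arctan(z/ε)),   δ_ε(z) = H_ε′(z) = ε / (π(ε² + z²)).

* **edf** — edge detecting function `1 / (1 + |∇(G_σg ∗ I)|)`: ≈ 0 on strong
  edges, 1 in flat regions; it modulates the geodesic curvature force that
  holds the contour at boundaries.
* **rdf** — region detecting function, a normalized signed pressure
  `(I(x) − (c1(x)+c2(x))/2) / max|·|`, where c1 and c2 are Gaussian-kernel
  weighted mean intensities of the inside and outside phase around x
  (`c1 = g_σ∗(I·H_ε(φ)) / g_σ∗H_ε(φ)`, analogously c2). Because the means
  are *local*, a smooth multiplicative bias field shifts pixel and midpoint
  together and the sign pattern — expand where the pixel is brighter than
  the local midpoint, contract where darker — survives inhomogeneity.
* The regularization term is the gradient flow of ∫ ½(|∇φ|−1)², which keeps
  φ well-sloped near the contour, so the method never re-initializes φ to a
  signed distance function; a ±c₀ binary step is a valid initialization.

Two of the four convolutions needed for c1/c2 depend only on the image and
are cached before iteration, so each step costs exactly **2** convolutions.
The local binary fitting (LBF) model, included as a baseline
(`lbf_evolve()`), needs at least 4 per step — here 6 — which is the
structural basis of the efficiency comparison.

Evaluation uses the Dice similarity coefficient `2|A∩B|/(|A|+|B|)` and the
symmetric Hausdorff distance between boundary point sets, scaled by
physical voxel spacing.

## Worked example

Segment a seeded synthetic disc corrupted by a 40% bias field and additive
noise (contrast-to-noise 10), fully automatically:

```r
library(erbls)
suite <- fixture_suite(seed = 1)
fx <- suite[["bias-disc"]]            # $image and ground-truth $mask
res <- segment_image(fx$image)        # Otsu init + ERBLS evolution
print(res)
#> <erbls segmentation: 100x100, 20 iterations, converged, 1959 fg px>
dice(res$mask, fx$mask)
#> [1] 0.9994898
hausdorff(res$mask, fx$mask)          # px; pass spacing= for mm
#> [1] 1
plot(res, image = fx$image)           # contour overlay
```

The printed line says the contour stabilized after 20 iterations (the
zero set unchanged for 10 consecutive iterations) with 1959 foreground
pixels; the mask overlaps the ground truth at DSC 0.9995 and its boundary
is nowhere farther than 1 px from the true boundary.

Volumes work the same way through `segment_stack()`, which seeds the middle
slice with Otsu and propagates each converged mask to the next slice as its
initial ±c₀ step. A thin command-line wrapper is installed at
`inst/cli/erbls` (subcommands `segment`, `segment-stack`, `evaluate`,
`make-fixture`).

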