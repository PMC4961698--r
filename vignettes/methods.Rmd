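---
title: "nlfuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nlfuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model the package implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design decisions taken where the published description of this family of
methods leaves the implementation open.

## The segmentation model

`nlfuse` labels a subject volume by non-local label fusion over a library of
co-registered (intensity, label) template pairs. The working assumptions
are:

* all volumes share one grid (same dimensions and voxel size, typically
  1 mm isotropic) and have been affinely registered to a common space
  upstream;
* intensities have been standardized to a common tissue scale (the package
  provides this: CSF/GM/WM means mapped to 50/150/250), because every
  weight in the fusion is a function of raw intensity differences;
* label maps are integer-valued, with 0 reserved for background.

For a masked voxel $x_i$, every voxel $x_{s,j}$ within a cubic search
volume $V_i$ of each of the $N$ selected templates contributes a vote for
its label neighbourhood, weighted by

$$ w(x_i, x_{s,j}) \;=\;
   \exp\!\left(-\frac{\lVert x_i - x_j\rVert^2}{2\sigma_d^2}\right)\,
   \exp\!\left(-\frac{\lVert P(x_i)-P(x_{s,j})\rVert_2^2}{h^2(x_i)}\right), $$

gated to zero when the structural similarity between the two patches —
the luminance-times-contrast product
$\mathrm{ss} = \frac{2\mu_p\mu_q}{\mu_p^2+\mu_q^2}\cdot
\frac{2\sigma_p\sigma_q}{\sigma_p^2+\sigma_q^2}$ — does not exceed the
threshold `ss_threshold`. The bandwidth is adaptive,
$h^2(x_i) = \lambda\,\min_{s,j}\lVert P(x_i)-P(x_{s,j})\rVert_2^2 +
\varepsilon$, so that when the subject patch exists verbatim in the library
($\min = 0$, $h^2 = \varepsilon$) the exact match receives essentially all
the weight — this is what makes self-segmentation exact, a property the
test suite asserts.

Votes are block-wise: each accepted weight is distributed over the whole
label block $B(y_{s,j})$ (default $3^3$) around the matched template voxel,
and the per-voxel vote vector is the sum over all overlapping blocks
(overcomplete aggregation), normalized to sum to 1. Voting runs at two
patch scales $P_1 = 3^3$ and $P_2 = 5^3$; the two vote maps are averaged
with weights 0.5/0.5 (late fusion) and the final label is the per-voxel
argmax.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_templates` (N) | 25 | templates | library preselection size; more templates help until a plateau |
| `patch_size_1/2` | 3, 5 | voxels (cube edge) | similarity scales; small patches resolve thin structures, large ones context |
| `search_radius` | 4 (9×9×9) | voxels | non-local search extent; bounds the anatomical variability absorbed without non-linear registration |
| `block_size` | 3 | voxels | vote-block edge; 1 recovers classical voxel-wise fusion |
| `lambda` | 0.15 | — | bandwidth scale relative to the best match |
| `epsilon` | 1e-4 | intensity² | numerical floor of `h²`; also the self-match limit |
| `sigma_d` | √2 | mm | spatial bandwidth (locality principle) |
| `ss_threshold` | 0.9 | — | patch pre-gate; higher = stricter, faster, riskier at boundaries |
| `scale_weights` | 0.5/0.5 | — | late-fusion weights |

The intensity-normalization targets (50/150/250) and the TMS trimming
fraction (0.25) are exposed as parameters of `norm_targets()` and
`tms_estimate_means()`.

## Design decisions in detail

**Weight exponents.** The spatial factor is
$\exp(-d^2/(2\sigma_d^2))$ and the intensity factor $\exp(-\mathrm{SSD}/h^2)$
with $h^2$ as above. These forms are dimensionally consistent (mm² over
mm², intensity² over intensity²) and match the bilateral-filter analogy of
the method family.

**Structural similarity.** The published description of this gate does not
fix a formula; we use the luminance×contrast product from the original
label-fusion line of work, with a documented degenerate rule: two constant
patches have ss = 1 when their means are equal, otherwise the sd-term is
treated as 1. The threshold is a parameter.

**Template preselection.** Sum of squared intensity differences over the
region mask, ranked ascending with ties broken by library order. The
selection criterion is not pinned down in the method family's description;
SSD is the standard choice and is deterministic.

**Boundary handling.** Patches, blocks and search windows are cropped to
the grid; no padding is invented. Cropped patch distances are rescaled by
(full patch volume / valid voxel count) so that the minimum in the `h²`
rule compares like with like between interior and boundary candidates.
Votes are only cast to in-grid block members.

**Normalization order.** The per-voxel vote vector is normalized **after**
the overcomplete block aggregation (one normalization per voxel). The
alternative — normalizing each block's votes by its own total weight before
summing — is implemented behind `normalize_blocks = TRUE`; both paths are
verified against an independent brute-force oracle. Whether the published
method normalizes before or after the overcomplete sum is ambiguous; the
default was chosen because it keeps vote mass proportional to evidence
(strongly-matched blocks count for more).

**Ties and degenerate votes.** Argmax ties break toward the smallest label
value, which favours background for the conventional 0-first label sets and
makes the binary case resolve an exact 0.5 vote to background. Voxels where
every comparison is ss-gated receive a uniform vote over the labels
observed in their search volume and are counted (`n_fallback`) so callers
can inspect them.

**TMS internals.** The trimmed-mean tissue estimator is specified here as:
initialize the three class means at the 10th/50th/90th percentiles of the
masked intensities; iterate (a) nearest-mean assignment, (b) within each
class discard the 25% of voxels farthest from the class mean — the
partial-volume exclusion surrogate, since partial-volume voxels lie between
the pure-tissue modes — and (c) recompute each mean as the trimmed mean;
stop when the largest mean shift is below 1e-3 or after 100 iterations.
The exact estimator of the original trimmed-mean method is not published in
the source we follow; this stand-in has the stated properties (robust,
trimmed, excludes partial volume) and every piece is testable. Fewer than
three distinct intensity modes is an error, not a silent answer.

**Piecewise-linear mapping.** Breakpoints (0,0) → (μ_csf,50) → (μ_gm,150)
→ (μ_wm,250), linear extrapolation above μ_wm with the last segment's
slope, clipping at 0 below. The anchoring at the origin and the
extrapolation rule are our choices (the source is silent); both preserve
continuity and monotonicity, which the suite asserts property-style.

**Partial-volume model.** Two-tissue linear mixing between adjacent class
means with hard saturation outside [μ_csf, μ_wm]; the third tissue's
fraction is exactly zero. Crisp ties (fraction exactly ½) go to the
lower-intensity tissue. This is the simplest model consistent with
"fraction of each tissue per voxel", and it makes tissue volumes conserve
the intracranial volume exactly — the suite checks conservation to 1e-9
relative.

**PVO numerator.** The typeset reproducibility formula reads as the
L0-norm of the mask difference, which would give 0 for identical masks —
contradicting "percent volume overlap". We implement the intersection
form, `pvo = 100 · dice` (bit-identical by construction), and reject the
literal reading.

**Asymmetry ratio.** Not printed in the source; we use the signed
difference referenced to the mean, `100·(L−R)/((L+R)/2)`, consistent with
how the reproducibility metrics reference the mean of two segmentations.
The pair-level value is reported on both rows of a structure pair.

**Ventricle threshold.** The rule "ventricle voxels at normalized intensity
≥ 100 are not ventricle" originates as a label-definition convention; it is
implemented as an optional post-fusion cleanup (`apply_ventricle_threshold`,
and per-scale `ventricle` config block) because on the normalized scale
ventricular CSF (≈50) is well below the cutoff while GM-like partial-volume
voxels (≈150) are above it.

## The synthetic-phantom world

`make_phantom` rasterizes geometric primitives (spheres, ellipsoids, boxes)
with per-structure class means, an optional smooth multiplicative bias
field (seeded random low-order polynomial, amplitude expressed as a
fraction of intensity), and additive Gaussian noise. `make_library` derives
a template library by applying one random smooth displacement field per
template — Gaussian-smoothed white noise, scaled to a requested RMS
magnitude in mm — to the intensity (trilinear) and label (nearest-neighbour)
volumes jointly, then adding per-template noise. `flip_augment` mirrors
across a grid axis and swaps lateralized labels.

Defaults used across the tests are 2 mm RMS displacements with 8 mm
smoothness and σ = 5 intensity noise; the displacement amplitude of real
inter-subject anatomy is not quantified in the source, so this knob is a
stated choice, not a calibration.

What the generator emulates: co-registered pairs, tissue-like intensity
modes, smooth anatomical variability, left/right symmetry, bias fields.
What it does not: Rician/MRI acquisition noise, partial-volume ramps at
real tissue interfaces, cortical folding geometry, true inter-subject
anatomy. Consequently a green fusion test establishes algorithmic
correctness (the equations are computed as stated, equivariances hold,
accuracy behaves monotonically in library size) — it does not establish
clinical-grade accuracy on real MRI, which requires a manually labeled
library this package deliberately does not ship.

## Numerical notes and limitations

* All randomness is seeded and scoped (`with_seed` restores the caller's
  RNG state); fusion itself is deterministic.
* The voting kernel is exact (no approximate nearest-neighbour search);
  its cost is `O(mask × N × search³ × patch³)`. Desk-scale problems
  (≤ 64³ grids, ≤ 25 templates) run in seconds to minutes on one CPU;
  full-brain 181×217×181 runs are possible but slow in this reference
  implementation.
* NIfTI-1 support covers single-file 3D scalar images in the common
  datatypes, sufficient for co-registered segmentation workflows; complex
  orientation metadata is carried through, not interpreted, because the
  package never resamples.
* Identity-style floating-point assertions use a 1e-6 relative tolerance;
  oracle-equivalence assertions use 1e-10 absolute on vote values.
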