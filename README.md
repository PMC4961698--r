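# nlfuse

Multi-atlas **n**on-**l**ocal patch-based label **fus**ion for volumetric
brain segmentation, with the surrounding machinery a volumetry pipeline
needs: robust tissue-intensity normalization, partial-volume tissue
classification, segmentation/reproducibility metrics, and a seeded
synthetic-phantom generator so everything is testable without imaging data.

## Who this is for

Researchers and tool builders working on T1-weighted MRI volumetry who need
a transparent, scriptable implementation of patch-based label fusion — the
family of methods where a new image is labeled by transferring expert labels
from a library of co-registered template images, weighting every candidate
label by local patch similarity instead of relying on one-to-one non-linear
registration. All volumes are assumed co-registered on a common grid
(e.g. a 1 mm isotropic stereotactic grid); preprocessing (denoising,
bias-field correction, affine registration) is out of scope and assumed done
upstream.

## The method

For every voxel `x_i` inside a region mask, candidate voxels `x_{s,j}` of
the `N` most similar library templates are examined inside a cubic search
volume (default 9×9×9). Each comparison is weighted by

    w(x_i, x_{s,j}) = exp( -||x_i - x_j||^2 / (2 sigma_d^2) )
                    * exp( -||P(x_i) - P(x_{s,j})||^2_2 / h^2 )

where `P(.)` are cubic intensity patches, `sigma_d` (default √2 mm) is a
spatial bandwidth enforcing locality, and the bandwidth is adaptive per
voxel, `h^2 = lambda * min ||P(x_i) - P(x_{s,j})||^2_2 + epsilon`
(`lambda` = 0.15), so an exact library match dominates. Comparisons whose
structural similarity (luminance × contrast of patch means/sds) does not
exceed a gate (default 0.9) are skipped (weight 0). Weights vote for the
whole label **block** (default 3×3×3) around the matched voxel; overlapping
block votes are summed (overcomplete aggregation, an implicit label
regularizer) and normalized per voxel. Voting runs at two patch scales
(3×3×3 and 5×5×5) and the two vote maps are averaged (late fusion,
weights 0.5/0.5) before the final per-voxel argmax label decision.

Supporting stages:

* **Intensity normalization** — trimmed-mean clustering (`tms_estimate_means`)
  robustly estimates CSF/GM/WM mean intensities while excluding
  partial-volume voxels, then `piecewise_linear_map` standardizes the image
  so CSF/GM/WM land at 50/150/250.
* **Tissue classification** — `classify_tissues` computes partial-volume
  coefficients (per-voxel tissue fractions by two-tissue linear mixing) and
  a crisp CSF/GM/WM segmentation inside the intracranial mask; fractions sum
  to 1, so tissue volumes conserve the intracranial volume exactly.
* **Metrics** — `dice`, `pvd`/`pvo` (percent volume difference/overlap,
  referenced to the mean of the two segmentations), signed left/right
  `asymmetry_ratio`, and per-structure volumetry reports.
* **Phantoms** — `make_phantom`/`make_library`/`flip_augment` build seeded
  synthetic intensity+label worlds, smoothly deformed template libraries and
  mirror-augmented libraries (left/right label swapping included).

## Worked example

Segment a held-out synthetic template with a 9-template library:

```r
library(nlfuse)

base <- make_phantom(phantom_spec(
  grid_shape = c(40, 40, 40),
  structures = list(list(label = 1L, shape = "sphere",
                         center = c(20, 20, 20), radii = 8, mean = 150)),
  background_mean = 50, noise_sigma = 5, seed = 1))
lib <- make_library(base$intensity, base$labels,
                    deform_spec(n_templates = 10, displacement_amplitude = 2,
                                displacement_smoothness = 8,
                                per_template_noise_sigma = 5, seed = 2))
subject  <- lib[[10]]          # held out
training <- lib[1:9]
mask <- region_mask_from_library(training, labels = 1L, search_radius = 4)
seg <- segment(subject$intensity, training, mask, fusion_params(n_templates = 9))

dice(as.array(seg) == 1L, as.array(subject$labels) == 1L)
structure_volumes(seg, structure_dict(1, "sphere", "midline", NA))
```

Output (about 20 s on one CPU):

```
Dice vs held-out truth: 0.9709
    name label hemisphere volume_cm3 pct_icc asymmetry_pct
1 sphere     1    midline      2.117      NA            NA
```

A Dice of 0.97 against the held-out ground truth means the fused labels
recover the deformed, noisy structure almost voxel-for-voxel; `volume_cm3`
is the labeled volume (2117 voxels at 1 mm³).

The full pipeline (normalize → segment per scale → tissue PVC → reports) is
driven by `run_pipeline(config)` or the CLI in `inst/cli/`:

```sh
inst/cli/nlfuse phantom --spec spec.json --out world/
inst/cli/nlfuse run     --config cfg.json
inst/cli/nlfuse eval    --pred out/labels.nii.gz --truth truth.nii.gz
```

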