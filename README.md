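# stripequant

Quantification of stripe (shadow) artifacts in light-sheet microscopy,
comparing conventional Gaussian illumination with self-healing Bessel
beam illumination.

In light-sheet imaging of cleared tissue, any absorbing or scattering
object in the excitation path — a bubble on the tissue surface, a bright
absorbing structure, an incompletely cleared spot — casts a dark stripe
along the illumination direction. With a Gaussian sheet the stripe is
effectively semi-infinite; a Bessel beam's ring system refills the core
behind an obstacle of radius *r* within a conical shadow of length
*L = r / tan Θ*, where *Θ = (n − 1)α* is the cone angle of an axicon of
apex angle *α* and index *n*, with depth of focus *δZ = d/Θ* and core
radius *r_c = 2.405 λ / (2π sin Θ)*.

The package is aimed at microscopists and image analysts who want to
*measure* how much of an acquisition is compromised by striping, and by
how much a second illumination modality would recover, with every stage
verifiable on synthetic data:

- **Beam optics + wave oracle** — closed-form Gaussian/Bessel beam
  relations, hyperbolic beam-profile fitting, and an angular-spectrum
  propagator used to validate the shadow models (self-healing included).
- **Synthetic generator** — brain-like phantoms (vessels, somata,
  diffuse background in an elliptical mask), surface obstacles with
  known transmittance, bidirectional illumination, Bessel out-of-focus
  haze, Poisson + read noise, and exact ground-truth stripe masks.
- **Fourier stripe estimator** — directional wedge filtering isolates
  the stripe component; a relative shadow-depth rule binarizes it; the
  striped area is reported as % of brain area per slice (plus a rotated
  control direction), summarized over a volume by a Gaussian fit to the
  per-slice fractions.
- **Paired line-profile metric** — gain-matched column profiles of the
  two modalities, absolute relative difference, bar-code binarization at
  a chosen threshold (default 5%), and a threshold-sensitivity sweep.
- **Colocalization** — rigid registration, γ = 1.1, IsoData
  auto-thresholding, per-slice Manders coefficients both ways, paired
  t test across slices.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # paired TIFF stacks + manifests
Rscript analysis/02_stripe_fourier.R  # stripe area per slice + control
Rscript analysis/03_profile_metric.R  # bar-code metric + threshold sweep
Rscript analysis/04_coloc.R           # Manders coefficients + paired t
```

Output of a run (seed 1, a 192 × 256 × 12 phantom at 10.4 µm/px with
ten opaque surface obstacles, and a 96 × 128 × 6 vasculature phantom):

```
mean striped fraction (parallel): 11.44% vs ground truth 8.70%
mean perpendicular control:       0.55%
volume Gaussian-fit demo (8446 synthetic slice fractions drawn at peak 16.4%, SD 6.3%): recovered peak 16.37%, SD 6.30%
area affected by streaks at 5% threshold: 26.9 +/- 3.2% (mean +/- SD over 12 slices)
M (Gauss content present in Bessel): 0.968 +/- 0.003 (SEM)
M (Bessel content present in Gauss): 0.810 +/- 0.011 (SEM)
paired t = 13.29, p = 4.31e-05, n = 6 slices
```

Read: the Fourier estimator finds 11.4% of the brain area striped where
the generator actually shadowed 8.7% (the rotated control confirms the
detections are directional); the paired profile metric flags 27% of
positions as differing between the modalities by more than 5%; and the
Manders pair is asymmetric — the Gaussian channel misses a fifth of the
content the Bessel channel retains, while almost everything in the
Gaussian channel is also in the Bessel channel — with the ordering
strict on every slice.

The same chain is available as one call:

```r
library(stripequant)
r <- replay("out_dir", seed = 1)   # byte-reproducible report bundle
```

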