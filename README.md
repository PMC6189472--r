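# isquant

Quantitative imaging of receptor dynamics at the immunological synapse.

When a T cell engages a stimulatory surface — micropatterned antibody
spots, an antibody-coated bead, or a supported lipid bilayer presenting
mobile anti-CD3 — its receptors are recruited, partially immobilized, and
transported as microclusters into the central cluster (cSMAC) of the
immunological synapse. `isquant` implements the four quantification
families used to characterize this behaviour from confocal and TIRF
microscopy, for imaging scientists and immunologists analysing such
experiments:

* **FRAP analysis** — double/single normalization of recovery traces and
  least-squares fitting of two models: the single-exponential recovery
  `F(t) = A (1 − e^(−t/τ))` (mobile fraction `A`, halftime
  `t½ = ln2·τ`) and the one-dimensional strip-bleach diffusion model
  `F(t) = I_final (1 − √(w² / (w² + 4πDt)))` (plateau `I_final`,
  diffusion coefficient `D`, with both the conventional halftime
  `t½ = 0.22 w²/D` and the model-exact `t½ = 3w²/(4πD)` reported).
* **Enrichment** — segmentation of antibody spots (intensity threshold)
  and of cells (edge-based, from DIC images), and per-cell on-spot/off-spot
  enrichment ratios (1 = no recruitment), plus the contact/opposite
  membrane ratio for cell–bead experiments.
* **Microcluster dynamics** — intensity-weighted Mander's M1/M2 and
  Pearson co-localization time series with per-frame thresholding,
  relative integrated-density time courses, kymographs along a line, and
  centripetal transport speed from the streak slope.
* **Synapse scoring** — automated cSMAC detection per cell (area +
  centrality criteria) and the synapse-forming fraction per condition with
  a Wilson 95% CI.

A synthetic-microscopy generator with known ground truth (closed-form and
reaction–diffusion FRAP, spot scenes, bead scenes, two-channel synapse
time-lapses) backs every stage, so the whole pipeline is verifiable by
parameter recovery without any external data.

## Worked example

Simulate a noisy FRAP experiment with a 30% immobile fraction, normalize,
and fit:

```r
library(isquant)

spec  <- scene_spec("frap", seed = 1, f_imm = 0.3, tau = 2,
                    bleach_depth = 0.5, noise = noise_gaussian(0.02))
curve <- simulate_frap_curve(spec, n_pre = 10, n_post = 100, dt = 0.2)
fit   <- fit_frap_exponential(double_normalize(curve))
fit
#> <frap_fit:exponential> converged
#>   mobile fraction A = 0.6744  tau = 2.107 s  t_half = 1.461 s
#>   rss = 0.2521 over 100 samples
```

The fitted mobile fraction (0.674) recovers the simulated 0.70 within the
noise; the immobile fraction is `1 − A`, and `t_half` is the recovery
halftime in seconds. `glance(fit)` returns the same numbers as a one-row
tibble, `autoplot(fit)` overlays the fit on the data.

Enrichment at a cell–bead contact, on a noiseless synthetic scene built
with a threefold contact enrichment:

```r
bs <- generate_bead_scene(scene_spec("bead", seed = 2, shape = c(96, 96),
                                     noise = noise_none(), ratio = 3))
bead_enrichment(get_frame(bs$stack, 1, 1), bs$contact, bs$opposite)
#> # A tibble: 1 × 5
#>   ratio mean_contact mean_opposite n_contact n_opposite
#>   <dbl>        <dbl>         <dbl>     <int>      <int>
#> 1     3         54.4          18.1       320        320
```

The ratio of background-subtracted mean intensities over the two
equal-sized membrane ROIs is exactly the prescribed threefold enrichment.

See `vignettes/isquant-methods.Rmd` for the models, parameter defaults,
numerical choices and limitations.

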