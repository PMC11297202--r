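# texmod

Tools for the computational study of **edge-based versus region-based
texture perception**. The package is aimed at visual psychophysicists who
work with second-order textures: it synthesizes Gabor-micropattern texture
arrays whose orientation, contrast, luminance, or orientation/contrast
*variance* is modulated by sine (SN), square (SQ) or cusp (CS = square
minus equal-amplitude sine) waveforms; simulates two-interval forced-choice
adaptive staircases against synthetic Weibull observers; and fits a single
difference-of-Gaussians (DoG) filter to triplets of sensitivity curves to
recover the **spatial frequency at peak filter amplitude** — a single
scalar that separates region-based processing (low peak SF, broad filter)
from edge-based processing (high peak SF, narrow filter).

## The model

Observed sensitivities (1/threshold) for the three waveforms across
modulation frequency are fitted simultaneously by

```
DoG(x) = α/(γ√(2π)) · exp(−x²/2γ²) − αβ/(γδ√(2π)) · exp(−x²/2(γδ)²)
```

where α is the centre gain, β the surround:centre gain ratio, γ the centre
SD (grid samples) and δ the surround:centre SD ratio. Predicted
sensitivity is the peak absolute circular convolution of the filter with
each unit-amplitude waveform. The fitted filter is summarized by

```
SF_peak = w · √( ln(βδ²) / (2π²γ²(δ² − 1)) )        [cycles per image, w = 256]
```

cross-checked against the DFT argmax of the sampled profile, and by its
receptive-field extent (5 surround SDs, in degrees). For contrast-variance
(CVM) textures the DoG is fitted to the cusp-wave sensitivities alone and
the SQ and SN curves are modelled as exactly 1/2 and 1/3 of the fitted
amplitude. At unit amplitude the waveform rms energies are 1 (SQ), 0.71
(SN) and 0.48 (CS): the inverse of the detection-threshold ordering a
region-based energy integrator predicts.

## Worked example

```r
library(texmod)

# Synthetic threshold study: 5 texture types x 3 waveforms x 4 frequencies
# x 2 tasks x 3 participants, thresholds = noisy reciprocal sensitivities
# of documented per-task generating filters.
records <- generate_thresholds(generator_scenario(seed = 11))
nrow(records)
#> [1] 360

pipeline <- run_pipeline(records)
pipeline
#> <texmod_pipeline> 30 fit group(s), 0 failure(s)
#>   Detection threshold ordering SQ < SN < CS (non-CVM): holds at every texture x frequency
#>   Mean log peak SF lower for detection than discrimination: CM=yes LM=yes OM=yes OVM=yes
#>   Mean RF extent (deg) by task: detection=4.14 discrimination=2.69

head(pipeline$summary[, c("participant", "texture_type", "task",
                          "peak_sf_analytic", "r_squared", "rf_extent_deg")])
```

The report lines are the study's qualitative signatures: detection
thresholds follow the waveform energy ordering (region-based), the fitted
peak spatial frequency is lower — and the implied receptive field larger —
for detection than for discrimination, and CVM sensitivity rows are
proportional 1 : 1/2 : 1/3 (CS : SQ : SN).

Lower-level entry points: `sample_waveform()`, `rms_amplitude()`,
`fundamental_amplitude()`, `synthesize_texture()`, `run_staircase()`,
`estimate_convergence_level()`, `predict_sensitivities()`, `fit_dog()`,
`fit_dog_cvm()`, `peak_sf_analytic()` / `peak_sf_dft()`. The methods
vignette (`vignettes/texture-filter-model.Rmd`) documents the model,
parameter conventions, numerical choices and the synthetic-data generator.

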