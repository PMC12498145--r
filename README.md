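# hsflim

Depth-selective macroscopic fluorescence lifetime imaging (MFLI) with
high-spatial-frequency structured illumination — simulation, demodulation,
calibration and fitting, fully in silico.

## The problem

Wide-field time-gated lifetime imaging of thick turbid samples (tissue
phantoms, small animals) mixes signal from all depths into every pixel:
surface-weighted fluorescence (e.g. skin) biases fitted lifetimes and FRET
fractions of deeper targets. Projecting a sinusoidal pattern at a high
spatial frequency `fx` and acquiring three phase-shifted gated stacks lets
the signal be decomposed per pixel and per time gate:

    I_DC  = (I1 + I2 + I3) / 3                      planar component
    I_AC  = sqrt(2)/3 * sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2)
    I_sub = I_DC - I_AC                             subsurface component

High spatial frequencies survive only a shallow traversal of a scattering
medium, so `I_AC` is surface-weighted and `I_sub` retains the subsurface
decay, which is then fitted with the IRF-convolved model

    Gamma(t) = IRF(t) * [ A1 exp(-t/tau1) + A2 exp(-t/tau2) ]

with FRET fraction `f1 = A1(1-exp(-T/tau1)) / sum_i Ai(1-exp(-T/tau_i))` and
amplitude-weighted lifetime `tau_a = f1 tau1 + (1-f1) tau2`.

How deep a given `fx` still samples is calibrated by a fluorescence
modulation transfer function, `MTF(fx) = M_R / M_S` (sample over source
modulation depth), computed depth-by-depth with a two-step time-resolved
Monte Carlo engine: excitation transport through the voxelized phantom,
fluorescence source formation with local quantum yield and lifetime, and
emission transport back to the camera. A single uniform-illumination run
synthesizes every frequency and phase by reweighting photons with the
pattern value at their launch position.

The package contains the complete tool chain: gated-stack containers and
I/O, pattern generation and demodulation, the MC engine, phantom builders
(tilted tube, 8-tube depth ladder, scattering-free wells, two-layer), a
gated-ICCD camera model with noise, lifetime/FRET fitting, and end-to-end
pipeline drivers with a small CLI.

## Worked example

Demodulate one simulated acquisition of the depth-ladder phantom (three
1 mm dye tubes 0.4 / 1.4 / 2.4 mm deep, AF700-like 0.9 ns fluorophore) and
fit the subsurface decays at `fx = 0.6 mm^-1`:

```r
library(hsflim)

spec <- phantom_spec("depth_ladder", n_tubes = 3L, thickness_mm = 6)
cam  <- camera_model(gain = "auto", noise = "poisson", target_peak = 1100)
ds   <- generate_hsf_dataset(spec, fx_list = c(0, 0.6), camera = cam,
                             n_photons = 2e5, n_emission = 8e5,
                             pixel_pitch_mm = 0.375, seed = 5)
dm   <- demodulate_gated(ds$triplets[[2]],          # the fx = 0.6 triplet
                         shot_debias = TRUE)        # counts are Poisson
fm   <- fit_stack(dm$I_sub, ds$irf_gated, k = 1,
                  roi_labels = ds$roi_labels, weights = "none")
subset(fm$roi, quantity == "tau")
```

```
  roi quantity      mean         sd  n
1   1      tau 0.8813615 0.07705161 78
5   2      tau 0.8810415 0.08336886 52
9   3      tau 0.8758088 0.11528898 78
```

Each row is one tube: the mean fitted mono-exponential lifetime over the
tube's pixels, its SD and the pixel count. All three tubes recover the
0.9 ns ground-truth lifetime within a few percent from the
surface-subtracted component alone; the SD grows with depth as the photon
count drops (tube 3 sits 2.4 mm below the surface). The equivalent fits of
`I_DC` carry the same mean but mix in surface-weighted signal — the ROI
comparison tables of `run_hsf_fli()` put both side by side.

The depth calibration behind the choice `fx = 0.6`:

```r
cv <- mtf_depth_sweep(fx_grid = 0.6, depth_grid = c(0.5, 1.75),
                      n_photons = 6e5, n_emission = 1.2e6, seed = 11)
cv$values
```

```
                  fx_0.6
depth_0.5   2.314592e-02
depth_1.75 -8.973378e-05
```

At 0.6 mm^-1 the modulation surviving from a 1.75 mm-deep tube is
indistinguishable from zero (the sweep's synchronous estimator is unbiased,
so near-zero MTFs fluctuate around zero at the Monte Carlo noise scale —
here the standard error is ~3e-3) and in any case below 0.01, two orders of
magnitude down: the practical sectioning depth limit at that frequency
(half-period lateral resolution: `lateral_resolution(0.6)` = 0.83 mm).

## Command line

```sh
Rscript -e 'hsflim::hsflim_cli()' pipeline --config cfg.json --out runs/demo
Rscript -e 'hsflim::hsflim_cli()' mtf --fx 0.6 --seed 1 --out runs/mtf
```

Verbs: `simulate`, `demodulate`, `mtf`, `fit`, `pipeline`, `report`; configs
are JSON (see `?read_run_config`).

## Documentation

The methods vignette (`vignettes/hsflim-methods.Rmd`) describes the models,
the Monte Carlo engine and its oracles, the camera and phantom defaults,
estimator choices (synchronous vs magnitude demodulation, IRF time-shift,
residual weighting) and known limitations.
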