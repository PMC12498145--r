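---
title: "Depth-selective lifetime imaging with structured illumination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-selective lifetime imaging with structured illumination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Macroscopic fluorescence lifetime imaging (MFLI) of thick, turbid samples —
tissue phantoms, small animals — collects each camera pixel's signal from an
extended three-dimensional region. Surface-weighted signal (skin, superficial
layers) mixes with the subsurface signal of interest and biases fitted
lifetimes and FRET fractions. `hsflim` implements, fully in silico, an optical
sectioning strategy for time-gated MFLI: project sinusoidal illumination at a
high spatial frequency, acquire three phase-shifted gated stacks, and split
the signal into a planar component, a spatially modulated (surface-weighted)
component, and the residual subsurface component that is then fitted for
lifetimes.

# Models

## Three-phase demodulation

For three co-registered acquisitions $I_1, I_2, I_3$ under sinusoidal
illumination phase-stepped by $2\pi/3$:

$$I_{DC} = (I_1+I_2+I_3)/3, \qquad
I_{AC} = \frac{\sqrt2}{3}\sqrt{(I_1-I_2)^2+(I_2-I_3)^2+(I_3-I_1)^2},$$

and $I_{sub} = I_{DC} - I_{AC}$. For a noiseless sinusoid
$I_i = a + b\cos(\theta+\phi_i)$ this returns $(a, b, a-b)$ exactly for any
local phase $\theta$ — verified as a property test at $10^{-10}$. Applied
per gate, the same identity yields time-resolved $I_{DC}(t)$, $I_{AC}(t)$,
$I_{sub}(t)$ stacks. $I_{AC}$ is a magnitude, so under noise $I_{sub}$ can go
slightly negative; such pixels are clamped to zero and counted
(`clamp_count`), with a switch to keep signed values.

High spatial frequencies only survive a shallow traversal of a scattering
medium, so $I_{AC}$ is surface-weighted and removing it de-biases the deeper
signal. The depth calibration of that statement is the MTF below.

Because $I_{AC}$ is a magnitude, shot noise rectifies into a positive floor,
$E[I_{AC}] \approx 1.15\sqrt{\text{counts}}$ at zero modulation, which
suppresses the $I_{sub}$ tail and shortens fitted lifetimes of dim targets.
For Poisson-count stacks the floor is exactly estimable from the counts
($E[I_{AC}^2] = b^2 + \tfrac43 I_{DC}$), and `shot_debias = TRUE` applies
the unbiased-in-$b^2$ correction
$I_{AC} = \sqrt{\max(I_{AC}^2 - \tfrac43 I_{DC},\, 0)}$. The pipeline uses
it on noisy data; the plain identity remains the default (the correction
under-estimates on noiseless input, and measured data with non-Poisson gain
noise would need the instrument's variance model instead).

## Modulation transfer function

$\mathrm{MTF}(f_x) = M_R(f_x) / M_S(f_x)$, the ratio of sample modulation
depth ($M_R$, ROI mean of $I_{AC}/I_{DC}$) to source modulation depth
($M_S$, the same demodulation identity applied to the projected patterns
themselves). Note: one printed form of the defining equation in the source
literature multiplies the two modulation depths; only the quotient is
consistent with the standard spatial-frequency-domain definition and with the
zero-frequency limit $\mathrm{MTF}(0)=1$, so the quotient is implemented.
$M_S$ is computed from the ideal digital patterns by default (the simulation
knows its source exactly); an option accepts imaged patterns for real data.

## Two-step time-resolved Monte Carlo

The depth calibration runs photon transport through voxelized media
(absorption $\mu_a$, scattering $\mu_s = \mu_s'/(1-g)$, Henyey–Greenstein
anisotropy $g$, refractive index $n$):

1. *Excitation*: collimated photons launched at the top surface (uniform,
   pencil, or pattern-modulated); survival weighting
   ($w \mathrel{*}= 1-\mu_a/\mu_t$ per interaction), Russian roulette below
   $10^{-4}$ with survival chance 0.1, Fresnel reflection at the top boundary
   ($n_{in}/n_{out}$ mismatch, including the specular entry loss), absorbing
   side and bottom faces, photon clock $t = L\,n/c$. Absorbed energy is
   tallied per voxel; inside fluorescent voxels every absorption event is
   recorded with position, exact time, deposited weight and the photon's
   *launch x-position*.
2. *Emission*: source events are weighted by the local quantum yield; each
   emitted photon starts at an event position with time = excitation arrival
   + an $\mathrm{Exp}(\tau)$ delay (the stochastic realization of the
   $(1/\tau)e^{-t/\tau}$ kernel — total emitted energy is independent of
   $\tau$ by construction), and is transported to the surface under the
   emission-wavelength properties.

Energy bookkeeping (launched = specular + absorbed + escaped + roulette net)
is exact to $10^{-9}$ per run. Oracles in the test suite: Beer–Lambert
transmission in absorbing-only slabs, the Henyey–Greenstein first moment,
ballistic transit times, the $1/(d^2+r^2)$ obliquity profile of a transparent
point source, and the diffusion-limit fluence slope
$\mu_{eff}=\sqrt{3\mu_a(\mu_a+\mu_s')}$ (within 15%; diffusion is
approximate).

### Pattern synthesis by launch-position reweighting

Transport is linear in the source, so a *single* uniform-illumination run
synthesizes every spatial frequency and phase: each detected fluorescence
photon is weighted by the pattern transmission at its excitation launch
x-position. A dual-route test checks reweighted stacks against direct
pattern-modulated launching within MC error. This is what makes a full
frequency × depth MTF sweep a desk-scale computation (one two-step run per
depth, not per pattern).

### ROI demodulation estimators for the MTF

The per-pixel magnitude formula is rectification-biased upward when the true
modulation reaches the MC noise floor ($E|b+\varepsilon| > b$), which matters
exactly where the interesting claim lives (MTF $\sim 10^{-2}$ at depth). The
sweep therefore sums the three phase images over the tube-projection rows
(pattern phase is constant within an image column), forms the complex phasor
$z = \tfrac23 (P_1 + P_2 e^{-2\pi i/3} + P_3 e^{-4\pi i/3})$ per column, and
projects it onto the known source phase — linear in the data, hence unbiased
at any modulation depth; it can fluctuate below zero at the noise scale. The
magnitude route is kept for parity with measured data. Block-wise standard
errors are attached; a warning is raised when the budget leaves the standard
error above max(25% of the value, 0.002).

## Camera model and synthetic phantoms

The gated-intensifier model integrates the fine-time surface stacks over
boxcar (optionally trapezoid) gate windows — 101 gates of 300 ps width
stepped by 80 ps under a 12.5 ns laser by default, so gates overlap — after
convolution with a synthetic Gaussian IRF on the fine axis (FWHM 300 ps,
center 500 ps by default; the convolution is folded into the gate-weight
matrix, which is exact). Gain is either fixed or auto-scaled so the brightest
noiseless planar pixel reaches a target peak (default 1100 counts, half the
~2300-count scattering-free control level, matching the phantom experiment's
regime). Noise: Poisson per pixel per gate, optional Gaussian read noise,
saturation clip.

Phantom builders (`phantom_spec()` / `build_phantom()`):

* `depth_ladder` — eight 1 mm dye-filled capillaries, tube 1 at 0.4 mm, 1 mm
  depth increments; ladder bulk $\mu_a=0.02$, $\mu_s'=1$ mm$^{-1}$.
* `single_tube` — one capillary at a prescribed depth in the calibration bulk
  ($\mu_a=0.002$, $\mu_s'=1$); dye $\mu_a=0.04$, $\mu_s'=0.09$.
* `tilted_tube` — depth ramp along the tube for profile comparisons.
* `well_plate` — scattering-free dye wells (the control regime).
* `two_layer` — a thin surface emitter over a deep inclusion: the minimal
  geometry isolating the surface-removal claim.

Defaults chosen where the stated world is silent: field of view 24 × 24 mm at
0.1875 mm pitch (the 0.6 mm$^{-1}$ pattern keeps ~8.9 px/period; lifetime
experiments use 0.375 mm to concentrate photons per pixel), voxel 0.1 mm,
anisotropy $g=0.9$ and $n=1.37$ (agar/intralipid-like), block thickness 6 mm
for the standard runs (diffuse return from deeper bulk is negligible for
inclusions within 3 mm, and the MTF is a ratio), two-layer surface yield 5%
of the inclusion yield with a 0.5 ns surface lifetime versus 1.0 ns at depth.
FRET mixtures are realized by interleaving quenched/unquenched donor
lifetimes across inclusion voxels in amplitude proportion — at camera pixel
scale each pixel averages many voxels, reproducing the bi-exponential
mixture; explicit donor–acceptor photophysics is out of scope.

## Lifetime fitting

The forward model is $\Gamma(t) = \mathrm{IRF}(t) * \sum_i A_i e^{-t/\tau_i}$
(discrete linear convolution on the gate axis, no periodic wrap; the
incomplete-decay correction enters only through the $1-e^{-T/\tau_i}$ factors
of the FRET fraction). Fitting is variable projection: amplitudes (and
optional baseline) solved by non-negative weighted linear least squares at
each candidate lifetime set; lifetimes optimized by bounded L-BFGS-B in
log-$\tau$; $\tau$ bounds 0.1–5 ns; initialization from the tail log-slope
(last 40% of gates), $k=2$ starting at $(0.5, 1.5)\times$ that estimate;
output ordered $\tau_1 \le \tau_2$ ($\tau_1$ = quenched donor). Sub-threshold
pixels return masked results, not errors; the stack-level mask is
peak $\ge \max(50, 2\%$ of image peak$)$.

Two deliberate choices beyond the minimal model:

* **IRF time shift.** A free shift parameter (default on) aligns the IRF with
  the decay. The diffuse transit delay of mm-deep signal (~100–250 ps here)
  is physically present in the data but absent from the instrument response;
  without the shift, mono-exponential $\tau$ is biased +15–30% and $R^2$
  saturates near 0.93 *on noiseless data*. A fitted shift is standard
  practice in lifetime analysis tools.
* **Residual weighting.** Poisson (Neyman) weights $1/\max(y,1)$ are the
  `fit_nlsf()` default, but the pipeline fits use the unweighted option: the
  demodulated $I_{sub}$ tail carries the $I_{AC}$ rectification floor and MC
  counting noise, neither Poisson in the camera counts, and Neyman weights
  over-emphasize that biased tail (measured on the ladder experiment:
  $\tau$ −7% with weights vs −2% without).

FRET quantities: $f_1 = A_1(1-e^{-T/\tau_1}) / \sum_i A_i(1-e^{-T/\tau_i})$
and $\tau_a = f_1\tau_1 + (1-f_1)\tau_2$; $f_1 \to A_1/(A_1+A_2)$ as
$T/\tau \to \infty$ (tested at $T/\tau = 100$).

# What the generator does and does not establish

The synthetic world reproduces: the acquisition geometry (gates, laser
period, three phases, 8-bit patterns), the published phantom geometries and
optical properties, diffuse transport physics at the stated scattering
parameters, shot noise at the experiment's count levels, and the ground-truth
sidecar that makes every estimation error exactly computable. It does not
reproduce: vendor-specific intensifier gain noise (an MCP-voltage LUT not
derivable from the published description — the Poisson+read model is a
stated stand-in), glass capillary walls (tubes are dye cylinders in bulk),
projector optics (patterns are launched collimated at normal incidence),
per-tissue refractive-index boundaries inside the volume (a single interior
index is used; inclusions are index-matched), sample curvature, or
autofluorescence. A green test therefore establishes correctness of the
algorithms against this stated world, not instrument-level realism.

Monte Carlo budgets in tests and the acceptance script are reduced relative
to the GPU-scale originals (10^5–10^6 photons, minutes on one CPU); standard
errors are attached where they matter and reduced-budget criteria are checked
with those errors in mind.

# Numerical choices

* Times in ps internally; lifetimes in ns at interfaces. Speed of light
  0.299792 mm/ps.
* Counts stored as doubles (demodulated components and MC outputs are
  real-valued).
* Heterogeneous transport uses exact DDA voxel marching; a homogeneous-bulk
  fast path takes analytic steps outside the bounding box of non-bulk
  voxels (identical distributions, ~2× faster).
* Weighted sampling of emission events uses inverse-CDF binary search.
* The native container is a single self-describing binary file
  (length-prefixed JSON header + little-endian float64 payload) with a plain
  CSV interchange format; both round-trip bit-exactly. (The environment this
  package targets has no HDF5/TIFF R bindings.)
* Run configs are JSON; every artifact embeds seed, config hash and package
  version.
* RNG: R's generator throughout (including inside the C++ kernels via
  `unif_rand`), so `set.seed()` makes every stage bit-reproducible.

# What surface removal achieves at desk scale

A caution worth stating plainly. Even an emitter in the top 0.1–0.2 mm of a
$\mu_s' = 1$ mm$^{-1}$ medium retains only ~10–15% modulation at
0.6 mm$^{-1}$: the collimated, fully modulated excitation is diluted by the
(unmodulated) diffuse fluence buildup near the surface — consistent with
this package's own shallow MTF values. Subtracting $I_{AC}$ therefore
removes a *surface-weighted slice* of the signal, not the surface signal
wholesale; on the two-layer phantom the test suite demonstrates the
mechanism (the demodulated AC decay carries the surface lifetime, 0.43 ns
fitted against the 0.5 ns surface truth, versus 0.70 ns for the planar
mixture) rather than a large shift of the $I_{sub}$ mean toward the deep
lifetime, which at desk-scale photon budgets is masked by the magnitude
estimator's floor. The lifetime-accuracy claims are exercised where the
source experiments made them: on the capillary-ladder phantom, where the
subsurface decays recover the scattering-free control lifetime to a few
percent (acceptance criteria).

# Known limitations

* The magnitude MTF estimator saturates at the noise floor
  $\approx 1.15\,\sigma$; use the synchronous estimator (or more photons)
  below MTF $\sim 3\sigma$.
* Per-pixel lifetime fits at desk-scale photon budgets carry MC noise well
  above camera shot noise; tube-mean lifetimes are accurate to a few percent
  but per-pixel dispersions are budget-limited and larger than the
  experiment's.
* Single excitation and emission channel; emission-wavelength properties
  default to the excitation table (separately settable).
* No phase-error self-calibration; patterns are assumed exactly
  $2\pi/3$-stepped (the DMD is digital).
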