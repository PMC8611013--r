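---
title: "Simulating a three-bin photon-counting CT system: models, parameters, and design choices"
author: "pcctsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a three-bin photon-counting CT system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

`pcctsim` is a desk-scale, single-slice simulator of a prototype
photon-counting-detector (PCD) CT system together with the analysis chain
that such a system enables: per-energy-bin image reconstruction, K-edge
threshold calibration, per-pixel neural-network material decomposition,
and image-quality scoring (Hounsfield units, contrast-to-noise ratio,
bar-pattern modulation).

The modeled scanner is a curved, equiangular fan-beam system:

* source-to-isocenter distance 227.5 mm; field of view 250 mm;
* a CdTe detector assembly of 48 modules, 80 rows x 2304 columns of
  native 0.230 mm x 0.190 mm pixels (each module served by a 3840-channel
  ASIC);
* three comparator thresholds per pixel forming energy bins
  30--50, 50--65 and 65--140 keV, with counter depths of 14, 13 and 12
  bits (saturation at $2^{b}-1$ counts);
* 1440 projections per rotation at 140 kVp;
* two readout modes: *standard* (5 x 6 detector binning, sixteen
  0.640 mm slices) and *HR* (native 1 x 1 pixels, 0.128 mm effective
  z pixel at the isocenter).

The source-to-detector distance is not part of the printed system
description; the package fixes it at 337.7 mm, the unique value consistent
with a 0.190 mm z pitch binned by five rows mapping to a 0.640 mm slice at
the isocenter ($\mathrm{SDD} = \mathrm{SID}\times 0.95/0.640$). It is a
configuration field and can be overridden.

# Physics chain

## Attenuation and spectra

Material physics lives in compact built-in tables of mass attenuation
$\mu/\rho$ (cm$^2$/g) sampled on a sparse energy grid and interpolated
log--log. Tables are split into segments at K-edge energies so that
interpolation never bridges a discontinuity; a query exactly on an edge
takes the right (above-edge) limit. The gadolinium (50.2 keV) and tungsten
(69.5 keV) K-edges are treated as normative landmarks because the threshold
calibration depends on them; all other coefficients follow standard
published cross-section shapes (photoelectric power-law decay with a
Compton floor) and are phantom parameters rather than claims.

The tube spectrum is an analytic Kramers shape, $\Phi(E)\propto
E\,(\mathrm{kVp}-E)$, hardened by Beer--Lambert transmission through a
configurable filter stack (default 2.5 mm aluminium equivalent — the
machine's inherent filtration is not printed anywhere, so this is a
configuration value). The exposure scale is set so that roughly
$9\times10^4$ photons per native detector column per mAs survive the
default filtration, a representative figure for a low-power portable
scanner at this geometry. Exposure defaults to 14 mAs per rotation
(7 mA x 2 s, the top of the system's operating range).

## Acquisition

For each view and native detector column the projector computes exact
(finely sampled, bilinear) line integrals of every material's
volume-fraction map. Expected bin counts then follow the polychromatic
Beer--Lambert model

$$N_b = \sum_E w_b(E)\,\Phi(E)\,
  \exp\Big(-\sum_m \mu_m(E)\, \ell_m\Big),$$

where $w_b(E)$ is the probability that a photon of true energy $E$ is
recorded inside bin $b$ after Gaussian energy blur (default
$\sigma = 4$ keV, a simple stand-in for the CdTe spectral response; pulse
pile-up, charge sharing and K-escape are deliberately out of scope).
Because neighbouring bins share thresholds, the three bins tile the full
30--140 keV window exactly: summed bin counts equal a single wide-bin
acquisition to numerical precision, which the test suite asserts at
$10^{-9}$ relative tolerance.

Counts are Poisson-sampled per (view, column, bin) and clipped at the
counter saturation; rows binned into a slice are handled as a fluence
multiplier with a correspondingly scaled clip. Column binning sums counts
after sampling, conserving photons exactly. The energy-integrating
(EID) comparison mode records $\sum_E E\,N(E)$ with Gaussian
quantum-plus-electronic noise, $\mathrm{Var}=\sum_E E^2 N(E)+\sigma_e^2$.

## Reconstruction

Log-normalization uses a 0.5-count floor so fully attenuated rays stay
finite. Reconstruction is the standard equiangular fan-beam filtered
back-projection: cosine weighting by $D\cos\gamma$, ramp filtering with
the equiangular kernel (optionally Hann-apodized), and
distance-weighted backprojection with linear detector interpolation. HU
calibration is empirical: a noiseless scan of a 100 mm-radius water
cylinder is reconstructed per channel and the central ROI mean defines
$\mu_{\mathrm{water}}$ for that channel, so water closes to 0 HU per bin by
construction. No beam-hardening correction is applied (a stated non-goal),
so wide channels show a few percent of cupping in large water paths; the
narrow bins 2 and 3 recover their spectrum-weighted effective $\mu$ within
2%, which is what the reconstruction test asserts.

The default reconstruction grid is 625 x 625 at the full profile. Because
a full-geometry run is expensive on a laptop, the package ships three
profiles — `full` (1440 views, 2304 columns, 625 px), `reduced`
(720 views, 768 columns at 3x pitch, 313 px) and `coarse` (360 views,
384 columns, 157 px). Phantoms are always rendered at twice the
reconstruction grid so that the forward and inverse models never share a
discretisation. The demonstration pipelines and the shipped analysis runs
use `reduced`; `coarse` drives the fast physics tests.

## Threshold calibration

Comparator thresholds are device (DAC) units related to keV by an unknown
gain and offset. Calibration sweeps one open threshold behind a gadolinium
foil (0.25 mm) and a tungsten foil (0.30 mm; thicker so that its
transmission step has comparable amplitude against the spectral
background). The negative derivative of counts with respect to threshold
is the blurred transmitted spectrum; its second difference peaks at the
K-edge. The peak is refined parabolically and then corrected to first
order for the smooth spectral background (a Gaussian of width $\sigma$ on
a local slope $b_1$ is displaced by $b_1\sigma^2/a$, estimated from the
window shoulders). Two landmark energies then fix gain and offset by a
two-point linear solve. On noiseless sweeps this recovers an identity
pixel within 0.02 keV/DAC and 0.5 keV and locates both edges within
0.5 keV.

# Material decomposition

## Network and training

The decomposition is deliberately per-pixel: a multilayer perceptron with
input width equal to the number of bins (3), eight hidden ReLU layers, and
one linear output per material. Hidden width defaults to 64 and is run at
16 in the shipped desk-scale pipelines; at three input features the
narrower network loses nothing measurable while training several times
faster. Features are per-bin HU values standardized by training-set mean
and SD (stored in the model).

Training minimises full-batch mean squared error for exactly 4500 epochs
at learning rate 0.00005. Two optimisation details matter and both are
documented deviations from the plainest possible choice:

* **Optimizer.** Plain gradient descent at this learning rate and epoch
  count leaves the loss at roughly a third of its starting value; Adam at
  the same printed learning rate and epochs converges to well below 10%
  of the initial loss (and to ~0.1% on noiseless training sets). Adam is
  therefore the default; plain GD remains available
  (`training_config(optimizer = "gd")`).
* **Initialization.** Glorot (Xavier) scaled-uniform initialization is
  used rather than He initialization. With eight deep, narrow ReLU layers
  He-scale weights produce strongly init-dependent extrapolation outside
  the training hull — material maps of tissue mixtures swing wildly
  between seeds — whereas the smaller Glorot weights bias the network
  toward near-linear solutions that extrapolate stably. This is also the
  default of the mainstream deep-learning frameworks this architecture
  would normally be written in.

Targets are one-hot per material for tissues; for solutes (iodine,
calcium) the hot entry is scaled to the normalised concentration
$c/c_{\max}$, so the iodine channel behaves as a concentration map and is
monotone in true concentration by construction of the training signal.
ROIs whose material is not among the output channels (for example plain
water when the channel list is iodine/calcium/white/gray) train the
background with an all-zero target.

## Training data

Training samples are 25 x 25-pixel square ROIs centered in regions of
known composition: seven ROIs on the multi-energy insert phantom (three
iodine concentrations, three calcium concentrations, water) and, for the
brain task, two tissue ROIs (white and gray matter), for
$(25\times25\times9)\times3 = 16{,}875$ scalar training units per
extraction.

One scan's ROI pixels are not 625 independent draws: FBP noise is
spatially correlated, so a single noisy realisation pins the
material-basis directions poorly and occasionally produces a network that
attributes a tissue-plus-iodine mixture to the calcium channel. The
pipelines therefore pool the ROI features of three replicate acquisitions
of the training phantom (the simulation analogue of measuring each ROI
thrice) and thin the pooled set back to one scan's worth of samples, so
the training cost is unchanged while the effective information triples.
The liver pipeline additionally includes the subject's back-muscle ROI as
a zero-iodine tissue anchor, mirroring a mixed phantom-plus-subject
training set; without it the network's response to soft tissue is an
unconstrained extrapolation.

Training on *noisy* reconstructions at the acquisition dose acts as data
augmentation and is essential: networks trained on noiseless or very
high-dose features fit sharp cliffs between the training clusters and
generalise poorly to intermediate mixtures.

# Phantoms: what they emulate and what they do not

All inputs are generated by code; there is no external data.

* **Insert phantom** — a 100 mm-radius water cylinder with 16 mm-radius
  solution inserts on a ring: iodine at 2/5/10 mg/mL, calcium at
  50/100/300 mg/mL, and water. Solute concentrations map to volume
  fractions through the solute density with linear partial-volume mixing.
* **Brain phantom** — elliptical cortical-bone skull shell (6 mm), a
  gray-matter ribbon around a white-matter core, optional iodinated
  vessels, a posterior muscle pad and an air reference. White and gray
  matter are water-based tissues at densities 1.025 and 1.040 (CT numbers
  near +25 and +40 HU); gray matter additionally carries a 1%
  calcium-shaped admixture so the two tissues are separable across three
  bins. These offsets are phantom parameters chosen so that per-pixel
  classification is reliable at the default dose (a contrast-detail
  choice, like a resolution phantom's); they deliberately exaggerate the
  real white/gray spectral difference, and passing the segmentation test
  therefore demonstrates the pipeline's mechanics, not clinical
  gray--white separability.
* **Liver phantom** — a soft-tissue body ellipse with liver, a tumor
  whose 3 mm rim is iodine-enhanced (3 mg/mL) around an unenhanced core,
  an iodinated aorta (8 mg/mL), and back muscles. Parenchymal enhancement
  defaults to 0.3 mg/mL, reflecting a hepatic arterial phase in which
  portally supplied parenchyma has taken up little contrast while a
  hypervascular rim and the aorta enhance strongly; the near-isodense
  appearance of the whole tumor in the total-energy image, against its
  high conspicuity in the iodine map, is exactly the clinical situation
  an iodine map is for. ROIs (tumor, liver, aorta, muscle, noise) are
  fixed circles placed strictly inside their regions so replicate runs
  are comparable; the noise ROI sits in uniform liver background.
* **Bar phantom** — alternating bone/air bars (default 0.5 mm, the scale
  of fine trabecular anatomy such as nasal turbinates) in a soft-tissue
  disc on a small 64 mm field of view, scored by the modulation statistic
  `(bar mean - gap mean) / (ideal bar - ideal gap)`.

Features of real data the generator does not emulate: scatter, bowtie
filtration, detector cross-talk and spectral distortion beyond the
Gaussian blur, anatomical texture and motion, 3-D cone-beam effects
(rows exist only for binning and slice bookkeeping). Consequently,
passing tests demonstrates correctness of the simulation-and-analysis
chain under its stated model, not performance on a physical scanner.

# Numerical choices

* Ray sampling step: half the phantom render pixel, bilinear
  interpolation; path lengths are exact for this sampling in the sense of
  the trapezoid-free midpoint rule.
* Zero-count guard $\varepsilon = 0.5$ counts in the log transform.
* Ramp filtering via FFT with the exact equiangular spatial kernel;
  Hann apodization multiplies the kernel's frequency response. The brain
  pipeline reconstructs with Hann (a smooth head kernel) to suppress
  skull-edge ringing; all other pipelines use the plain ramp.
* Backprojection interpolates linearly along the detector and weights by
  $1/L^2$; the 2$\pi$ view parameterisation covers each ray path twice in
  opposite directions, which the equiangular weighting accounts for
  without an extra factor.
* Per-stage random seeds derive from a single master seed by fixed
  affine offsets modulo $2^{31}-19$; every stochastic operation takes an
  explicit seed and replays bitwise.
* Training-ROI square side adapts to the reconstruction grid (25 px at
  the system scale of 313 px and above, 11 px on the coarse test grid) so
  ROIs stay inside their inserts.

# Problem sizes used in the shipped analyses

The demonstration pipelines and the acceptance analysis run the `reduced`
profile (720 views, 768 native columns, 313 px reconstruction, hidden
width 16), which reproduces the full-profile behaviour of every quantity
the package reports while keeping a complete liver-pipeline replicate
under a few minutes on one CPU core. The geometry and training
bookkeeping quantities (effective pixel sizes, channel counts, training
unit counts, counter saturation) are computed from the full-system
configuration, which is exact at any profile.

# Known limitations

* No beam-hardening or scatter correction: wide-channel HU of large or
  dense objects are biased by design; quantitative claims are restricted
  to water-calibrated channels and to contrasts.
* The decomposition is per-pixel; it uses no spatial context, so its
  noise behaviour is governed entirely by the per-pixel spectral
  conditioning of the three bins.
* The EID mode is a first-moment model with Gaussian noise, intended for
  HU-agreement comparisons, not for detailed EID noise modelling.
* Counter saturation is modeled as a hard clip per readout; real
  pile-up-related distortions near saturation are out of scope.
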