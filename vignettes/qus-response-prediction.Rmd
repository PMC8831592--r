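---
title: "Quantitative ultrasound parametric imaging and deep-learning response prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound parametric imaging and deep-learning response prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qusdl)
```

# Overview

`qusdl` implements a complete desk-scale pipeline from raw radiofrequency
(RF) ultrasound echoes to a patient-level prediction of breast-tumor
response to neoadjuvant chemotherapy:

1. **Synthetic RF generation** with known scattering ground truth, so
   every downstream stage can be verified quantitatively without clinical
   data (which is private in this application domain).
2. **QUS spectral estimation** per analysis window: mean power spectra of
   Hanning-gated scan lines, reference-phantom normalization, linear band
   regression (mid-band fit MBF, spectral slope SS, 0-MHz intercept SI),
   and spherical Gaussian form-factor inversion for the effective
   scatterer diameter (ESD) and effective acoustic concentration (EAC).
3. **Parametric mapping**: a sliding-window analysis over the manually
   outlined tumor core and an automatically dilated 5 mm margin band
   produces co-registered 4-channel images (MBF, SI, ESD, EAC).
4. **Two-stage prediction**: a convolutional feature network (residual or
   residual-attention backbone) is trained on single planes, its frozen
   256-dimensional features are averaged over each tumor's 4--7 planes,
   and a fully connected network predicts responder vs non-responder.
5. **Evaluation and explanation**: classification metrics in the
   non-responder-positive convention, ROC/AUC, Kaplan-Meier and log-rank
   survival comparison, and occlusion-based prediction difference (PDA)
   maps.

# The acoustic model

## Pulse and acquisition geometry

The simulated transducer transmits near 6 MHz with a −6 dB band of
3--8 MHz; RF lines are sampled at 40 MHz, so the axial pitch is
c/(2·f~s~) ≈ 0.019 mm at c = 1540 m/s. The pulse amplitude spectrum is a
two-sided Gaussian whose widths are set separately left and right of the
peak so that the −6 dB points fall exactly on the band edges even though
the band is asymmetric around the center frequency; a smooth DC-kill
factor (negligible above 2 MHz) enforces |P(0)| = 0.

## Backscatter and attenuation

Tissue scattering follows the spherical Gaussian form-factor model

$$\mathrm{BSC}(f) = C_0\,\mathrm{EAC_{lin}}\,a^6 k^4
  e^{-0.827\,k^2 a^2},\qquad k = 2\pi f/c,\; a = \mathrm{ESD}/2,$$

with C~0~ = 1 in internal units, so EAC (= 10 log10 EAC~lin~) is reported
relative to a fixed internal reference; all recovery checks are
self-consistent in these units. Round-trip power attenuation in dB is
4·α·f·d with α in dB/MHz/cm, f in MHz and d the one-way depth in cm (the
amplitude-coefficient convention of the reference-phantom literature); the
simulator and the estimator's compensation use this same convention, which
makes the round trip exact in expectation.

## Frequency-domain synthesis

Each scan line is synthesized segment-wise in the frequency domain: white
Gaussian noise is shaped by the square root of the expected power spectrum
|P(f)|²·BSC(f)·10^(−4αfd/10) at the segment-center depth and transformed
back. Segments (128 samples) are combined by overlap-add with a
square-root periodic Hann cross-fade at quarter-segment hop — the squared
fades sum to one (constant overlap-add), so the process is continuous in
depth and analysis gates may straddle segment joins. Within each segment a
deterministic amplitude ramp applies the known depth dependence of
attenuation at the band-center frequency, removing the level steps a
purely piecewise-constant scheme would leave. The price of this design is
a slight spectral smoothing of the target spectrum by the cross-fade
kernel (~0.3 MHz), which the spectral-fidelity test accounts for
explicitly by convolving the analytic expectation with the fade and gate
kernels. This synthesis was chosen over point-scatterer convolution
because it has an exact, testable spectral expectation.

# Spectral estimation choices

* **Gate**: 2 mm Hanning gates per scan line; DFT zero-padded to the next
  power of two ≥ 4× the gate length (512 at 40 MHz).
* **Normalization**: values(f) = 10 log10(S~s~/S~r~) + 4(α~s~−α~r~)·f·d,
  restricted to the 3--8 MHz band, with point compensation at the
  window-center depth. The sample attenuation is not identifiable at desk
  scale and is a configuration value, default 1.0 dB/MHz/cm (a typical
  breast-tissue literature value); the reference phantom is fixed at its
  calibrated 0.576 dB/MHz/cm and 1488 m/s.
* **Band regression**: ordinary least squares of dB values against MHz;
  MBF is evaluated at the band midpoint (5.5 MHz). Whether the original
  acquisition convention evaluated at 5.5 or 6 MHz is not documented;
  the midpoint is the standard Lizzi-Feleppa practice and is configurable.
* **Form-factor inversion**: a grid search over ESD = 1--300 µm in 1 µm
  steps; for each candidate the dB-domain least-squares intercept (the
  EAC) is closed-form, and the candidate with the smallest residual wins.
  The wavenumber uses the sample sound speed (default 1540 m/s), not the
  phantom's 1488 m/s.
* **Known bias**: the finite gate smooths the spectrum (kernel ≈ 0.4 MHz),
  which biases ESD slightly low and EAC slightly high on curved spectra.
  At 2000 lines per window the median errors are ~4--6% (ESD) and
  ~0.9 dB (EAC); at the ~5--10 lines of a 2 mm map window the spread and
  bias are larger, which is why map-level checks use medians over the ROI
  and a looser EAC band.

# Parametric maps and network inputs

Windows slide with 95% overlap in the clinical configuration (step
0.1 mm); each window's parameters are written to its center pixel, so the
map pixel pitch equals the step and the pixel counts per axis equal
floor((L−w)/step)+1 (181 across 20 mm). A window contributes whenever its
center lies in the core or margin; windows may overhang the ROI edge. The
margin is the set of outside pixels within 5 mm Euclidean distance of the
core, clipped to the frame.

Network inputs are built by zeroing outside the selected mask (core, or
core plus margin), cropping to the mask bounding box (so tumors of
different sizes fill the canvas), bilinear resampling to 512×512, min-max
normalizing per channel with parameters computed on the training set only,
and clipping to [0, 1]. Background pixels are re-zeroed after
normalization: the dB-valued channels can be negative, and a literal
(x−min)/(max−min) would lift the background to a nonzero constant,
breaking the zero-background convention that occlusion analysis relies
on. Normalization parameters carry a provenance tag and the preprocessing
refuses parameters not derived from a training set.

# Networks and training

The feature network is a residual (`resnet`) or residual-attention
(`ran`) backbone over 4-channel inputs. The residual module is
y = F(x)+x with a 1×1 projection when channels change; the attention
module is the attention-residual form y = (1+M(x))⊙T(x) with a
sigmoid-terminated encoder-decoder mask branch, so M ∈ (0,1) and trunk
information is never suppressed entirely. After the final stage, global
average pooling and a linear projection produce the fixed 256-d feature
vector; the plane-level training head is 256→100→2 with dropout, matching
the patient-level predictive network's shape.

Two presets exist. `small` — one residual/attention stage per resolution,
8 base channels — is the configuration exercised by the tests and the
desk-scale experiments. `full` — 3/4/23/3 residual stages, or three
attention stages of 1/2/3 modules plus a residual tail — reproduces the
deep topologies at reduced width; it builds and runs forward but is not
trained in the test-suite (single-CPU scale). Inputs larger than 32 px
are average-pooled by the stem to a 32 px working resolution before the
convolutions; augmentation is applied at this working resolution, so
shifts are quantized to stem-pool multiples of the input pitch.

Training uses Adam at learning rate 1e-4, batch size 8, dropout 0.5 and a
5:1 cost weight on the non-responder class (the optimized clinical
hyperparameters), with stochastic horizontal flips and shifts up to 30%
of the image size, and early stopping on validation loss (default
patience 10 epochs; validation loss is the monitored quantity since the
original criterion is not documented beyond "performance"). The seed
governs weight initialization, batch order and augmentation; single-
platform reruns are bit-reproducible. The patient-level predictor is
trained on averaged, frozen features with the same loss; because its
steps are orders of magnitude cheaper, the pipeline gives it a larger
epoch budget (400, patience 40) at the same learning rate. There is no
joint fine-tuning of the two stages.

# The synthetic cohort

The generator emulates the structure of the clinical acquisition: 4--7
planes per patient at distinct cross-sections (per-plane ±10% jitter of
the ellipse axes), an elliptical core contour per plane, a 5 mm margin
shell, the 76.2% / 23.8% responder / non-responder imbalance (exact
largest-remainder counts), and 10-year recurrence-free survival with
exponential event times (responders 0.004/month, non-responders
0.02/month — a hazard ratio matching a clearly separated survival plot)
censored uniformly on [0, 120] months.

Tissue microstructure statistics for breast tumors are not documented, so
the class contrast is a free synthetic choice, fixed once: responder
cores ESD 60 µm / EAC 25 dB (margins 45/22), non-responder cores
110 µm / 35 dB (margins 80/30), background 30 µm / 20 dB, α = 1.0
dB/MHz/cm everywhere. These are tissue-scale scatterer magnitudes with a
strong contrast; passing end-to-end tests therefore demonstrates that the
pipeline recovers and exploits class-linked microstructure, **not** that
clinical tumors are this separable. Real RF data additionally contain
coherent/structured scattering, depth-dependent beam effects,
attenuation heterogeneity and contouring error, none of which the
generator emulates.

# Desk-scale problem sizes

The standard experiment (`syntheticExperiment()`) uses 60 patients,
~26×23 mm planes at 0.4 mm line pitch, 8--12 mm tumors, 50%
sliding-window overlap, the small `ran` backbone and a 12-epoch feature
budget; one run takes a few minutes on one CPU. The spectral-recovery
experiment uses single 2 mm gates averaged over 2000 lines, 20 replicate
seeds. The clinical-scale configuration (6×4 cm frames, 95% overlap,
512×512 inputs, full presets) is expressible with the same API but is not
what the tests run.

```{r example}
r <- syntheticExperiment(seed = 1, includeNull = TRUE)
r$auc       # held-out patient-level AUC
r$nullAuc   # label-permutation control, ~0.5
```

# Numerical and design notes

* Window-position counts use floor with a 1e-9 tolerance so exact
  multiples of the step are not lost to floating-point error.
* The form-factor grid search returns the first minimizing grid point;
  the dB-domain residual is convex enough in practice that ties are not
  observed away from the grid ends.
* `estimateQus()` and the vectorized in-map estimator are asserted equal
  in the tests, so map pixels and the exported single-window chain cannot
  drift apart.
* Log-rank and Kaplan-Meier computations are delegated to the `survival`
  package; the test-suite checks them against hand-rolled product-limit
  and permutation/calibration oracles. AUC is delegated to `pROC` and
  checked against the midrank rank-sum formula.
* Splits use per-class largest-remainder allocation. An exact test-set
  size can be forced (`nTest`) since a "about 30%" clinical split is not
  reproducible from a fraction alone.
* Cohorts are stored in memory and serialized as RDS by the command-line
  wrapper; contours and spectra export as plain CSV/TSV.

# Limitations

* EAC is reported relative to an internal reference (C~0~ = 1), not in
  absolute scatterers/cm³; only differences and recoveries are
  meaningful.
* Attenuation is compensated with a single point term per window and the
  sample attenuation is assumed known; no attenuation estimation is
  performed.
* The occlusion (PDA) scan re-extracts features once per patch, channel
  and plane; at the full 512×512 resolution this is minutes of compute
  per plane — explanation maps at desk scale should use smaller inputs.
* The deep "full" presets are structural reproductions at reduced width;
  nothing here speaks to their GPU-scale training behavior.
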