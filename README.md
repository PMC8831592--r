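# qusdl

Quantitative ultrasound (QUS) parametric imaging and deep learning for
predicting breast-tumor response to neoadjuvant chemotherapy — as a fully
testable, desk-scale R pipeline.

## The problem

Locally advanced breast cancer is treated with neoadjuvant chemotherapy
before surgery, but whether a tumor will respond is only confirmed months
later from post-surgical histopathology. QUS spectroscopy characterizes
tissue microstructure from the frequency content of raw radiofrequency
(RF) echoes, independently of instrument settings, and pre-treatment QUS
parametric maps of the tumor and its margin carry information about
eventual response. This package implements the full chain from RF data to
a patient-level response prediction:

* **Spectral parameters per analysis window.** The mean power spectrum of
  Hanning-gated scan lines is normalized by a reference phantom with known
  acoustics (attenuation 0.576 dB/MHz·cm, sound speed 1488 m/s) to cancel
  the system transfer function:
  `values(f) = 10·log10(S_s/S_r) + 4(α_s−α_r)·f·d` on the 3–8 MHz band.
  A linear regression gives the spectral slope SS, 0-MHz intercept SI and
  mid-band fit MBF; fitting the spherical Gaussian form-factor model
  `BSC(f) = C₀·EAC·a⁶k⁴·exp(−0.827k²a²)` (k = 2πf/c, a = ESD/2) yields
  the effective scatterer diameter ESD and acoustic concentration EAC.
* **Parametric maps.** A 2 mm sliding window (95% overlap clinically,
  i.e. 0.1 mm isotropic pixels) scans the manually contoured tumor core
  plus an automatically dilated 5 mm margin, producing co-registered
  4-channel images (MBF, SI, ESD, EAC).
* **Two-stage predictor.** A residual or residual-attention convolutional
  backbone — attention modules compute `y = (1+M(x))⊙T(x)` with a
  sigmoid mask branch — is trained on single planes (plane label =
  patient response, class-weighted cross-entropy 5:1, Adam 1e-4, batch 8,
  dropout 0.5, flip/shift augmentation, early stopping). Its frozen 256-d
  features are averaged over each tumor's 4–7 planes and a 256→100→2
  softmax network predicts responder vs non-responder.
* **Evaluation and explanation.** Metrics use the non-responder-positive
  convention (sensitivity = correctly identified non-responders), plus
  ROC/AUC, Kaplan–Meier + log-rank survival comparison, and occlusion
  (prediction difference) maps locating the image regions that drive a
  prediction.

Because clinical RF archives are private, the package ships a synthetic
RF generator with exact spectral expectations and known ground truth
(class-dependent microstructure, multi-plane patients, class-dependent
censored survival), so every stage is verified quantitatively.

## Worked example

Recover scattering parameters from one simulated analysis window:

```r
library(qusdl)
g   <- FrameGeometry(nLines = 2000, nSamples = 360, lateralPitch = 0.05,
                     depthOffset = 10)
fr  <- simulateRFFrame(ScatteringSpec(esd = 80, eacDb = 30, attenuation = 1),
                       g, seed = 1)
ref <- simulateReferenceFrame(g, seed = 5001)          # phantom: 0.576 dB/MHz.cm
sW  <- meanPowerSpectrum(rfSamples(fr)[100:203, ], 40) # one 2 mm gate
rW  <- meanPowerSpectrum(rfSamples(ref)[100:203, ], 40)
estimateQus(sW, rW, depthCm = 1.29, config = qusConfig())
#> QusEstimate: MBF -63.46 dB, SS 2.28 dB/MHz, SI -75.99 dB, ESD 78.0 um, EAC 30.62 dB
```

The true ESD is 80 µm and the true EAC 30 dB: the window recovers them to
a few percent and well under 1 dB, the documented accuracy of 2 mm gates
at this averaging depth (EAC is relative to an internal reference,
C₀ = 1).

Run the full desk-scale pipeline — simulate a 60-patient cohort, map it,
train both networks, and evaluate on the held-out test patients:

```r
r <- syntheticExperiment(seed = 1, includeNull = TRUE)
c(auc = r$auc, accuracy = r$accuracy, nullAuc = r$nullAuc)
#>      auc accuracy  nullAuc
#>      1.0      1.0      0.5
```

Held-out AUC and accuracy are 1.0 under the generator's strong class
contrast; the label-permutation control sits at chance (≈0.5), confirming
the signal comes from the class-linked microstructure and not from
leakage. Occlusion maps for a patient's plane come from
`pdaMaps(featureNet, predictor, planes, targetPlane)`.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/qusdl simulate --n-patients 20 --seed 1 --out cohort.rds
Rscript inst/scripts/qusdl run --cohort cohort.rds --arch ran --out predictions.csv
```

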