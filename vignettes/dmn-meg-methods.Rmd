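---
title: "Spectral power and envelope connectivity of the DMN in absence epilepsy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral power and envelope connectivity of the DMN in absence epilepsy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnmeg)
```

## The analysis problem

Childhood absence epilepsy (CAE) produces brief generalized seizures whose
electrographic signature is a ~3 Hz spike-and-wave discharge (SWD).
Resting-state MEG makes it possible to ask how oscillatory activity and
functional connectivity of the default mode network (DMN) — bilateral
medial frontal cortex, posterior cingulate, precuneus, lateral and medial
temporal lobes, and inferior parietal lobes, twelve regions in all —
differ between healthy children, the interictal (between-seizure) state,
and the ictal (during-seizure) state.

`dmnmeg` implements that analysis as a tested pipeline over five stages:

1. **Segment selection.** From annotated recordings, cut 5 s ictal
   windows centered in seizures strictly longer than 10 s, 30 s
   interictal windows centered in SWD-free spans with more than 30 s of
   clean signal on each side, and two 30 s control windows per control
   subject. A zero-phase notch (50 Hz and harmonics) removes powerline
   contamination first.
2. **Source estimation (toy scale, optional).** A depth-weighted
   minimum-norm inverse with regularization $\lambda^2 = 0.33$ maps
   sensor data back to sources; ROI time courses are unweighted means of
   member sources. When the input is already ROI-level — the synthetic
   default — this stage is bypassed.
3. **Spectra.** Welch PSD (5 s Hann windows, 50% overlap), normalized to
   relative PSD, $\mathrm{rel}(f) = \mathrm{PSD}(f) / \sum_i
   \mathrm{PSD}(f_i)$, then aggregated into six bands: delta 2–4, theta
   5–7, alpha 8–12, beta 15–29, gamma1 30–59, gamma2 60–90 Hz.
4. **Connectivity.** Corrected amplitude envelope correlation (AEC-c)
   per band: band-pass, remove the zero-lag (leakage) component of each
   signal of a pair from the other by time-domain regression, correlate
   Hilbert envelopes in both directions, and average. Node strength is
   the sum of a region's 11 pairwise values; relative node strength
   divides by the band's total.
5. **Statistics.** Kruskal–Wallis omnibus and pairwise contrasts
   (ictal vs. interictal, interictal vs. control) per ROI × band ×
   measure, Benjamini–Hochberg FDR within each (measure, contrast)
   family, and median-difference maps.

## Why AEC-c

Instantaneous field spread mixes every source into every sensor — and,
after any linear inverse, into every reconstructed ROI. Such leakage is
zero-lag by construction, so a plain envelope correlation between two ROI
signals is inflated by shared signal that carries no physiological
coupling. Regressing one band-limited signal out of the other removes
exactly that zero-lag component; amplitude coupling carried on
phase-shifted carriers survives. We orthogonalize in the time domain on
the band-passed signals, compute envelopes afterwards (the correction is
applied to signals, not envelopes), and symmetrize by averaging the two
directions, which makes `aecc_pair(x, y)` exactly equal to
`aecc_pair(y, x)`.

Numerical choices worth knowing:

* **Trimming.** Filter and Hilbert transients are excluded by dropping
  1 s from each end before correlating (configurable).
* **Sign.** The raw signed correlation is kept by default; a `rectify`
  switch takes absolute values. Signed is the least-processed choice and
  keeps the null distribution centered at zero.
* **Degenerate pairs.** If orthogonalization leaves a near-constant
  envelope (e.g. `y` was an exact multiple of `x`), that direction
  contributes 0 rather than an undefined correlation.
* **Static windows.** One matrix per segment (5–30 s); no sliding
  windows.

## The synthetic cohort

No public recordings accompany this problem, so the package ships a
seeded generator whose defaults *are* the study conditions: 33 patients
and 26 controls, five consecutive 2 min epochs per subject, and — as a
desk-scale choice made for runtime, not fidelity — a 300 Hz sampling
rate, which keeps comfortable Nyquist headroom above the highest
analysed band edge (90 Hz).

Each ROI signal is 1/f-coloured noise (exponent 1, unit variance) plus
one amplitude-modulated carrier per band (carriers at 3, 6, 10, 22, 45,
75 Hz). Envelope modulators are rectified low-pass (< 1 Hz) Gaussian
noise with unit mean; coupled pairs replace a fraction $c$ of their own
modulator with a shared one, and their carriers sit $\pi/2$ apart so
zero-lag orthogonalization does not destroy the planted coupling.
Regime structure:

* **Control:** posterior ROIs (PCC, PCu, IPL) get a 2.5× alpha gain,
  reproducing the parieto-occipital resting alpha peak.
* **Interictal:** delta carrier raised (1.1 vs. 0.6) and beta–gamma2
  lowered relative to controls — the interictal spectral signature the
  statistics stage should detect.
* **Ictal:** interictal background plus scheduled SWD bursts. Within a
  burst the background is attenuated to 0.1 and a harmonic-rich 3 Hz
  spike-wave waveform (1/k harmonic decay plus one Gaussian-derivative
  transient per cycle, amplitude 6) dominates, so mid-seizure windows
  are delta-dominated and lose the alpha peak. Two seizures of 11–15 s
  are placed per patient recording such that the span before the first
  seizure and the tail span each exceed 90 s while the inter-seizure gap
  stays below 90 s — so every patient yields ictal and interictal
  segments by construction, and a 26-subject control cohort yields
  exactly 52 control datasets.

What the generator does **not** emulate: realistic head geometry or
sensor physics (the forward model is an explicit toy matrix), eye/muscle
artifacts, non-stationary alpha reactivity, inter-subject anatomical
variability, or hyperventilation provocation. Passing tests therefore
demonstrate that the algorithms recover planted structure under the
stated noise model — not that the clinical effect sizes of real cohorts
would reproduce.

The default ROI coordinate table is a *synthetic placeholder* (plausible
MNI centroids); it exists to give the ROI set concrete geometry and can
be overridden with a study-specific TSV.

## Design decisions in ambiguous corners

* **Strict thresholds.** "Longer than 10 s" and "> 30 s" are read
  strictly; a 10.000 s seizure yields no ictal window.
* **Clean-span rule.** A single condition — SWD-free span ≥ 90 s with
  the 30 s window centered — implies both guard intervals. Recording
  edges count as valid guards (no SWD can live outside the file), and at
  most one interictal window is taken per clean span.
* **Control windows** are tiled earliest-first and non-overlapping.
* **Relative-PSD range.** "Total power across the spectrum" is taken as
  1–90 Hz: 90 Hz is the highest analysed edge; 1 Hz excludes DC/drift
  bins. Configurable.
* **Band edges** are inclusive on both sides; bins in the printed
  inter-band gaps (4–5, 7–8, 12–15, 29–30, 59–60 Hz) belong to no band.
* **Alpha-peak detection** requires a local maximum in 8–12 Hz that both
  exceeds twice the 5–15 Hz neighbourhood median *and* is the maximum
  over that neighbourhood. The dominance condition matters: a 3 Hz
  spike-wave discharge has a harmonic line at 9 Hz, which is locally
  prominent but does not dominate its neighbourhood — without the
  condition, ictal spectra would be scored as having an alpha peak.
* **Regularization bookkeeping.** $\lambda^2$ is stored directly with
  default 0.33. Note that 0.33 equals $1/\mathrm{SNR}$ at the customary
  assumed SNR of 3, not the $1/\mathrm{SNR}^2$ convention; we follow the
  printed value. Depth exponent defaults to 0.8, the common choice.
* **Kruskal–Wallis everywhere.** Pairwise contrasts reuse the two-group
  Kruskal–Wallis (equivalent to a Wilcoxon rank-sum up to the chi-square
  approximation) so omnibus and follow-up tests share one machinery.
  FDR families are (measure, contrast) across the 72 ROI × band cells.
* **Observations are per dataset** (segment), mirroring how recordings
  are counted in this design; `per_subject = TRUE` averages within
  subject first for a conservative alternative.
* **Degenerate Welch case.** A 5 s ictal segment equals one 5 s window;
  the single periodogram is accepted rather than shrinking the window
  (and with it the frequency resolution).

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run the pipeline at sizes
chosen to keep a full run on one CPU to a few minutes: determinism is
demonstrated on a 2-patient / 2-control cohort with 6 min recordings
(bit-identity is independent of cohort size); null calibration uses
identically generated 8-vs-8 recording sets of 60 s over the full 72
ROI × band grid; the control-count check uses the full 26-subject
control cohort at the default 10 min per subject. The full 59-subject
default pipeline (66 ictal, 66 interictal and 52 control segments)
completes in about seven minutes on one CPU.

## Known limitations

* The null spread of AEC-c on 60 s segments is wide (sd ≈ 0.07) because
  sub-1 Hz envelopes provide few effective samples per minute;
  single-pair null estimates can exceed 0.1 in magnitude even though
  their mean is near zero. Longer segments shrink this in the usual
  $1/\sqrt{T}$ fashion.
* The toy inverse is linear algebra on explicit matrices; it validates
  the estimator's contracts, not head-model physics.
* Orthogonalization removes genuinely zero-lag physiological coupling
  along with leakage — an inherent property of the corrected-AEC family,
  inherited deliberately.
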