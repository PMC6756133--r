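---
title: "Measuring neural envelope tracking: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neural envelope tracking: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envtrack)
```

## The problem

When a listener hears continuous speech, low-frequency cortical activity
follows the slow amplitude modulations — the *envelope* — of the speech
signal. The strength of this neural envelope tracking can be read out from
EEG and rises with the signal-to-noise ratio (SNR) of speech in stationary
noise, which makes it a candidate objective marker of speech understanding:
instead of asking a listener to repeat sentences, one correlates the
stimulus envelope with its reconstruction from the EEG and reads a
"neural" speech reception threshold (SRT) off the tracking-versus-SNR
curve. Because a listener's attention waxes and wanes, and because clinical
protocols may prefer to occupy the listener with an undemanding task such
as watching a silent movie, the pipeline also has to quantify how the
*task* changes tracking — in level, and in the shape and topography of the
underlying response.

`envtrack` implements this measurement chain end to end: envelope
extraction from audio, EEG cleaning, backward decoding and forward
temporal response function (TRF) estimation, psychometric fitting, and the
statistical battery (paired sign-flip permutation tests, dependent
correlation comparison, variance-homogeneity testing, and cluster-based
permutation testing over channels × lags). Because raw recordings of this
kind cannot be shared, the package ships a synthetic-study generator with
known ground truth against which every stage is validated.

## Envelope extraction

The stimulus envelope is computed with an auditory-inspired front end: a
gammatone filterbank of 4th-order all-pole filters whose center
frequencies are spaced by 1 equivalent rectangular bandwidth (ERB) from
50 to 5000 Hz — exactly 28 channels under the Glasberg–Moore ERB-rate
function \(E(f) = 21.4\,\log_{10}(0.00437 f + 1)\) — followed by
sample-wise power-law compression \(|x|^{0.6}\) per subband and an
unweighted average across subbands:

```{r erb}
erb_space(50, 5000, 1)
```

Choices worth noting:

* The gammatone realization is the Slaney-style cascade of four biquads,
  applied **causally** (forward only). A zero-phase variant would shift
  subband energy backwards in time and blur the causal relation that the
  forward model later estimates.
* Compression is applied to the raw rectified subband signal, not to a
  Hilbert envelope; at the modulation rates of interest (< 10 Hz) the two
  differ negligibly after band-pass filtering, and the rectified form is
  the cheaper and more common convention for this analysis.
* The exponent 0.6 approximates loudness growth; it is a parameter of
  `extract_envelope()`.

## EEG cleaning

Four stages, in order:

1. **Amplitude blanking** (`blank_and_interpolate()`): any sample whose
   absolute amplitude exceeds 500 µV (a level essentially never produced
   by the brain) is replaced by linear interpolation between the nearest
   surviving samples of that channel; runs touching a recording edge hold
   the nearest surviving value. Only supra-threshold samples are touched.
2. **Ocular-artifact suppression** (`mwf_denoise()`): a multichannel
   Wiener filter. Artifact samples are detected on the eight
   fronto-polar channels (Fp1, AF7, AF3, Fpz, Fp2, AF8, AF4, AFz) as
   instantaneous power above 5× that channel's time-averaged power. The
   filter stacks ±3-sample delayed copies of all channels, estimates
   artifact and clean covariance matrices from the flagged and unflagged
   segments, and keeps generalized eigencomponents whose
   artifact-to-clean power ratio exceeds 1 — the estimated artifact is
   subtracted from every channel. A known limitation of any such
   minimum-mean-square-error filter: on channels where the artifact
   dominates the signal (the fronto-polar row during blinks), suppressing
   ~95 % of blink-band power necessarily costs some brain-signal fidelity
   there, and finite-sample covariance estimates cause mild subtraction
   even on channels with no ocular contribution (per-channel fidelity
   ρ ≈ 0.94+ away from the eyes, ≈ 0.8 at the blink focus in the packaged
   ground-truth test).
   When no sample exceeds the detection threshold the recording is
   returned unchanged with a warning, not an error.
3. **Average re-referencing** (`rereference_average()`): subtracting the
   per-sample channel mean; an idempotent projection.
4. **Band-pass filtering and resampling** (`bandpass()`,
   `resample_to()`): a zero-phase Chebyshev type-II band-pass with
   stopband edges 10 % outside the passband. The stated 80 dB attenuation
   is interpreted as the *total* two-pass attenuation: zero-phase
   (forward–backward) filtering squares the magnitude response, so each
   pass is designed for 40 dB. The delta preset is 0.5–4 Hz and theta
   4–8 Hz, bracketing the word (2.5 Hz) and syllable (4.1 Hz) rates of
   the matrix sentences. The filter is designed in zero-pole-gain form
   and run as a cascade of second-order sections — at a 256 Hz rate the
   24th-order band-pass is numerically unusable as a single expanded
   polynomial. The *same* filter code path is applied to EEG and
   envelope, which tests assert to the bit. Resampling is DC-normalized
   Kaiser-windowed polyphase; the processing order is: clean at the
   native rate, filter at 256 Hz, analyse at 128 Hz.

## Backward decoding and the forward TRF

The decoder is a linear map from the multichannel EEG and its time-shifted
copies onto the envelope:
\[
\hat s(t) = \sum_{n=1}^{N}\sum_{\tau} g(n,\tau)\, R(t+\tau, n),
\]
with post-stimulus lags \(\tau\) spanning 0–75 ms (default) or 0–500 ms.
Training solves the ridge normal equations
\(g = (R R^{\mathsf T} + \lambda I)^{-1} R S^{\mathsf T}\) with
\(\lambda = \max |R R^{\mathsf T}|\), after z-scoring each channel and the
envelope; z-scoring makes that λ rule meaningful across scales. Boundary
samples are zero-padded so the sample count is preserved. The decoder is
trained on a continuous attended stimulus and applied to the test trials —
train/test stimulus separation is enforced by the pipeline. Tracking is
summarized per trial as the median Spearman correlation between envelope
and reconstruction over a moving-block bootstrap (5 s blocks, paired
resampling, percentile interval); block resampling preserves the
autocorrelation that ordinary i.i.d. resampling of samples would destroy.

The forward model reverses the roles: each channel is regressed on the
delayed envelope, giving a per-channel kernel — the TRF — whose
deflections are labelled P1/N1/P2 by sign and latency window (defaults
20–70, 60–120, 120–250 ms). `trf_peaks()` refines latencies by quadratic
interpolation around the grid extremum, which removes the ±½-sample
quantization of the 128 Hz lag grid. For the forward model the default
ridge is deliberately *lighter* than the decoder's rule:
\(\lambda = 0.01 \max|X^{\mathsf T}X|\). The decoder rule is tuned for a
4000-column ill-conditioned design; applied to the 65-column forward
design it over-smooths the kernel enough to distort peak morphology
(measured: per-channel kernel correlation drops to ≈ 0.65 on noiseless
data and the P1 peak disappears). Both the rule and the scale are exposed
(`lambda`, `lambda_scale`).

## The synthetic study

`study_config()` fixes the conditions the generator emulates:

* **Stimulus**: two lists of twenty 2 s sentences with uniform 0.8–1.2 s
  gaps — exactly 80 s of speech in ≈ 120 s. Within a sentence the envelope
  is a rectified sum of sinusoidal modulators at 2.5 and 4.1 Hz on a DC
  pedestal (word and syllable rates); gaps are exactly zero.
* **Response kernels**: 64-channel kernels built from Gaussian deflections
  (σ = 12 ms) at +50, −80 and +160 ms. P1/N1 have a fronto-central
  topography; P2 adds a pronounced right-frontal component. The movie
  kernel scales P2 by 0.4, so the attention−movie kernel difference is a
  160 ms right-frontal deflection. The overall amplitude (0.8 µV per
  envelope z-unit against 20 µV of 1/f noise) was set so that
  quiet-condition tracking lands at ρ ≈ 0.25–0.3 with the 0–75 ms delta
  decoder — the magnitude range this kind of study reports.
* **Tracking gain**: per-condition logistic maps from SNR to a gain in
  [0, 1], midpoints −9.15 dB (attention) and −6.96 dB (movie), spread
  2 dB. The differing midpoints reproduce the key interaction: the
  attention advantage is large at low SNR and fades where passive
  listening suffices. A single shared gain map cannot produce this —
  the kernels differ only beyond 120 ms, invisible to a 0–75 ms decoder.
* **Noise and artifacts**: per-channel 1/f Gaussian noise (20 µV RMS);
  blinks as 300 ms raised-cosine pulses, 150 µV, frontally weighted, 12
  per minute; optional ±800 µV single-sample glitches (designed to exceed
  the 500 µV blanking threshold) for a glitch-heavy condition.
* **Sizes**: 10 subjects, 7 SNRs from −12.5 to +2.5 dB, one presentation
  per SNR and condition, 180 s of training stimulus. These are
  desk-scale choices: the logic of every analysis is independent of the
  counts, and tests that need repetition averaging generate 3
  presentations explicitly.

What the generator does **not** emulate: real speech spectra (no actual
sentence audio is synthesized), spatially correlated background EEG,
non-stationary attention within a trial, eye movements other than blinks,
and electrode drift. Passing tests therefore demonstrate that the
pipeline recovers what it injects under the stated model — correct code,
calibrated statistics — not that the effect sizes transfer to any real
recording.

## Statistics

* **Psychometric fits** (`fit_psychometric()`): the logistic
  \(p(x) = \gamma + (1-\gamma-\lambda)/(1+e^{-(x-\alpha)/\beta})\) with
  α the SRT and β the spread in dB. The *reported slope* is the derivative
  at the midpoint, \(100(1-\gamma-\lambda)/(4\beta)\) %/dB — a spread of
  1.773 dB corresponds to 14.1 %/dB. Word scores are fitted by binomial
  maximum likelihood with γ = λ = 0; tracking-versus-SNR curves free the
  guess and lapse rates so the logistic can ride on the floor and ceiling
  of the correlation measure. Multiple starts (L-BFGS-B) guard against
  local optima; non-convergence is flagged via `fit_ok`, never silent.
* **SNR binning** (`bin_snrs()`): seeded 1-D k-means (default 7
  clusters), centers sorted; tests verify the objective against an exact
  dynamic-programming solution.
* **Condition comparison per SNR bin**
  (`paired_permutation_by_snr()`): sign-flip permutation of paired
  differences (mean statistic by default, t optional), exact enumeration
  whenever \(2^{n}\) fits in the permutation budget, Holm–Bonferroni
  across bins.
* **Dependent correlations** (`compare_dependent_correlations()`): the
  two tracking-versus-SNR correlations share the SNR variable, so the
  overlapping-correlations z test is used, with the covariance term
  evaluated at the back-transformed average of the two correlations.
* **Spread** (`brown_forsythe()`): one-way F on absolute deviations from
  group medians.
* **Cluster-based permutation** (`cluster_permutation()`): paired t maps
  over channels × lags, cluster-forming threshold at two-sided α = 0.05,
  clusters connected through the BioSemi-64 template adjacency (4 cm
  neighbour threshold on an idealized spherical 10-10 layout, built in
  code — it is a template, not a digitised cap) and lag contiguity,
  cluster mass = summed t, familywise p from the sign-flip null of the
  maximal mass. Positive and negative clusters are formed separately.
  Under pure noise the familywise error sits in [0.02, 0.08] at nominal
  0.05 (checked over 1000 runs on a reduced grid).

## Numerical and degenerate-input conventions

* Ridge solves use the Cholesky path on the regularized normal equations;
  a zero ridge on a rank-deficient design is refused rather than silently
  pseudo-inverted.
* Constant channels z-score to zero instead of NaN.
* Blanking with a channel entirely above threshold errors (nothing to
  interpolate from); an artifact-free recording passes the Wiener filter
  unchanged with a warning.
* All stochastic steps (generator, bootstrap, permutations, k-means) are
  seeded and reproducible; permutation tests switch to exact enumeration
  when feasible, which also makes them invariant to subject ordering.
* Bootstrap intervals are percentile intervals; with exchangeable data the
  interval is symmetric around the median up to Monte-Carlo error.

## Known limitations

* The envelope front end has no per-channel level adaptation or dynamic
  compression; it is a fixed power law.
* The Wiener filter's frontal-channel trade-off discussed above.
* The neural-SRT fit pools subject × SNR points; a hierarchical model
  would propagate subject-level uncertainty but is out of scope.
* The cluster test controls familywise error for the *presence* of an
  effect; cluster extents are descriptive, not confidence regions — the
  reported 140–190 ms window should be read accordingly.
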