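# envtrack

Neural envelope tracking of continuous speech from EEG.

When a listener hears running speech, low-frequency cortical activity
follows the speech amplitude envelope. `envtrack` measures that tracking
and turns it into an objective correlate of speech understanding:

* **Envelope extraction** — 28-channel ERB-spaced gammatone filterbank
  (50–5000 Hz, Glasberg–Moore ERB rate), per-subband power-law
  compression `|x|^0.6`, averaged to a single envelope.
* **EEG cleaning** — 500 µV amplitude blanking with linear interpolation,
  multichannel Wiener filtering of ocular artifacts (frontal power
  detection at 5× average, GEVD rank selection), common-average
  re-referencing, zero-phase Chebyshev type-II band-pass (delta 0.5–4 Hz /
  theta 4–8 Hz, 80 dB two-pass stopband attenuation 10% outside the band),
  polyphase resampling (256 → 128 Hz analysis rate).
* **Linear models** — backward ridge decoder
  `g = (R Rᵀ + λI)⁻¹ R Sᵀ` with `λ = max|R Rᵀ|` over post-stimulus lags
  (0–75 or 0–500 ms), reconstructing the envelope as
  `ŝ(t) = Σₙ Στ g(n,τ) R(t+τ,n)`; forward temporal response functions
  (TRFs) per channel with P1/N1/P2 peak extraction; moving-block
  bootstrapped Spearman tracking scores.
* **Statistics** — logistic psychometric fits
  `p = γ + (1−γ−λ)/(1+e^(−(SNR−α)/β))` (α = SRT in dB SNR, reported slope
  `100(1−γ−λ)/(4β)` %/dB), seeded 1-D k-means SNR binning,
  overlapping dependent-correlation z test, per-SNR paired sign-flip
  permutation tests with Holm–Bonferroni, Brown–Forsythe spread test, and
  cluster-based permutation testing over channels × lags with a BioSemi-64
  template adjacency.
* **Synthetic studies** — a generator with known ground truth
  (matrix-sentence timelines, condition-specific P1/N1/P2 kernels with an
  attenuated right-frontal P2 in the distracted condition, SNR-dependent
  tracking gain, 1/f noise, blinks, glitches), so the whole chain is
  testable without access to raw recordings.

The audience is auditory-neuroscience and audiology researchers analysing
speech-tracking EEG experiments, and methodologists who need a tested,
seeded reference implementation of this analysis family.

## Worked example

Simulate the default two-condition study (10 subjects, 7 SNRs from −12.5
to +2.5 dB, ~120 s trials) and run the full analysis — about seven
minutes on one core:

```r
library(envtrack)

report <- run_study(study_config(n_subjects = 10, seed = 11),
                    analysis_config(seed = 12))
report
```

```
study report: 10 subjects, config e6953979
SNR-tracking Spearman correlations:
attention     movie 
    0.842     0.833 
per-bin paired permutation tests (Holm adjusted):
 snr_bin center  mean_diff       p_raw p_adjusted
       1  -12.5 0.01224933 0.365634366 0.36563437
       2  -10.0 0.08392547 0.001998002 0.01398601
       3   -7.5 0.09984097 0.002997003 0.01398601
       4   -5.0 0.09833757 0.001998002 0.01398601
       5   -2.5 0.08521593 0.001998002 0.01398601
       6    0.0 0.10802763 0.001998002 0.01398601
       7    2.5 0.07446474 0.001998002 0.01398601
neural SRT [attention]: -9.23 dB SNR
neural SRT [movie]: -7.28 dB SNR
cluster permutation: 61 cluster(s), |t| > 2.26, 1000 permutations
          channels lag_low_ms lag_high_ms      mass n_cells sign           p
 F4,FC4,FC2,FCz,Fz   101.5625    226.5625 309.56873      83    1 0.008991009
               AF7   109.3750    195.3125 -42.27310      12   -1 0.363636364
           FC1,FC3   343.7500    398.4375  36.88130      13    1 0.510489510
 ...
```

Read: tracking rises with SNR in both conditions (Spearman 0.84/0.83);
the attention advantage (`mean_diff` = attention − movie tracking ρ) is
significant at every bin except the lowest, where both conditions track
weakly; the neural SRTs — midpoints of logistic fits to tracking vs SNR
with free guess/lapse rates — land at −9.23 and −7.28 dB against
generator gain midpoints of −9.15 and −6.96 dB; and the only significant
TRF cluster (p = 0.009) covers right-frontal/fronto-central channels
around 100–230 ms, recovering the injected late P2 difference.

Single stages are available directly, e.g.

```r
spec <- erb_space(50, 5000, 1)        # 28 ERB-spaced centers
env  <- extract_envelope(audio, fs, spec)
eeg  <- bandpass(rereference_average(eeg), "delta")
dec  <- train_backward(eeg_train, env_train, lag_spec(0, 75, 128))
bootstrap_spearman(env_test, reconstruct(dec, eeg_test))
```

A thin command-line front end lives at `inst/cli/envtrack.R`
(`simulate`, `envelope`, `run`).

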