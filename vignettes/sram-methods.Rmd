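---
title: "Modulation-based intelligibility metrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulation-based intelligibility metrics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sram)
```

## The problem

At a fixed signal-to-noise ratio, *clear* speech — the deliberately
articulated style a talker adopts for a hard-of-hearing listener — is more
intelligible than conversational speech. Classic SNR-driven predictors
cannot see this difference, because the long-term spectra of the two styles
are nearly identical. What differs is the *temporal envelope*: clear speech
is slower (fewer syllables per second) and more deeply modulated at low
modulation frequencies.

The SRAM (syllable-rate-adjusted modulation) index exploits exactly this.
It measures the power of the envelope modulation spectrum **at and above
the syllable rate**, discarding the below-rate components that carry
prosody rather than phonetic information. Its unadjusted sibling, TMP
(total modulation power), integrates from 1 Hz regardless of rate, and
serves as the ablation baseline: the difference between the two isolates
the contribution of the syllable-rate adjustment.

## The metric pipeline

For a mono waveform $s(n)$ (any rate above 12 kHz; speech corpora are
typically 16 kHz):

1. **Silence trimming.** Non-overlapping 10 ms frames; frames more than
   40 dB below the loudest frame are silence; the signal is cut from the
   first to the last active frame. Both parameters are configurable
   (`trim_silence()`); the defaults are ordinary practice for recorded
   sentences with room tone at the edges.
2. **Octave filterbank.** Six octave-wide Butterworth bandpass filters
   (overall order 6) centred at 125–4000 Hz with edges $f_c/\sqrt2$,
   $f_c\sqrt2$, plus a sixth-order 6 kHz high-pass. Filtering is causal;
   the metric uses envelope *power*, which is indifferent to group delay.
3. **Intensity envelopes.** $e_i(n) = |s_i(n) + \mathrm{j}H\{s_i(n)\}|$
   via the FFT analytic-signal construction.
4. **Modulation spectrum.** Bartlett's method: the envelope is cut into
   non-overlapping 1 s windows (so the resolution is exactly 1 Hz), the
   one-sided periodogram of each window is averaged, and the result is
   normalized by the window duration times the mean squared envelope:
   $$m_i(f) = \frac{P_i(f)}{\frac{D}{N}\sum_n e_i(n)^2}.$$
   The normalization cancels absolute amplitude: the metric of $\alpha x$
   equals the metric of $x$ for any $\alpha > 0$.
5. **Summation.**
   $$\mathrm{TMP} = \sum_{k=1}^{25}\tfrac17\sum_{i=1}^{7} m_i(k), \qquad
     \mathrm{SRAM} = \sum_{k=\lfloor SR\rfloor}^{25}\tfrac17\sum_{i=1}^{7} m_i(k),$$
   with the SRAM lower bound clamped to 1 when $\lfloor SR\rfloor < 1$
   (so SRAM $=$ TMP for rates below 2/s) and an empty sum (value 0) when
   $\lfloor SR\rfloor > 25$.

The metric is **non-intrusive**: in noisy conditions it is computed on the
noisy signal alone, with no clean reference.

### Numerical choices

* **Periodogram convention.** The literature leaves the periodogram
  normalization open. We use the one-sided PSD convention,
  $P(f) = |X(f)|^2/(f_s L)$ with non-DC bins doubled, which makes
  $m_i(f)$ dimensionless and independent of the envelope sample rate. Any
  fixed convention rescales TMP and SRAM jointly and cancels in the
  four-parameter transformation; the test suite pins ours against an
  independently coded DFT oracle to $10^{-10}$ relative error.
* **Envelope decimation.** Envelopes are decimated to 200 Hz (zero-phase
  order-6 Butterworth anti-alias at 90 Hz, with reflection padding to
  suppress edge transients) before the Bartlett step. All content up to
  100 Hz — four times the 25 Hz ceiling — survives; the tests verify
  agreement with a full-rate computation within 1% on band-limited
  envelopes. A 1 s window is then 200 samples instead of 16 000.
* **Window remainders.** A trailing partial window is discarded whenever
  at least one full window exists; an envelope shorter than 1 s is
  zero-padded to one window (the metric is defined for signals as short
  as 1 s). The normalization denominator uses the whole (padded)
  envelope, reading the formula literally.
* **Degenerate inputs.** An all-zero envelope would make the
  normalization 0/0; the spectrum is defined as identically zero there,
  so silent bands contribute nothing rather than NaNs.

## Syllable rate

SRAM needs the syllable rate. Two routes:

**Reference (transcript available).** Each word is mapped to ARPAbet
phonemes and every stress-carrying vowel phoneme counts as one syllable;
the rate is the count over the trimmed duration. The package bundles a
small hand-curated lexicon (~180 everyday words of the kind used in
audiometric sentence lists); `load_lexicon()` accepts a full CMU-style
dictionary file for broad coverage. The first listed pronunciation is
used (deterministic); out-of-vocabulary words fall back, with a warning,
to counting orthographic vowel groups.

**Blind estimation (clean audio only).** The same filterbank and
envelopes, down-sampled to 100 Hz and low-passed at 25 Hz (2nd-order
Butterworth); the $M = 4$ highest-energy band envelopes enter a
Hann-windowed ($K = 11$) temporal correlation
$$y_j(n) = \tfrac1K\Big|\sum_{k=1}^{K} w_k\, e_j'(n)\, e_j'(n+l)\Big|,
  \quad l = k - \lfloor K/2\rfloor - 1,$$
with out-of-range samples taken as zero; the pairwise products of the
$y_j$ average into a sub-band correlation $z(n)$, which is min–max
normalized; local maxima with topographic prominence above $p = 0.07$
count as syllables. The estimator is defined for clean speech;
`evaluate_manifest()` refuses to run it on noisy conditions.

Decisions worth recording:

* The absolute value in the temporal correlation sits outside the
  windowed sum, exactly as the formula is printed (for non-negative
  envelopes the two readings coincide anyway).
* "Prominence" is implemented as standard topographic prominence on the
  normalized trace; no minimum inter-peak distance is imposed.
* Band energy for the $M$-of-7 selection is the summed squared envelope
  after the 25 Hz low-pass; ties break deterministically by band order.
* A degenerate trace (silent input, $\max z = \min z$) yields rate 0
  with a warning rather than an error.

Estimation quality is scored by the range-normalized RMSE
(`sr_error()`), the same functional form used for intelligibility
prediction error.

## Intelligibility evaluation

* **Psychometric fit** (`fit_srt()`): two-parameter logistic
  $f(\mathrm{SNR}) = 1/(1+e^{-k(\mathrm{SNR}-\mathrm{SRT})})$ by
  least squares with analytic gradients; the SRT is where the curve
  crosses 0.5. Initialization is the interpolated 0.5 crossing plus a
  logit-regression slope, with a fixed fallback grid of slope starts;
  bounded L-BFGS-B; fully deterministic. Quiet conditions have no SNR and
  are excluded. Data entirely on one side of 0.5 are fitted but flagged
  `ill_conditioned` with a warning, since the SRT is then extrapolated.
* **Clear-speech benefit** (`clear_benefit()`):
  $\delta_{SRT} = SRT_{clear} - SRT_{conv}$; negative favours clear
  speech.
* **Transformation** (`fit_transform()`): the four-parameter logistic
  $f(x) = d - (d-a)/(1+(x/c)^b)$ mapping a metric to a score, fitted by
  bounded least squares from five fixed starting points (no randomness),
  scored by the range-normalized RMSE $\sigma$ (stored as a fraction,
  printed as percent). Constant scores return a flagged degenerate flat
  fit with $\sigma = 0$.
* **Manifest evaluation** (`evaluate_manifest()`): per-sentence metrics
  on each condition's own audio, averaged per condition; the
  transformation fitted over all conditions (quiet included as a
  condition); SRT curves per (speaker, style) fitted to both human scores
  and transformed predictions over the noisy conditions only; $\delta_{SRT}$
  per speaker from both. Quiet enters the transformation but not the SRT
  fit — the only self-consistent reading when conditions are "$n$ noise
  levels + quiet".

## What the synthetic generator emulates — and what it does not

`make_syllabic_signal()` builds a carrier gated by a raised-cosine burst
train: bursts at period $1/\mathrm{rate}$, width
$\min(0.5/\mathrm{rate},\,0.25)$ s. The 50% duty cycle mimics the
vowel-energy rhythm of running speech; the 250 ms cap reflects that vowel
nuclei do not stretch proportionally at very slow speaking rates — a
1 syllable/s talker pauses more, rather than producing half-second vowels.
Two carriers are available: spectrally tilted Gaussian noise (default
tilt −6 dB/octave, a speech-like roll-off) and a deterministic multitone
(one random-phase tone per octave band), the latter resembling voiced
excitation. An optional slow gain "wander" (≤1 Hz low-passed noise,
default off) emulates prosodic level drift below the syllable rate.

The style-contrast fixture used in the tests and the acceptance script
pairs a *clear-like* family (2 bursts/s, full modulation depth) against a
*conversational-like* family (4.5 bursts/s, depth 0.65) on identical
carriers, both with wander 0.3, mixed into speech-shaped noise at
−15…+5 dB SNR. The depth difference encodes the documented deeper
low-frequency modulation of clear speech; the wander supplies the
below-syllable-rate power that the SRAM gate strips more aggressively
from the fast family ($\lfloor 4.5\rfloor = 4$ removes bins 1–3) than
from the slow one ($\lfloor 2\rfloor = 2$ removes bin 1).

These fixtures have exact ground truth and reproduce the qualitative
clear-speech phenomenon, which is what passing tests demonstrate. They do
**not** contain formant transitions, consonant bursts, pitch, coarticulation
or pauses; quantitative agreement with results on recorded speech is not
implied, and the recorded-corpus adapter (`zenodo_manifest()`) exists
precisely so users can rerun the same machinery on real recordings they
have downloaded themselves.

`make_ssn()` shapes Gaussian noise to a reference's Welch long-term
average spectrum (4096-point windows, smoothed over 1/3 octave —
configurable); `mix_at_snr()` scales noise for an exact broadband RMS
ratio over the speech extent, the common convention in speech-in-noise
work. All generators are pure functions of their
arguments and seed, and restore the caller's RNG state.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
material at deliberately small scale: 2 s signals for the estimator sweep
(8 rates × 5 seeds), 1.5 s signals for the 20-signal identity grid, a
16-condition corpus (2 speakers × 2 styles × 3 SNRs + quiet) for the
manifest round trip, and 56 random envelopes for the spectrum oracle.
These sizes were chosen as the smallest that exercise every branch
(partial Bartlett windows, quiet conditions, both carriers) while keeping
the whole suite near half a minute.

## Known limitations

* The bundled lexicon is small; real transcripts need a full CMU-style
  dictionary file, and the orthographic fallback is crude for
  morphologically complex words.
* "Sixth-order octave-wide Butterworth" is read as overall order 6
  (prototype order 3 as bandpass), the standard octave-band usage; if the
  original filters were prototype order 6, absolute band levels would
  differ slightly, though the normalization limits the effect on the
  metrics.
* The blind rate estimator degrades on noisy audio by design and is
  guarded accordingly; it also reports pseudo-syllables on stationary
  noise, whose envelopes genuinely fluctuate — this is a property of
  envelope-based rate estimation, not a bug.
* WAV support covers mono PCM 16/24-bit and IEEE float; multi-channel
  files are rejected rather than downmixed.
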