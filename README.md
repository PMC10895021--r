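# sram

Objective speech-intelligibility metrics from envelope modulation power,
for speech and hearing scientists who need to predict how intelligible a
recording will be — in particular for **clear speech**, the slow, deeply
modulated speaking style whose intelligibility advantage over
conversational speech defeats classic SNR-based predictors.

## What it computes

The core index is **SRAM** (syllable-rate-adjusted modulation). A mono
waveform is trimmed of edge silence, split by a 7-band octave Butterworth
filterbank (125 Hz – 4 kHz centres plus a 6 kHz high-pass), and each
band's Hilbert intensity envelope

$$e_i(n) = \sqrt{s_i(n)^2 + H\{s_i(n)\}^2}$$

is turned into a normalized modulation power spectrum by Bartlett's
method with 1 s windows (1 Hz resolution):

$$m_i(f) = P_i(f) \Big/ \tfrac{D}{N}\textstyle\sum_n e_i(n)^2 .$$

Band-averaged spectra are summed over modulation frequencies:

$$\mathrm{TMP} = \sum_{k=1}^{25}\tfrac17\sum_{i=1}^{7} m_i(k),
\qquad
\mathrm{SRAM} = \sum_{k=\lfloor SR\rfloor}^{25}\tfrac17\sum_{i=1}^{7} m_i(k),$$

where $SR$ is the syllable rate in syllables/s. Discarding modulation
power *below* the syllable rate is the whole trick: it removes prosodic
energy that does not carry intelligibility, and it removes more of it
from fast (conversational) speech than from slow (clear) speech.

Around the core the package provides:

* syllable rate from a transcript (ARPAbet vowel counting) or blind from
  clean audio (sub-band envelope correlation + peak prominence);
* psychometric fitting — two-parameter logistic speech reception
  thresholds (SRT), the clear-speech benefit
  $\delta_{SRT} = SRT_{clear} - SRT_{conv}$, the four-parameter
  metric-to-intelligibility transformation and its normalized RMS error
  $\sigma$;
* manifest-level evaluation (CSV of conditions → per-condition metrics,
  transformation fit, SRT table, $\delta_{SRT}$);
* deterministic synthetic fixtures: syllabic burst-train signals with
  exact ground truth, speech-spectrum-shaped noise, exact-SNR mixing;
* mono WAV I/O (PCM 16/24-bit, IEEE float) and a command-line front end
  (`system.file("cli", "sram.R", package = "sram")`).

## Worked example

```r
library(sram)

# a clear-like (2 syll/s, deep modulation) and a conversational-like
# (4.5 syll/s, shallower) signal on the same carrier, in noise at -8 dB
clear <- make_syllabic_signal(rate = 2,   duration = 2, mod_depth = 1,
                              seed = 7, wander_depth = 0.3)
conv  <- make_syllabic_signal(rate = 4.5, duration = 2, mod_depth = 0.65,
                              seed = 7, wander_depth = 0.3)
noise <- make_ssn(clear, duration = 2, seed = 107)

compute_metric(mix_at_snr(clear, noise, -8), syllable_rate = 2,   trim = FALSE)
#> SRAM = 0.0414633  (syllable rate 2 /s)
compute_metric(mix_at_snr(conv,  noise, -8), syllable_rate = 4.5, trim = FALSE)
#> SRAM = 0.0300756  (syllable rate 4.5 /s)
```

The clear-like signal scores ~38% higher SRAM at the same SNR — the
clear-speech advantage the metric is built to expose. TMP, which keeps
the below-rate bins, separates the two far less (0.0427 vs 0.0345).

```r
estimate_syllable_rate(clear)
#> <syllable rate: 2.5 /s (5 syllables / 2 s, estimated)>
reference_syllable_rate("The orange was very sweet", 3.5)
#> <syllable rate: 2 /s (7 syllables / 3.5 s, reference)>

snr <- c(-15, -10, -8, -5, 0, 5)
fit_srt(snr, logistic2(snr, k = 0.5, srt = -9.1))
#> SRT fit: k = 0.5 /dB, SRT = -9.1 dB (RMSE 4.83e-12)
clear_benefit(-9.1, -5.2)
#> [1] -3.9
```

An SRT of −9.1 dB means 50% of keywords are understood at −9.1 dB SNR;
a benefit of −3.9 dB means clear speech tolerates 3.9 dB more noise than
conversational speech for the same intelligibility.

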