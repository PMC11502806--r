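# segwin

Synthetic-data pipeline for locating the **temporal segmentation window of
speech perception** — the shortest per-syllable duration at which auditory
cortex still resolves successive syllables of continuous speech as discrete
events — from auditory evoked magnetic fields (AEFs).

The package is aimed at auditory/MEG researchers who want a fully
controlled, ground-truth-known replica of the classic design: a synthetic
four-syllable word (VCVCVCV; V, CV, CV, CV) is time-stretched to eight
speech rates (75–600 ms total duration) at constant average level; each
syllable's consonant/vowel spectral transition, located by a cepstral
dynamic measure D(t) = Σᵢ Cᵢ(t)², serves as its timing reference; simulated
bilateral superior-temporal dipole sources produce M50/M100 responses per
syllable; and the analysis chain counts significant M100 components,
localizes their sources, and correlates component counts with perceived
syllable counts and stimulus duration. Because the 375- and 300-ms words
have mean syllable lengths of exactly 93.75 and 75.00 ms, a perception/
M100 boundary between those conditions brackets the segmentation window at
**75–94 ms**.

At its core are:

* a formant synthesizer and WSOLA time stretch (`synthesize_base_word()`,
  `time_stretch()`, `generate_stimulus_set()`);
* the cepstral dynamic measure in both its printed (ΣCᵢ²) and
  delta-regression variants, with peak-picked transition references
  (`cepstral_analysis()`, `dynamic_measure()`, `find_transitions()`);
* the analytic spherical-conductor (Sarvas) forward model with a 204-channel
  planar-gradiometer helmet (`dipole_field()`, `gradiometer_response()`,
  `default_sensor_array()`);
* a seeded epoch generator with M50/M100 biphasic sources, latency/amplitude
  jitter, white + 1/f sensor noise, >3000 fT/cm artifact epochs, and a
  recorded ground truth (`simulate_epochs()`, `simulate_behavior()`);
* the analysis chain in its canonical order — rejection, averaging,
  zero-phase 1–75 Hz band-pass + 60 Hz notch, DC baseline — then M100
  counting under the strict 4-SD significance rule and iterative
  least-squares dipole fitting over 40-ms windows (`preprocess_epochs()`,
  `detect_counts()`, `fit_dipole()`);
* the statistical layer: Spearman rho with a t-approximation test, the
  asymptotic Wilcoxon signed-rank test, and two-group discriminant analysis
  via Wilks' Λ = det(W)/det(W+B) on dipole position + orientation
  (`spearman()`, `wilcoxon_signed_rank()`, `discriminant_wilks()`,
  `analysis_report()`), orchestrated by `run_experiment()`.

## Worked example

Simulate one 600-ms session at the default study conditions and count the
evoked M100 components:

```r
library(segwin)

array  <- default_sensor_array()                 # 204 planar gradiometers
stim   <- generate_stimulus_set()[["600"]]       # 600-ms /atataka/
epochs <- simulate_epochs(stim, array, default_sim_config(), seed = 7)
evoked <- preprocess_epochs(epochs)
print(evoked)
#> <evoked> 204 channels x 1001 samples, 108 epochs averaged
#>   - reject: 12 epochs removed
#>   - average: 108 epochs
#>   - filter: band-pass 1-75 Hz + 60 Hz notch (Q=10), zero phase
#>   - baseline: DC over -100..0 ms removed

det <- detect_counts(evoked, array, epochs$ground_truth$onsets_ms)
det$left$components[, c("index", "peak_latency_ms", "peak_amplitude_ft_cm",
                        "delta_amplitude", "baseline_sd")]
#>   index peak_latency_ms peak_amplitude_ft_cm delta_amplitude baseline_sd
#> 1     1             100               -90.95          128.30        2.59
#> 2     2             253               -31.13           50.10        2.59
#> 3     3             401               -34.70           53.49        2.59
#> 4     4             548               -37.26           58.56        2.59
```

All four syllables evoke a significant M100 (peak-to-M50 difference and peak
amplitude both beyond 4 × the 2.59 fT/cm baseline SD), at latencies locked
to each syllable's CV transition + ~100 ms. Repeating this across durations
reproduces the study's central pattern: only the word-onset M100 survives at
75–225 ms, all four appear from 375 ms upward — the boundary sits between
300 and 375 ms, i.e. between 75.00- and 93.75-ms syllables.

The numbered drivers under `analysis/` run the stages as a narrative —
`01_stimuli.R` through `06_experiment_stats.R` (the last one is the full
15-participant experiment, ~15 min) — writing tables under `results/`.

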