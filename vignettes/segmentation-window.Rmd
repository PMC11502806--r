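---
title: "Simulating the temporal segmentation window of speech perception"
author: "segwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the temporal segmentation window of speech perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(segwin)
```

## The scientific question

When people listen to continuous speech they hear discrete chunks —
syllables. Somewhere in auditory cortex there is a shortest chunk duration,
a *temporal segmentation window*, below which successive syllables can no
longer be resolved as separate perceptual (and neural) events. One way to
locate it is to synthesize a single multi-syllable word, time-compress it to
a range of speech rates at constant average level, and watch two things as a
function of word duration: how many sounds listeners report hearing, and how
many discrete M100 responses (the prominent auditory cortical deflection
~100 ms after an acoustic onset) the magnetoencephalogram shows. If both
collapse from four (one per syllable) toward one at the same speech rate,
the per-syllable duration at that rate brackets the window.

`segwin` implements this entire study design in silico: a formant-synthesized
four-syllable test word, WSOLA time stretching, a cepstral spectral-transition
detector for the syllable timing references, an analytic MEG forward model,
a synthetic epoch generator with known ground truth, and the analysis chain —
epoch rejection, averaging, filtering, baseline correction, M50/M100
detection with a 4-SD significance rule, equivalent-current-dipole fitting,
and the rank-based statistics linking perception, duration, and M100 count.
With a four-syllable word whose 375- and 300-ms versions have mean syllable
lengths of 93.75 and 75.00 ms, a perception boundary between those two
conditions brackets the segmentation window at roughly 75–94 ms.

## The stimulus

The test word is a VCVCVCV sequence (seven phonemes, four syllables:
V, CV, CV, CV), modeled on /atataka/. `synthesize_base_word()` builds it
from first principles:

* voiced /a/ segments are a glottal impulse train (f0 = 120 Hz) shaped by
  three cascaded formant resonators (800/1200/2600 Hz — an /a/-like
  envelope);
* the plosives /t/ and /k/ are a closure followed by a 10-ms band-passed
  noise burst (2.5–4.5 kHz for /t/, 1–2.5 kHz for /k/); the closure occupies
  40 % of the syllable period;
* the four syllable onsets — the consonant-release-to-vowel spectral
  transitions that serve as the perceptual timing references — fall at exact
  quarters of the word, so a word of duration *d* has mean inter-onset
  spacing *d*/4 by construction. This is what makes the segmentation-window
  arithmetic exact: 600 ms → 150 ms syllables, 375 ms → 93.75 ms,
  300 ms → 75.00 ms.

Two synthesis details serve the downstream transition detector rather than
voice quality. First, closures are not silent: they carry a low-level
(0.15) "voice bar" continuation of the vowel. Because the cepstral
coefficients C₁..C_N exclude the gain term C₀, a pure amplitude fade is
invisible to them, so filling closures with the vowel's own spectral
envelope confines detectable spectral change to the consonant releases —
exactly where the timing reference should sit. Second, the vowel fades into
the closure over 10 ms, avoiding a spurious vowel-offset transient.

`time_stretch()` changes duration while preserving the short-time spectral
envelope, using waveform-similarity overlap-add (WSOLA): output frames are
copied from input positions advanced at the reciprocal rate, each refined
within ±4.5 ms to maximize waveform continuity. We first implemented a phase
vocoder and rejected it: its transient smearing corrupted the burst timing
that the transition detector depends on. WSOLA keeps local waveform shape
(hence formants, verified to ±5 %) and has bounded event-time jitter of
about half an overlap-add frame (7.5 ms). Metadata (phoneme boundaries,
syllable onsets) are scaled exactly by the stretch factor, so the spacing
arithmetic is exact regardless of the audio engine.

`generate_stimulus_set()` synthesizes the slowest (600 ms) word and
stretches *downward* to 75, 150, …, 525 ms, then normalizes every stimulus
to a common RMS ("constant average sound pressure"). The duration grid is
uniform multiples of 75 ms; it is configurable.

## The dynamic measure and transition detection

`cepstral_analysis()` computes the real cepstrum (inverse DFT of the log
magnitude spectrum) of 25-ms Hamming frames at a 5-ms hop, keeping N = 12
coefficients. `dynamic_measure()` offers two variants:

* `"as_printed"`: D(t) = Σᵢ Cᵢ(t)² — a static envelope-magnitude quantity;
* `"delta"` (default for detection): D(t) = Σᵢ Δᵢ(t)², where Δᵢ is the
  least-squares slope of Cᵢ over a centered 5-frame window — the classical
  spectral-transition measure, which peaks where the spectral envelope
  changes fastest.

Both are provided because the printed formula is the static sum while the
quantity's described role (a *spectral transition* reference) corresponds to
the delta form; the ambiguity is preserved rather than resolved silently.

`find_transitions()` smooths D(t) with a 3-frame moving average and greedily
keeps the n highest local maxima at a minimum separation (30 ms at the base
rate, scaled with the stretch factor). On the 600-ms word the three detected
transitions land within 2.5 ms of the construction's references. On
stretched stimuli the analysis parameters should be scaled with the stretch
factor; accuracy is ±10 ms for stretch factors down to ~0.375 and degrades
beyond, where a whole syllable is shorter than one analysis frame. The
simulation pipeline therefore uses the generator's ground-truth onsets by
default (`use_detected_transitions = FALSE`), isolating MEG analysis
behavior from detector error; flipping the switch closes the loop.

## Forward model

`dipole_field()` implements the closed-form magnetic field of a current
dipole in a spherically symmetric conductor. For MEG this is exact for any
number of concentric conductivity layers — layering never affects the
external field under spherical symmetry — so the conventional "three-layer
spherical head model" reduces to this formula, and radial dipoles are
exactly silent. The default sensor array (`default_sensor_array()`) places
102 sites quasi-uniformly (Fibonacci lattice) on a 0.12-m helmet cap with
two orthogonal planar gradiometers per site (204 channels), each realized
as a two-point difference of the radial field component over a 16.8-mm
baseline, in fT/cm. The two-point difference matches physical pick-up coils
and is accurate to O(baseline²). Coordinates: origin at the sphere center,
x left→right, y posterior→anterior, z inferior→superior.

## The synthetic-data generator

`simulate_epochs()` is first-class, tested code, and its defaults *are* the
study conditions. Each epoch (−100…900 ms at 1000 Hz, 1001 samples) is the
superposition over hemispheres and syllables of

> lead field of the syllable's dipole × biphasic M50/M100 timecourse,

plus noise. The components are Gaussian-windowed deflections (SD 12 ms) of
opposite sign at 50 and 100 ms after the syllable's CV transition, with
M50 = −0.4 × M100 in amplitude. Sources are mirrored tangential dipoles at
|r| = 60 mm (30 mm beneath the temporal sensors) with M100 moment
30 nA·m; syllables 2–4 are scaled by 0.6 ("smaller responses in the same
direction"); the first syllable's dipole sits 5 mm more laterally
(`lateral_offset_mm`), emulating the reported novelty-like lateral shift of
the word-onset source.

**Neural adaptation.** Later-syllable amplitudes additionally pass through a
logistic gate in the inter-onset interval: scale × logistic((ISI − 84 ms)/4 ms).
This models the short-term adaptation of auditory cortex to rapid
stimulation and is what makes the detected M100 count duration-dependent —
overlap alone does not suppress components at this SNR (we measured counts
of ~4 at every duration without the gate). The threshold, 84 ms, is the
midpoint of the 75–93.75 ms window, the same modeling choice as the
behavioral threshold below; both are explicit generator parameters, not
measured values.

**Jitter and noise.** Per epoch, component latencies jitter with SD 5 ms and
amplitudes with SD 15 %. Sensor noise is white (SD 55 fT/cm per sample)
plus low-frequency drift with 1/f power (SD 30 fT/cm), synthesized
spectrally on a 4× decimated grid (the process is band-limited below
125 Hz by construction) and upsampled. These defaults put the single-epoch
best-channel SNR near −10 dB, so a ~100-epoch average sits near +10 dB. A
seeded 10 % of epochs receive a single-channel artifact exceeding the
3000 fT/cm rejection threshold; with 120 epochs per condition, at least ~100
artifact-free epochs survive. Everything is reproducible bit-for-bit from
one seed, and the generating truth (dipoles, jitters, artifact epochs, the
noiseless projection) is recorded in `ground_truth`.

**Behavior.** `simulate_behavior()` models a listener resolving each of the
4 syllables independently with probability
logistic((duration/4 − 84 ms)/4 ms), reporting max(1, Binomial(4, p)) sounds.
The expectation crosses 3.5 between the 300- and 375-ms conditions — the
perception boundary the design brackets.

What the generator does *not* emulate: source extent and realistic cortical
geometry, heterogeneous per-channel noise, eye/cardiac artifacts with
spatial structure, inter-participant anatomical variability, and any
oscillatory (theta/gamma) dynamics. Passing tests therefore demonstrate that
the analysis chain recovers what this generative model encodes — counts,
latencies, source separations — not that it would behave identically on
recorded data.

## Preprocessing

`preprocess_epochs()` applies the fixed order: reject epochs exceeding
3000 fT/cm → average survivors (warning below 100) → zero-phase filter the
average → subtract the −100…0 ms DC baseline. The filter is a 4th-order
Butterworth band-pass (1.0–75 Hz) applied forward-backward plus a biquad
notch at 60 Hz, also zero-phase; zero phase is essential because detection
reads peak latencies. Numerical choices: the channel mean is removed before
filtering (the band-pass has zero DC gain; removing the mean makes that
exact on finite epochs), channels are reflect-padded 500 samples against
edge transients, and the notch Q is 10 — narrow enough to leave 10 Hz
untouched (±1 dB passband contract), wide enough that its ringing decays
within the epoch (a Q of 30 leaves a finite-length 60-Hz epoch at ~15 %
amplitude, violating the ≥20 dB attenuation contract the pipeline tests).

## Detection and the 4-SD rule

Per hemisphere, `select_channel()` picks the channel with the largest
peak-to-peak amplitude at 50–150 ms (ties to the lowest index).
`find_m100_1()` takes the largest-|amplitude| extremum in 60–160 ms as
M100₁ and records its polarity. Expected latencies for M100₂..₄ are the
syllable CV-transition times plus the M100₁ latency, searched within
±20 ms. Three definitional choices matter and are deliberate:

* a later component must be a *genuine local extremum* of M100₁'s polarity
  inside its window — a merged ridge without its own peak, or a window-edge
  maximum on another component's flank, is not a component;
* the M50 reference is the deepest opposite-direction excursion between the
  previous counted peak and this one (at most 60 ms back). When it crosses
  zero it is a true polarity-reversed M50; when it does not, it is the
  preceding trough, so a wiggle riding on a flank contributes only its own
  height, not the flank's;
* significance is the conjunction of the two printed forms of the rule: the
  peak-to-M50 difference must exceed 4 baseline SDs *and* the peak amplitude
  itself must exceed 4 baseline SDs (strictly). The difference criterion
  alone is a peak-to-trough range statistic, and for any in-band Gaussian
  noise such a range spans 4 SD in a scanned window far too easily (~20–30 %
  per window measured under the null); the conjunction brings the
  false-positive rate under 5 % while leaving real components — 10–30 SD at
  this SNR — untouched. Because M100₂..₄ are defined with reference to
  M100₁, they are eligible only when M100₁ itself is significant.

The baseline SD comes from the pre-stimulus samples; `detect_counts()`
pools it over the hemisphere's channels (they share a common noise level by
construction, and 101 samples of a single channel estimate the SD with only
~10 effective degrees of freedom). The per-hemisphere counts are combined
as their maximum. The false-positive property is evaluated on a fixed
measurement channel: selecting the max-peak-to-peak channel among 100+ on
*source-free* data is an extreme-value selection that no fixed threshold
corrects, and is not how a measurement channel is chosen in practice.

## Dipole fitting

`fit_dipole()` is the iterative least-squares equivalent-current-dipole fit:
for a candidate position, the moment timecourse is solved linearly at every
sample of the 40-ms window (peak ± 20 ms) against the unit-moment forward
fields — via SVD pseudo-inverse, because the spherical lead field is rank 2
(the radial moment is silent) — and the position minimizes the residual sum
of squares. Candidates are screened on a 3×3×3 grid (2-cm spacing) beneath
the window's strongest channel; Nelder-Mead simplex refinement starts from
the best grid points, with a barrier keeping positions strictly inside the
sphere. Orientation is the first principal axis of the moment timecourse,
sign-normalized; gof = 1 − SS_residual/SS_data. One dipole per hemisphere is
fitted on that hemisphere's channels. On a noiseless single-dipole field the
round trip recovers the position to well under 1 mm with gof > 0.999; at the
default noise, the median error over seeded runs is under 5 mm. Fits of the
bilateral simulation carry a few millimeters of systematic bias from the
contralateral source — visible in the lateral-offset recovery, which returns
~4 mm for a 5-mm generative offset. No gof acceptance threshold is imposed;
gof is reported and can be filtered on.

## Statistics

`spearman()` computes rho as the Pearson correlation of mid-ranks with a
t-approximation p (n − 2 df) — adequate at the pooled 120-pair scale, and
within 0.05 of exact enumeration even at n = 5. `wilcoxon_signed_rank()`
drops zero differences, mid-ranks ties, and uses the normal approximation
with tie correction and a 0.5 continuity correction, which keeps the
asymptotic p within 0.02 of exact sign-pattern enumeration at n = 8.
`discriminant_wilks()` tests two groups of dipole descriptors (x, y, z
position and the three orientation components, orientation signs normalized
first) via Λ = det(W)/det(W+B) with Bartlett's chi-square approximation;
for two groups this is equivalent to MANOVA, and the implementation is
verified against an independent eigendecomposition and `manova()` to 1e-10.
No multiple-comparison correction is applied, matching the reporting
convention of the emulated analysis. `analysis_report()` assembles the three
correlations (pooled pairs and condition means, labeled), the per-condition
Wilcoxon tests against the 600-ms reference, and the six pairwise component
discriminant rows ("1 vs. 2" … "3 vs. 4") per hemisphere.

## Orchestration and problem sizes

`run_experiment()` runs participants × durations end to end with seeds
derived from one master seed by a stable hash of (stage, participant,
condition), so runs are bit-reproducible and adding conditions never
perturbs existing ones. The default configuration is the full study — 15
participants, 8 durations, 120 epochs, 204 channels — and takes on the
order of 15 minutes on one core. The test suite exercises the same code at
reduced sizes chosen for tight feedback (16–24-site arrays and 8–40-epoch
sets for contracts that do not depend on geometry density; the full default
conditions for the acceptance checks: 20-seed detection at 600 ms, 4-seed
duration profiles, 40-run false-positive estimates, 20-seed noisy
localization). `scripts/acceptance.R` re-runs the full default experiment.

## Known limitations

* The audio-level transition detector is reliable at the base rate and for
  moderate compression; at extreme rates (75–150 ms words) syllables are
  shorter than an analysis frame and the pipeline's timing references come
  from the generator's ground truth instead.
* The 4-SD rule's set-level specificity is limited by its M100₁ stage: a
  100-ms search window on in-band noise false-alarms at ~11 % per
  source-free session even though the per-component rate is under 5 %.
* Bilateral sources bias single-dipole fits by a few millimeters; the
  simultaneous two-dipole fit that would remove this is out of scope.
* Wilks' Λ p-values use Bartlett's approximation; at the small per-group
  sizes of a 15-participant study they are approximate, as in the emulated
  analysis software.
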