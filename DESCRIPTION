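Package: segwin
Title: Temporal Segmentation Window of Speech Perception from Auditory Evoked Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic-data pipeline for studying the temporal segmentation
    window of speech perception in auditory cortex. Synthesizes a four-syllable
    test word, time-stretches it to a range of speech rates at constant average
    level, locates consonant/vowel spectral transitions with a cepstral dynamic
    measure, simulates auditory evoked magnetic fields from bilateral
    superior-temporal current dipoles in a spherical conductor, and implements
    the analysis chain: epoch rejection, averaging, band-pass and notch
    filtering, baseline correction, M50/M100 component detection with a
    4-standard-deviation significance rule, equivalent-current-dipole fitting,
    and the nonparametric correlation and discriminant statistics linking
    evoked-component counts, perceived syllable counts, and stimulus duration.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
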