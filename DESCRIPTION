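Package: fractalHRV
Title: Short-Term Fractal Scaling of Heart Rate Variability and Exercise Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exercise-intensity assessment from beat-to-beat RR interval
    recordings using the short-term scaling exponent alpha1 of detrended
    fluctuation analysis (DFA a1). Provides readers for consumer heart-rate-monitor
    RR exports, missed-beat artifact detection and cubic-spline correction,
    smoothness-priors detrending, rolling time-varying alpha1 computation
    (2-minute windows on a 5-second grid), and estimation of the first and second
    heart-rate-variability thresholds (HRVT at alpha1 = 0.75, HRVT2 at
    alpha1 = 0.5) by linear regression or first-crossing interpolation. Includes
    an exact circulant-embedding fractional-Gaussian-noise generator, synthetic
    incremental-ramp scenarios with planted thresholds, and an artifact-injection
    experiment quantifying alpha1 bias and threshold robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
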