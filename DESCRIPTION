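Package: whiskerglm
Title: Point-Process GLM Encoding Models for Whisker Mechanics and
    Primary Afferent Spiking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether primary whisker afferent spiking is
    driven by rotational forces (bending moment, acceleration-related
    moment) rather than whisker angle. Provides whisker biomechanics
    (quadratic Bezier curvature, curvature change, contact forces,
    Savitzky-Golay angular acceleration, push angle), Bernoulli
    point-process GLMs with stimulus and spike-history filters,
    cross-validated single-trial spike-train prediction with circular-shift
    chance controls, Hilbert-transform whisking amplitude/phase tuning
    analyses, and simulation studies of the angle-curvature confound and of
    single-trial versus repeated-trial prediction ceilings. Includes a
    synthetic-data generator emulating active pole exploration and passive
    whisker stimulation so the full analysis chain is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
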