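Package: erndim
Title: Error-Related Negativity Quantification and Transdiagnostic Symptom Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for relating the error-related
    negativity (ERN) to dimensional psychopathology. Implements adaptive-mean
    and alternative ERP amplitude scoring with baseline correction and
    threshold rejection, even/odd split-half reliability with Spearman-Brown
    correction, exclusion screening for flanker-task cohorts, questionnaire
    scale scoring and projection onto three transdiagnostic symptom dimensions,
    a per-questionnaire and joint-dimension regression battery with Bonferroni
    handling, Fisher-z power analysis for correlations, and a two-step-task
    stay-probability analysis of model-based (goal-directed) learning. Every
    stage is driven by calibrated synthetic-data generators (flanker behaviour,
    response-locked EEG epochs with known ground-truth amplitudes, latent
    three-factor questionnaire cohorts, hybrid reinforcement-learning agents)
    so the full pipeline is verifiable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
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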