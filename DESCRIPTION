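Package: rpevs
Title: Spatiotemporal Analysis of Reward Prediction Error Valence and
    Surprise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the two dimensions of a reward
    prediction error (RPE) -- its categorical valence and its unsigned
    magnitude (surprise) -- are expressed in simultaneously recorded EEG
    and fMRI during probabilistic reversal learning.  Includes a
    criterion-triggered reversal-learning task simulator, a suite of
    reinforcement-learning observer models with maximum-likelihood
    fitting and BIC comparison, single-trial sliding-window regularized
    Fisher discrimination of epoched EEG with leave-one-out ROC (Az)
    cross-validation, permutation null thresholds and forward models,
    and an EEG-informed BOLD general linear model with conjunction
    analysis, resampling-based cluster-size correction, percent signal
    change extraction and a value-update regression.  A synthetic-data
    module generates behavior, EEG epochs and BOLD volumes with planted
    ground truth so that every stage of the pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
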