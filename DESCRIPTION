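Package: axfuse
Title: Clinician-AI Probability Fusion for Axillary Lymph Node Staging on FDG-PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a confidence-weighted fusion of ordinal clinician
    diagnoses (5-grade certainty scale) with continuous AI probabilities for
    axillary lymph node metastasis on FDG-PET/CT, together with the evaluation
    machinery used to study such systems: dichotomized sensitivity/specificity/
    accuracy at nested grade cutoffs, ROC curves with Youden-optimal operating
    points, regrade transition tables, confidence-retention curves, and
    patient-level k-fold cross-validation. Ships synthetic generators for
    cohort diagnosis records (latent-difficulty reader and AI error models) and
    paired PET/CT chest phantoms, plus a small trainable 3D residual attention
    network with auxiliary classifiers, so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
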