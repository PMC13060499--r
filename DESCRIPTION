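Package: sleepproto
Title: Prototype-Quantized Sequence-to-Sequence Sleep Staging with Mechanistic Explanations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-to-sequence sleep staging from multichannel polysomnography
    (EEG, EOG, EMG) in which every decision passes through a learned discrete
    codebook of prototype vectors. Provides EDF reading and the standard
    spectrogram preprocessing pipeline, a stage-structured synthetic
    polysomnography generator, time-wise hard-attention masking with
    Gumbel-softmax selection, residual channel mixing with adaptive channel
    dropout, vector quantization with a straight-through estimator and
    commitment loss, end-to-end training and occlusion-robustness evaluation,
    a mechanistic explanation framework (integrated-gradient relevance with
    completeness, prototype reconstruction with fidelity, plausibility and
    stability metrics, feature-level occlusion relevance and natural-language
    rules), and a downstream clinical analysis of prototype occupancy
    (prototype-grams) with Monte-Carlo cross-validated linear classification
    and rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
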