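Package: duovox
Title: Dual-Pathway Acoustic and Linguistic Speech Reconstruction from
    High-Gamma ECoG
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale framework for reconstructing perceived speech from
    intracranial high-gamma recordings through two complementary decoding
    pathways: an acoustic pathway (bidirectional LSTM adaptor trained with a
    mel-spectrogram plus Laplacian spectral loss, Griffin-Lim vocoding, and a
    HiFi-GAN-style generator skeleton for architecture contracts) and a
    linguistic pathway (seq2seq Transformer adaptor decoding word tokens with
    a KL token loss and Huber length loss), fused by a voice-cloning contract
    that combines linguistic content with the acoustic reference's long-term
    spectrum. Includes a forward-encoding simulator of speech-responsive
    auditory cortex that generates paired speech/neural datasets, high-gamma
    signal preprocessing, speech-responsive electrode selection by paired
    t-test with Bonferroni correction, and the full evaluation suite:
    Levenshtein alignment, word and phoneme error rates, phoneme confusion
    matrices with phoneme-class-clarity statistics and their chance model,
    aligned mel-spectrogram R-squared, additive-noise reference curves, and
    Gaussian-noise-replacement causality controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
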