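---
title: "Dual-pathway speech reconstruction from high-gamma ECoG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-pathway speech reconstruction from high-gamma ECoG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Speech decoding from intracranial recordings faces a trade-off: regression
onto spectral features (mel-spectrograms) preserves acoustic richness —
pitch, timbre, prosody — but yields poorly intelligible words when training
data is scarce, while classification onto discrete linguistic tokens yields
intelligible word sequences but discards the speaker's acoustic signature.
`duovox` implements, at desk scale, a dual-pathway architecture that decodes
both representations in parallel from z-scored high-gamma activity
(70–150 Hz analytic amplitude at 50 Hz frame rate) and fuses them through a
voice-cloning contract: linguistic content from the token pathway, vocal
identity from the acoustic pathway.

Because human ECoG data of this kind is not openly distributable, the
package ships a forward-encoding simulator that generates paired
speech/neural datasets with the statistical structure the decoders assume.
Every downstream stage — preprocessing, electrode selection, both adaptors,
fusion, and the full evaluation suite — is exercised against this simulator.

## The synthetic-data generator

**Speech.** Sentences are drawn from a closed vocabulary (default 50 words)
whose words are 2–5 phoneme strings with strictly alternating
vowel/consonant classes. The phoneme inventory has 8 vowels (harmonic
stacks, f0 = 120 Hz, three formant peaks each) and 12 consonants (Gaussian
band-limited noise bursts with centre frequencies spread over
0.35–7.6 kHz). Segments are joined with 10 ms raised-cosine ramps applied
inside each segment so nominal durations tile exactly; sentences carry
0.4 s leading/trailing silence (the stimulus-protocol inter-sentence
interval) and a 120 ms inter-word gap. The gap length is a generator
parameter: the package's template recognizer segments words at silent runs,
and the 64 ms STFT analysis window must fit inside the gap for that
segmentation to be well defined. Word and phoneme annotations are exact
half-open sample intervals in TIMIT-style `.wrd`/`.phn` conventions.

**Neural responses.** Each responsive channel carries a weighted
combination of log-mel bands (a smooth random Gaussian tuning bump plus a
weaker secondary bump), delayed by a per-channel latency drawn from
40–120 ms — consistent with auditory cortical response latencies — and
convolved with a causal gamma-shaped lag kernel (shape 2, scale 2 frames).
The clean response is standardized to unit variance per recording, Gaussian
noise with standard deviation `noise_sd` is added (so per-channel SNR is
`1 / noise_sd^2`), and the result is z-scored per block. Non-responsive
channels carry pure noise. Neural data are simulated directly at the 50 Hz
modelling rate; an optional "raw mode" synthesizes a wideband carrier whose
70–150 Hz amplitude follows the 50 Hz envelope, solely to exercise the
preprocessing chain.

**Reference conditions.** The default study configuration is 200 sentences
of 3–6 words, 64 channels of which 40 are speech-responsive, `noise_sd` =
0.5, and a random sentence-level 70/20/10 train/validation/test split. The
"separable" configuration used to probe linguistic decodability raises the
sentence count to 400 — roughly the 20 minutes of paired data the decoding
framework targets — and lowers `noise_sd` to 0.1. Sentence count is free
configuration throughout.

**What the simulator does not emulate.** Natural phonotactics, speaker
variability, coarticulation beyond linear cross-fades, non-linear or
adapting neural responses, correlated noise across channels, and artifacts.
Passing tests therefore demonstrate that the pipeline recovers structure
a linear-lagged encoding actually put in, not that it would reach the same
numbers on human cortex.

## Signal preprocessing and electrode selection

High-gamma extraction follows standard analytic-amplitude practice: eight
Gaussian bandpass filters with centres log-spaced over 70–150 Hz (bandwidth
0.39 × centre), FFT-based Hilbert amplitudes averaged across filters,
polyphase resampling to 50 Hz, and per-block z-scoring with a
constant-block guard (blocks with standard deviation below 1e-12 map to
zeros).

Sentence onsets are speech initiations preceded by silence: interior gaps
must strictly exceed 400 ms; the first segment's pre-roll gap uses a
non-strict comparison so a recording opening with exactly the 0.4 s
protocol silence still yields an onset. Speech-responsive electrodes are
selected by a classical paired one-sided Student t-test of mean post-onset
(400–600 ms) versus pre-onset (−200–0 ms) activity, Bonferroni corrected
across channels at family alpha 0.01. Windows are half-open in frames
(pre [−10, 0), post [20, 30) at 50 Hz); onsets whose windows cross block
boundaries are dropped because z-scoring is discontinuous there.

## Spectral operators and losses

The mel-spectrogram operator uses STFT `n_fft` 1024, hop 320 and 80 mel
bands over 0–8 kHz with natural-log compression floored at 1e-5. Hop 320
at 16 kHz gives exactly 50 frames/s — frame-aligned with the neural rate —
and honours the vocoder's 320-samples-per-frame output relation.

The acoustic training loss is `L = L_Mel + 0.1 · L_Lap`: the mean absolute
mel difference plus a Laplacian edge term. The Laplacian kernel is the
standard 5-point stencil with mirror padding (the kernel itself is a free
choice; this one annihilates constants, so the term compares local
spectrotemporal structure only). The mean (not sum) reduction keeps the
printed loss weights meaningful across utterance durations.

The GAN generator objective is implemented in least-squares form with
per-layer-normalized L1 feature matching and weights `lambda_fm` = 2,
`lambda_mel` = 50. The adversarial equation is written from the
discriminator's viewpoint in the source framework; the generator /
discriminator split here follows the standard LSGAN convention (generator
term `(D(x_sae) − 1)^2`, discriminator term `(D(x) − 1)^2 + D(x_sae)^2`)
and is documented as an interpretation.

The fusion-quality metric is a per-frame KL divergence between mel frames
(each log-mel frame shifted positive and normalized to sum 1, floor 1e-8,
`0 log 0 = 0`) plus a mean-absolute MFCC difference (13 DCT-II
coefficients of the log-mel). It is a metric only; no external
text-to-speech engine is fine-tuned.

## The acoustic pathway

A three-layer bidirectional LSTM maps selected-channel high-gamma to
spectral features, one output frame per input frame. The default feature
space is the 80-band log-mel itself (identity feature-to-mel map); a 768-d
fixed-random-projection mode preserves the wider interface dimension of
pre-trained speech encoders for interface tests. Waveforms are produced by
Griffin-Lim inversion of the pseudo-inverted mel filterbank (60 iterations,
zero initial phase, hence deterministic); a HiFi-GAN-style generator
skeleton — transposed-convolution upsampling at rates [2,2,2,2,2,2,5]
(product 320), kernel sizes [2,2,3,3,3,3,10], two-branch dilated residual
fusion per stage, and a full-padded kernel-81 output convolution — realizes
the `320·T + 80` output-length contract at unit-test scale with random
weights.

The engine is written in vectorized base R with hand-derived
backpropagation through time (no deep-learning framework is involved);
batched over whole utterances sorted by length, with exact masking for
variable lengths. Gradients are pinned against central finite differences
in the test suite. The reference optimizer is SGD with learning rate 3e-3
and momentum 0.5 with 10% between-layer dropout; training output biases
are initialized to the training-set band means so early epochs learn
structure rather than the global mel offset, and early stopping returns
the best-validation checkpoint (patience 10). Because the robust L1
objective yields constant-magnitude gradients, plain SGD at the reference
rate converges slowly at desk scale; desk runs therefore use the Adam
variant (learning rate 3e-3, batch 8) and a hidden size of 64 per
direction, which reaches held-out aligned mel R^2 above 0.6 on the
reference dataset in roughly 30 epochs (~5 minutes of CPU). The hidden
size of the full-scale architecture is not pinned by the printed parameter
count; it is configurable, and the parameter count is reported by the
print method.

## The linguistic pathway

An attention-based seq2seq Transformer decodes word-token sequences:
3 + 3 pre-LN encoder/decoder blocks, hidden 256, 8 heads, sinusoidal
positional encoding, linear input projection of the (average-pooled)
neural frames, a 1024-d linguistic-feature interface layer projecting onto
vocabulary logits, and a scalar length head on the mean-pooled encoder
memory. The desk recipe shrinks this to 2 + 2 blocks, hidden 96, 4
heads.
The vocabulary reserves PAD = 0, SOS = 1, EOS = 2; decoding is greedy from
SOS until EOS (no beam search — the reference framework states no search
strategy). The loss is the token-level KL divergence with label smoothing
0.1 (disclosed: smoothing makes the KL strictly proper) plus a Huber
(delta = 1) length loss at weight 1; the L2 term of the objective is
realized as decoupled AdamW weight decay 0.01 rather than an explicit loss
term.

The library defaults reproduce the reference recipe exactly (50 Hz frames
consumed directly, no augmentation, no dropout, no auxiliary loss). Four
opt-in additions make training practical and accurate on 20-minute-scale
data, and the desk recipe uses all of them:

* **A monotonic alignment prior** on cross-attention: a fixed Gaussian
  score bias `−((j − a − b·k)^2) / (2σ^2)` centred on the expected encoder
  frame of output position `k`, with rate `b`, offset `a` and spread `σ`
  estimated by linear regression of word-midpoint frames on word index
  over the training annotations. Speech-to-sequence models at this data
  scale are known to fail at learning alignment before they overfit; the
  prior (in the spirit of guided attention in neural TTS) supplies the
  monotonicity that large corpora would teach, while leaving all content
  learning to the attention weights. It is estimated from training data
  only and can be disabled (`align_prior = FALSE`); without it the desk
  models learn word priors but never the neural alignment.
* **Moderate temporal pooling** (`downsample` = 3, i.e. 60 ms frames):
  shortens the encoder sequence while keeping consonant-scale temporal
  detail. This is the single largest accuracy factor at desk scale —
  pooling at 80 ms roughly doubles the held-out word error rate, because
  consonant bursts span only 80 ms.
* **Input-noise augmentation** (`augment_sd` = 0.3) and **sublayer
  dropout** (0.1): the regularizers beyond weight decay and label
  smoothing.
* **An auxiliary frame-wise word-classification loss** (weight 0.5) on
  the encoder memory, with labels from the training annotations (PAD in
  silence): it teaches the encoder local word identity directly, roughly
  halving the epochs the decoder needs to converge.

Desk checkpoints are selected by validation WER (greedy decoding every
third epoch) rather than validation loss. Beam search was evaluated and
did not improve on greedy decoding under the final recipe, so greedy
remains both the default and the evaluated path.

## Fusion

The voice-cloning stage fixes the contract — reference waveform plus
transcribed word sequence in, fused waveform out — and ships a transparent
baseline engine: the decoded text is synthesized from the phoneme
templates and filtered so its long-term average spectrum (LTAS, smoothed
over 9 frequency bins) matches the (spectral-subtraction denoised)
acoustic-pathway reference. External engines can be registered but are
never required. The reference input is the acoustic-pathway output; the
alternative reading (a linguistic-pathway reference) is configurable
through the request object. No perceptual-quality replication is attempted.

## Evaluation

Word and phoneme error rates divide the Levenshtein distance by the
reference length (rates can exceed 1; the denominator is the reference).
Alignment uses unit costs and a deterministic traceback preference
match > substitution > deletion > insertion. Confusion matrices tally
matches and substitutions with insertion/deletion margins; phoneme class
clarity (PCC) is the within-class over between-class substitution ratio,
with an analytic chance model under uniform substitution over the other
P − 1 symbols, weighted by observed per-symbol error counts.

Aligned mel R^2 slices both spectrograms at the reference word intervals
(hypothesis spans from its own annotations when present, else by
proportional mapping), linearly resamples each hypothesis segment to the
reference frame count, and correlates the concatenated voiced segments.
Note two properties of this flattened Pearson statistic on synthetic
spectra. It has a high broadband baseline — independent white noise scores
near 0.3 against speech, because any broadband signal shares the band-mean
structure — and it is bounded below 1 even for nearly identical audio: the
templates' spectrally sparse mel rows contain near-floor cells where log
compression amplifies arbitrarily small perturbations (60 dB SNR audio
scores about 0.83, not 0.99). All comparisons in the package are therefore
relative (matched vs. corrupted vs. chance), not absolute.

WER/PER on synthetic audio use a bundled template recognizer (per-frame
nearest-template cosine matching in linear mel space with a silence
template, run-length collapse with a 2-frame minimum, word segmentation at
silence runs, vocabulary lookup by phoneme edit distance). Its own error
floor on clean synthesis is zero on the default inventory and is asserted
in the tests; on noisy or vocoded audio its errors are acoustic
confusions, which is what the confusion/PCC analyses need. Standard errors
are computed across trials (the unit of replication is fixed as the
trial).

The Gaussian-noise-replacement control replaces the first half, second
half, or all of the neural input with standard normal noise and scores
word-level R^2 separately over each temporal half — the causality check
that reconstruction is temporally locked to its neural input rather than
hallucinated from the decoder prior.

## Numerical choices and degenerate inputs

* Z-scoring guards: blocks with standard deviation < 1e-12 map to zeros;
  channels with zero clean response stay zero at zero noise.
* Paired t-test with zero differences returns t = 0, p = 0.5; fewer than
  two usable onsets is an error, an empty selection is an error.
* `pcc` returns flagged `Inf` when between-class substitutions are absent
  and flagged `NaN` with zero substitutions; `chancePcc` refuses
  single-class inventories.
* Probability floors: token KL uses `0 log 0 = 0` and floors predictions
  at 1e-300; mel-frame probabilities floor at 1e-8.
* Mirror padding everywhere a finite-support kernel meets an edge (STFT
  framing, Laplacian stencil); the Laplacian adjoint used in
  backpropagation is the exact transpose of the padded stencil and is
  tested as such.
* Seeds: every stochastic stage derives its stream from one master seed
  through a deterministic splitter, so dataset regeneration is
  bit-identical and training histories are exactly reproducible.

## Problem sizes used by the tests and the acceptance script

Unit tests run on miniature datasets (16–24 sentences, 8–16 channels).
The acceptance analyses use the reference dataset (200 sentences, 64
channels) for acoustic parameter recovery (hidden 64, Adam, ~30 epochs)
and the causality control, the 400-sentence separable dataset for
linguistic recovery (hidden 96, 48 epochs), a 100-sentence/16-channel/20-word
configuration with proportionally smaller adaptors for the data-volume
ablation (the smaller vocabulary keeps word identity learnable at
fractions of an already small training set, so the data-volume effect is
visible above the noise floor), and simulation sizes of 10^5–10^6 draws for the calibration and
chance-model checks. These sizes are the package's
choices for a desk-scale study; the printed reference architecture (hidden
256, 3 + 3 blocks) remains the configuration default.

## Known limitations

* The vocoder is Griffin-Lim, not a trained neural vocoder; vocoded audio
  is intelligible to the template recognizer but not natural-sounding.
* The fusion engine transfers only the long-term average spectrum — a
  deliberately transparent stand-in for voice cloning, not a perceptual
  match.
* The alignment prior assumes roughly constant word rate, which the
  generator satisfies; strongly variable speech rates would need the
  prior disabled or re-estimated.
* Error rates from the template recognizer reflect template-space
  confusability, which is cleaner than large-vocabulary ASR behaviour.
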