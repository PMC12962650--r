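#' MelSpectrogram: log-mel time-frequency representation
#'
#' Frames-by-bands matrix of natural-log mel energies produced by
#' [melSpectrogram()]. Frames advance at `sampleRate / hop` Hz (50 Hz at the
#' package defaults of 16 kHz audio and hop 320), bands span 0-8 kHz on the
#' mel scale, and values are floored at `log(1e-5)`.
#'
#' @slot values numeric matrix, frames x n_mels.
#' @slot frameRate frames per second.
#' @slot sampleRate audio sample rate the frames refer to.
#' @slot hop hop length in samples.
#' @exportClass MelSpectrogram
setClass("MelSpectrogram",
  representation(values = "matrix", frameRate = "numeric",
                 sampleRate = "numeric", hop = "integer"))

setValidity("MelSpectrogram", function(object) {
  if (!all(is.finite(object@values))) return("mel values must be finite")
  if (object@frameRate <= 0) return("frameRate must be positive")
  TRUE
})

#' AnnotatedUtterance: waveform with word and phoneme intervals
#'
#' A mono waveform together with TIMIT-style annotations: half-open
#' `[start, end)` sample intervals for words and phonemes.
#'
#' @slot wave numeric waveform in [-1, 1].
#' @slot sampleRate samples per second (16000 throughout the package).
#' @slot words data.frame with columns `start`, `end` (0-based samples,
#'   half-open) and `label`.
#' @slot phonemes data.frame with the same columns for phoneme segments.
#' @slot id utterance identifier.
#' @exportClass AnnotatedUtterance
setClass("AnnotatedUtterance",
  representation(wave = "numeric", sampleRate = "numeric",
                 words = "data.frame", phonemes = "data.frame",
                 id = "character"))

setValidity("AnnotatedUtterance", function(object) {
  for (tab in list(object@words, object@phonemes)) {
    if (nrow(tab) == 0) next
    if (!all(c("start", "end", "label") %in% names(tab)))
      return("annotation tables need start/end/label columns")
    if (any(tab$end <= tab$start)) return("annotation intervals must be non-empty")
    if (any(tab$end > length(object@wave)))
      return("annotation intervals exceed waveform length")
  }
  if (object@sampleRate <= 0) return("sampleRate must be positive")
  TRUE
})

#' NeuralRecording: z-scored high-gamma matrix at 50 Hz
#'
#' Channels-by-frames matrix of block z-scored high-gamma analytic
#' amplitude, the N x T input consumed by both decoding pathways.
#'
#' @slot hg numeric matrix, channels x frames.
#' @slot frameRate frames per second (50).
#' @slot blockStarts integer 1-based frame indices where recording blocks
#'   begin; the first element is always 1.
#' @slot channelIds integer channel identifiers (row order of `hg`).
#' @exportClass NeuralRecording
setClass("NeuralRecording",
  representation(hg = "matrix", frameRate = "numeric",
                 blockStarts = "integer", channelIds = "integer"))

setValidity("NeuralRecording", function(object) {
  if (length(object@blockStarts) < 1 || object@blockStarts[1] != 1L)
    return("blockStarts must begin with frame 1")
  if (is.unsorted(object@blockStarts, strictly = TRUE))
    return("blockStarts must be strictly increasing")
  if (max(object@blockStarts) > max(1L, ncol(object@hg)))
    return("blockStarts exceed frame count")
  if (length(object@channelIds) != nrow(object@hg))
    return("channelIds must match hg rows")
  TRUE
})

#' Vocabulary: closed word set with phoneme spellings and token ids
#'
#' Houses the word tokens of the linguistic pathway. Token ids are
#' contiguous from 0 with reserved PAD = 0, SOS = 1, EOS = 2 followed by
#' one id per word.
#'
#' @slot words character vector of unique word strings.
#' @slot phonemeSeqs list of character vectors, the phoneme spelling of
#'   each word.
#' @slot tokenIds named integer vector over `c("<pad>","<sos>","<eos>", words)`.
#' @exportClass Vocabulary
setClass("Vocabulary",
  representation(words = "character", phonemeSeqs = "list",
                 tokenIds = "integer"))

setValidity("Vocabulary", function(object) {
  if (anyDuplicated(object@words)) return("word strings must be unique")
  if (length(object@phonemeSeqs) != length(object@words))
    return("one phoneme sequence per word required")
  ids <- sort(unname(object@tokenIds))
  if (!identical(ids, seq(0L, length(object@tokenIds) - 1L)))
    return("token ids must be contiguous from 0")
  need <- c("<pad>", "<sos>", "<eos>", object@words)
  if (!all(need %in% names(object@tokenIds)))
    return("tokenIds must cover PAD/SOS/EOS and every word")
  TRUE
})

#' EncodingModel: forward model of speech-responsive cortex
#'
#' Linear-lagged spectrotemporal encoding used by the simulator: each
#' responsive channel responds to a weighted combination of mel bands,
#' delayed by a per-channel latency and smeared by a causal gamma-shaped
#' lag kernel, plus Gaussian noise; non-responsive channels carry noise only.
#'
#' @slot weights channels x n_mels gain matrix (all-zero rows for
#'   non-responsive channels).
#' @slot lagKernel causal impulse response over frames, sums to 1.
#' @slot latency integer per-channel lag in frames.
#' @slot noiseSd noise standard deviation in units of the (unit-variance)
#'   clean response.
#' @slot responsiveMask logical per channel.
#' @exportClass EncodingModel
setClass("EncodingModel",
  representation(weights = "matrix", lagKernel = "numeric",
                 latency = "integer", noiseSd = "numeric",
                 responsiveMask = "logical"))

setValidity("EncodingModel", function(object) {
  if (abs(sum(object@lagKernel) - 1) > 1e-8) return("lagKernel must sum to 1")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (length(object@responsiveMask) != nrow(object@weights))
    return("responsiveMask must match weight rows")
  if (length(object@latency) != nrow(object@weights))
    return("latency must match weight rows")
  bad <- !object@responsiveMask &
    rowSums(abs(object@weights)) > 1e-12
  if (any(bad)) return("non-responsive channels must have all-zero weights")
  TRUE
})

#' SyntheticDataset: paired speech/neural trials with split labels
#'
#' @slot utterances list of [AnnotatedUtterance-class] objects.
#' @slot neural list of [NeuralRecording-class] objects aligned 1:1 with
#'   `utterances`.
#' @slot split character vector in `{train, val, test}` per trial.
#' @slot vocab the [Vocabulary-class] the sentences were drawn from.
#' @slot model the generating [EncodingModel-class].
#' @slot seed integer seed the dataset was generated from.
#' @slot config the generating configuration list.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(utterances = "list", neural = "list", split = "character",
                 vocab = "Vocabulary", model = "EncodingModel",
                 seed = "integer", config = "list"))

setValidity("SyntheticDataset", function(object) {
  if (length(object@utterances) != length(object@neural))
    return("utterance and neural lists must align 1:1")
  if (length(object@split) != length(object@utterances))
    return("one split label per trial required")
  if (!all(object@split %in% c("train", "val", "test")))
    return("split labels must be train/val/test")
  TRUE
})

#' ResponsivenessResult: per-channel speech-responsiveness test
#'
#' Output of [responsivenessTest()]: paired one-sided t statistics of
#' post-onset versus pre-onset mean high-gamma, Bonferroni-corrected
#' across channels.
#'
#' @slot statistic per-channel paired t statistic.
#' @slot pValue per-channel one-sided p-value.
#' @slot alpha family-wise alpha (0.01).
#' @slot correctedAlpha `alpha / n_channels`.
#' @slot selected logical mask, `pValue < correctedAlpha`.
#' @slot nOnsets number of usable onsets entering the test.
#' @slot channelIds channel identifiers.
#' @exportClass ResponsivenessResult
setClass("ResponsivenessResult",
  representation(statistic = "numeric", pValue = "numeric", alpha = "numeric",
                 correctedAlpha = "numeric", selected = "logical",
                 nOnsets = "integer", channelIds = "integer"))

setValidity("ResponsivenessResult", function(object) {
  if (any(object@pValue < 0 | object@pValue > 1, na.rm = TRUE))
    return("p-values must lie in [0, 1]")
  ok <- object@selected == (!is.na(object@pValue) &
                            object@pValue < object@correctedAlpha)
  if (!all(ok)) return("selected must equal p < corrected alpha")
  TRUE
})

#' ConfusionMatrix: phoneme substitution/match counts with margins
#'
#' Reference symbols index rows, hypothesis symbols index columns; the
#' diagonal holds match counts and off-diagonal cells substitution counts.
#' Insertions (hypothesis symbols with no reference partner) and deletions
#' (reference symbols with no hypothesis partner) are kept as margins.
#'
#' @slot counts P x P numeric matrix.
#' @slot insertions named numeric vector per hypothesis symbol.
#' @slot deletions named numeric vector per reference symbol.
#' @slot classMap named character vector mapping each symbol to
#'   `"vowel"` or `"consonant"`.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", insertions = "numeric",
                 deletions = "numeric", classMap = "character"))

setValidity("ConfusionMatrix", function(object) {
  if (nrow(object@counts) != ncol(object@counts))
    return("counts must be square")
  if (!identical(rownames(object@counts), colnames(object@counts)))
    return("row and column symbols must agree")
  if (!all(rownames(object@counts) %in% names(object@classMap)))
    return("classMap must cover all symbols")
  if (!all(object@classMap %in% c("vowel", "consonant")))
    return("classes must be vowel/consonant")
  TRUE
})

#' EvalReport: per-trial and aggregate decoding metrics
#'
#' @slot perTrial data.frame with one row per trial and one column per
#'   metric (mel R^2, WER, PER, ...).
#' @slot summary data.frame with columns `metric`, `mean`, `se`, `n`
#'   (standard error across trials; `NA` for a single trial).
#' @slot confusion the pooled [ConfusionMatrix-class] (may be empty).
#' @slot pcc phoneme class clarity of the pooled confusion matrix with its
#'   chance level, as a named numeric vector.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(perTrial = "data.frame", summary = "data.frame",
                 confusion = "ConfusionMatrix", pcc = "numeric"))

setMethod("show", "MelSpectrogram", function(object) {
  cat(sprintf("MelSpectrogram: %d frames x %d bands @ %g Hz (floor %.3f)\n",
              nrow(object@values), ncol(object@values), object@frameRate,
              log(1e-5)))
})

setMethod("show", "AnnotatedUtterance", function(object) {
  cat(sprintf("AnnotatedUtterance '%s': %.2f s @ %g Hz, %d words, %d phonemes\n",
              object@id, length(object@wave) / object@sampleRate,
              object@sampleRate, nrow(object@words), nrow(object@phonemes)))
})

setMethod("show", "NeuralRecording", function(object) {
  cat(sprintf("NeuralRecording: %d channels x %d frames @ %g Hz, %d block(s)\n",
              nrow(object@hg), ncol(object@hg), object@frameRate,
              length(object@blockStarts)))
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d words, %d token ids (PAD/SOS/EOS reserved)\n",
              length(object@words), length(object@tokenIds)))
})

setMethod("show", "SyntheticDataset", function(object) {
  tab <- table(factor(object@split, levels = c("train", "val", "test")))
  cat(sprintf("SyntheticDataset: %d trials (train %d / val %d / test %d), seed %d\n",
              length(object@utterances), tab[1], tab[2], tab[3], object@seed))
})

setMethod("show", "ResponsivenessResult", function(object) {
  cat(sprintf("ResponsivenessResult: %d/%d channels selected (alpha %.3g, Bonferroni %.3g, %d onsets)\n",
              sum(object@selected), length(object@selected), object@alpha,
              object@correctedAlpha, object@nOnsets))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: %d symbols, %d matches, %d substitutions, %d ins, %d del\n",
              nrow(object@counts), round(sum(diag(object@counts))),
              round(sum(object@counts) - sum(diag(object@counts))),
              round(sum(object@insertions)), round(sum(object@deletions))))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  print(object@summary, row.names = FALSE)
})
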