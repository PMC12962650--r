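#' Accessors for duovox containers
#'
#' Small accessor layer over the S4 containers so user code never touches
#' slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("melValues", function(x) standardGeneric("melValues"))
#' @rdname accessors
#' @export
setMethod("melValues", "MelSpectrogram", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("melValues", "matrix", function(x) x)

#' @rdname accessors
#' @export
setGeneric("waveform", function(x) standardGeneric("waveform"))
#' @rdname accessors
#' @export
setMethod("waveform", "AnnotatedUtterance", function(x) x@wave)
#' @rdname accessors
#' @export
setMethod("waveform", "numeric", function(x) x)

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setMethod("sampleRate", "AnnotatedUtterance", function(x) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "MelSpectrogram", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setGeneric("wordIntervals", function(x) standardGeneric("wordIntervals"))
#' @rdname accessors
#' @export
setMethod("wordIntervals", "AnnotatedUtterance", function(x) x@words)

#' @rdname accessors
#' @export
setGeneric("phonemeIntervals", function(x) standardGeneric("phonemeIntervals"))
#' @rdname accessors
#' @export
setMethod("phonemeIntervals", "AnnotatedUtterance", function(x) x@phonemes)

#' @rdname accessors
#' @export
setGeneric("hgMatrix", function(x) standardGeneric("hgMatrix"))
#' @rdname accessors
#' @export
setMethod("hgMatrix", "NeuralRecording", function(x) x@hg)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "NeuralRecording", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "MelSpectrogram", function(x) x@frameRate)

#' @rdname accessors
#' @export
setGeneric("blockStarts", function(x) standardGeneric("blockStarts"))
#' @rdname accessors
#' @export
setMethod("blockStarts", "NeuralRecording", function(x) x@blockStarts)

#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setMethod("channelIds", "NeuralRecording", function(x) x@channelIds)
#' @rdname accessors
#' @export
setMethod("channelIds", "ResponsivenessResult", function(x) x@channelIds)

#' @rdname accessors
#' @export
setGeneric("vocabWords", function(x) standardGeneric("vocabWords"))
#' @rdname accessors
#' @export
setMethod("vocabWords", "Vocabulary", function(x) x@words)

#' @rdname accessors
#' @export
setGeneric("tokenIds", function(x) standardGeneric("tokenIds"))
#' @rdname accessors
#' @export
setMethod("tokenIds", "Vocabulary", function(x) x@tokenIds)

#' @rdname accessors
#' @export
setGeneric("phonemeSpelling", function(x) standardGeneric("phonemeSpelling"))
#' @rdname accessors
#' @export
setMethod("phonemeSpelling", "Vocabulary", function(x) {
  stats::setNames(x@phonemeSeqs, x@words)
})

#' @rdname accessors
#' @export
setGeneric("splitLabels", function(x) standardGeneric("splitLabels"))
#' @rdname accessors
#' @export
setMethod("splitLabels", "SyntheticDataset", function(x) x@split)

#' @rdname accessors
#' @export
setGeneric("trialUtterances", function(x) standardGeneric("trialUtterances"))
#' @rdname accessors
#' @export
setMethod("trialUtterances", "SyntheticDataset", function(x) x@utterances)

#' @rdname accessors
#' @export
setGeneric("trialNeural", function(x) standardGeneric("trialNeural"))
#' @rdname accessors
#' @export
setMethod("trialNeural", "SyntheticDataset", function(x) x@neural)

#' @rdname accessors
#' @export
setGeneric("datasetVocabulary", function(x) standardGeneric("datasetVocabulary"))
#' @rdname accessors
#' @export
setMethod("datasetVocabulary", "SyntheticDataset", function(x) x@vocab)

#' @rdname accessors
#' @export
setGeneric("encodingModel", function(x) standardGeneric("encodingModel"))
#' @rdname accessors
#' @export
setMethod("encodingModel", "SyntheticDataset", function(x) x@model)

#' @rdname accessors
#' @export
setGeneric("responsiveMask", function(x) standardGeneric("responsiveMask"))
#' @rdname accessors
#' @export
setMethod("responsiveMask", "EncodingModel", function(x) x@responsiveMask)

#' @rdname accessors
#' @export
setGeneric("selectedMask", function(x) standardGeneric("selectedMask"))
#' @rdname accessors
#' @export
setMethod("selectedMask", "ResponsivenessResult", function(x) x@selected)

#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("confusionMargins", function(x) standardGeneric("confusionMargins"))
#' @rdname accessors
#' @export
setMethod("confusionMargins", "ConfusionMatrix", function(x) {
  list(insertions = x@insertions, deletions = x@deletions)
})

#' @rdname accessors
#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))
#' @rdname accessors
#' @export
setMethod("classMap", "ConfusionMatrix", function(x) x@classMap)

#' @rdname accessors
#' @export
setGeneric("perTrialMetrics", function(x) standardGeneric("perTrialMetrics"))
#' @rdname accessors
#' @export
setMethod("perTrialMetrics", "EvalReport", function(x) x@perTrial)

#' @rdname accessors
#' @export
setGeneric("reportSummary", function(x) standardGeneric("reportSummary"))
#' @rdname accessors
#' @export
setMethod("reportSummary", "EvalReport", function(x) x@summary)
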