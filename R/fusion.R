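## Pathway fusion via the voice-cloning contract: linguistic content from
## decoded tokens, vocal identity from the acoustic-pathway reference.

#' Transcribe token ids to text
#'
#' Space-joined lowercase words; PAD/SOS/EOS ids are stripped.
#'
#' @param tokens integer token ids (0-based) or a `TokenSequence`.
#' @param vocab a [Vocabulary-class].
#' @return character scalar (empty string for an empty sequence).
#' @export
transcribeTokens <- function(tokens, vocab) {
  ids <- tokenIds(vocab)
  toks <- as.integer(tokens)
  reserved <- ids[c("<pad>", "<sos>", "<eos>")]
  toks <- toks[!(toks %in% reserved)]
  if (length(toks) == 0) return("")
  unknown <- setdiff(toks, unname(ids))
  if (length(unknown) > 0)
    stop("unknown token id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lut <- stats::setNames(names(ids), ids)
  paste(tolower(lut[as.character(toks)]), collapse = " ")
}

#' Spectral-subtraction denoising
#'
#' Estimates the noise magnitude profile from the quietest 10 percent of
#' STFT frames and subtracts it (flooring at 2 percent of the original
#' magnitude), resynthesizing with the original phase. The output RMS
#' never exceeds the input RMS.
#'
#' @param x waveform or [AnnotatedUtterance-class].
#' @return denoised waveform.
#' @export
denoiseReference <- function(x) {
  if (is(x, "AnnotatedUtterance")) x <- waveform(x)
  if (length(x) < 1024L || stats::sd(x) < 1e-12) return(x)
  S <- stft(x)
  mag <- Mod(S)
  energy <- colSums(mag^2)
  nq <- max(1L, floor(0.1 * length(energy)))
  profile <- rowMeans(mag[, order(energy)[seq_len(nq)], drop = FALSE])
  cleanMag <- pmax(mag - profile, 0.02 * mag)
  y <- istft(cleanMag * exp(1i * Arg(S)), n_out = length(x))
  rin <- sqrt(mean(x^2)); rout <- sqrt(mean(y^2))
  if (rout > rin && rout > 0) y <- y * (rin / rout)
  y
}

## engine registry lives in the package namespace
cloneEngines <- new.env(parent = emptyenv())

#' Register a voice-cloning engine
#'
#' An engine is a function `function(request) -> waveform`. External
#' engines (large TTS systems) may be registered here; the bundled
#' `"ltas"` baseline is always available and is the only engine tests
#' rely on.
#'
#' @param name engine identifier.
#' @param fn engine function.
#' @return invisibly, the engine name.
#' @export
registerCloneEngine <- function(name, fn) {
  assertThat(is.function(fn), "engine must be a function")
  assign(name, fn, envir = cloneEngines)
  invisible(name)
}

#' Build a voice-cloning request
#'
#' @param reference_waveform the (optionally denoised) acoustic-pathway
#'   output carrying the target vocal identity; at least 0.5 s.
#' @param target_text word sequence transcribed from the decoded tokens.
#' @param vocab a [Vocabulary-class] covering the text.
#' @param inventory phoneme inventory for the baseline synthesizer.
#' @param engine engine id (see [registerCloneEngine()]).
#' @param seed RNG seed for the synthesis.
#' @param sample_rate audio sample rate.
#' @param filter_order spectral resolution (smoothing bins) of the LTAS
#'   matching filter.
#' @return a `CloneRequest` list.
#' @export
cloneRequest <- function(reference_waveform, target_text, vocab,
                         inventory = defaultPhonemeInventory(),
                         engine = "ltas", seed = 1L, sample_rate = 16000,
                         filter_order = 9L) {
  assertThat(nchar(trimws(target_text)) > 0, "target text must be non-empty")
  assertThat(length(reference_waveform) >= 0.5 * sample_rate,
             "reference must be at least 0.5 s")
  structure(list(reference = reference_waveform, text = target_text,
                 vocab = vocab, inventory = inventory, engine = engine,
                 seed = seed, sample_rate = sample_rate,
                 filter_order = filter_order),
            class = "CloneRequest")
}

#' Long-term average spectrum of a waveform
#' @param x waveform.
#' @param smooth smoothing width in bins (odd).
#' @return numeric vector over 513 frequency bins.
#' @export
ltas <- function(x, smooth = 9L) {
  mag <- rowMeans(Mod(stft(x)))
  k <- rep(1 / smooth, smooth)
  as.numeric(stats::filter(mag, k, sides = 2L, circular = TRUE))
}

#' @keywords internal
ltasBaselineEngine <- function(request) {
  words <- strsplit(trimws(request$text), "\\s+")[[1]]
  synth <- synthesizeUtterance(words, request$vocab, request$inventory,
                               request$sample_rate, seed = request$seed,
                               id = "clone")
  y <- waveform(synth)
  lr <- ltas(request$reference, request$filter_order)
  ly <- ltas(y, request$filter_order)
  gain <- pmin(pmax(lr / pmax(ly, 1e-8), 0), 20)
  # leave bins without source energy untouched: amplifying them only
  # injects rumble into silent spans
  gain[ly < 1e-3 * max(ly)] <- 1
  S <- stft(y)
  out <- istft(S * gain, n_out = length(y))
  # preserve the synthesis' exact silences: spectral filtering rings into
  # silent spans otherwise
  out[y == 0] <- 0
  peak <- max(abs(out))
  if (peak > 1) out <- out / peak
  attr(out, "annotations") <- synth
  out
}

#' Clone a voice onto decoded linguistic content
#'
#' Pluggable fusion stage combining the two decoding pathways: the target
#' text (linguistic pathway) is synthesized and filtered so its long-term
#' average spectrum matches the reference waveform's (acoustic pathway),
#' transferring the reference's coarse vocal signature onto the decoded
#' word sequence. External engines may replace the bundled baseline.
#'
#' @param request a `CloneRequest` (see [cloneRequest()]).
#' @return fused waveform; the baseline engine attaches the synthesis
#'   annotations as attribute `"annotations"`.
#' @export
voiceClone <- function(request) {
  assertThat(inherits(request, "CloneRequest"), "need a CloneRequest")
  fn <- if (request$engine == "ltas") ltasBaselineEngine
    else if (exists(request$engine, envir = cloneEngines))
      get(request$engine, envir = cloneEngines)
    else stop("unknown clone engine '", request$engine, "'", call. = FALSE)
  fn(request)
}
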