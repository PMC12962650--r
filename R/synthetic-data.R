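## Synthetic paired speech + ECoG generator.
##
## Speech is built from a closed inventory of phoneme templates (vowels =
## harmonic stacks with formant peaks, consonants = band-limited noise
## bursts); simulated cortex responds to the stimulus log-mel spectrogram
## through a linear-lagged forward encoding model with per-channel latency,
## a causal gamma-shaped lag kernel, additive Gaussian noise, and block
## z-scoring -- the statistical structure the decoding pathways assume.

#' Construct a phoneme template
#'
#' @param label phoneme symbol.
#' @param klass `"vowel"` or `"consonant"`.
#' @param duration_s segment duration in seconds (> 0).
#' @param formants for vowels: formant centre frequencies in Hz.
#' @param formant_amps relative formant amplitudes.
#' @param band for consonants: `c(center, width)` of the noise band in Hz.
#' @param f0 fundamental frequency for vowels (Hz).
#' @return a `PhonemeTemplate` list with a `spectral_profile` of per-mel-band
#'   target energies (the mel projection of the template's ideal spectrum).
#' @export
phonemeTemplate <- function(label, klass, duration_s,
                            formants = NULL, formant_amps = NULL,
                            band = NULL, f0 = 120) {
  assertThat(klass %in% c("vowel", "consonant"),
             "klass must be vowel or consonant")
  assertThat(duration_s > 0, "duration_s must be positive")
  tmpl <- list(label = label, klass = klass, duration_s = duration_s,
               formants = formants, formant_amps = formant_amps,
               band = band, f0 = f0)
  fb <- melFilterbank()
  freqs <- seq(0, 8000, length.out = 513L)
  prof <- as.numeric(fb %*% templateSpectrum(tmpl, freqs))
  assertThat(all(prof >= 0), "spectral profile must be non-negative")
  tmpl$spectral_profile <- prof
  structure(tmpl, class = "PhonemeTemplate")
}

#' Ideal magnitude spectrum of a template on a frequency grid
#' @keywords internal
templateSpectrum <- function(tmpl, freqs) {
  if (tmpl$klass == "vowel") {
    env <- vowelEnvelope(tmpl, freqs)
    harm <- seq(tmpl$f0, 8000, by = tmpl$f0)
    spec <- numeric(length(freqs))
    for (h in harm) {
      i <- which.min(abs(freqs - h))
      spec[i] <- spec[i] + vowelEnvelope(tmpl, h)
    }
    spec
  } else {
    exp(-0.5 * ((freqs - tmpl$band[1]) / (tmpl$band[2] / 2))^2)
  }
}

#' @keywords internal
vowelEnvelope <- function(tmpl, f) {
  bw <- c(90, 140, 200)[seq_along(tmpl$formants)]
  env <- 0
  for (j in seq_along(tmpl$formants))
    env <- env + tmpl$formant_amps[j] * exp(-0.5 * ((f - tmpl$formants[j]) / bw[j])^2)
  env
}

#' Default phoneme inventory: 8 vowels and 12 consonants
#'
#' Small enough for exhaustive tests, rich enough for phoneme-confusion
#' analysis. Vowels are harmonic stacks (f0 = 120 Hz) with 3 formant
#' peaks; consonants are Gaussian band-limited noise bursts with centres
#' spread over 0.35-7.6 kHz.
#'
#' @return named list of `PhonemeTemplate` objects.
#' @export
defaultPhonemeInventory <- function() {
  vdef <- list(
    aa = c(730, 1090, 2440), iy = c(270, 2290, 3010), uw = c(300, 870, 2240),
    eh = c(530, 1840, 2480), ae = c(660, 1720, 2410), ao = c(570, 840, 2410),
    ih = c(390, 1990, 2550), ah = c(640, 1190, 2390))
  cdef <- list(
    m = c(350, 250), b = c(550, 350), p = c(800, 450), d = c(1150, 600),
    g = c(1600, 750), n = c(2200, 900), k = c(3000, 1100), t = c(3900, 1300),
    ch = c(4900, 1500), sh = c(5900, 1600), f = c(6800, 1700), s = c(7500, 1800))
  inv <- c(
    lapply(names(vdef), function(l)
      phonemeTemplate(l, "vowel", 0.12, formants = vdef[[l]],
                      formant_amps = c(1, 0.6, 0.3))),
    lapply(names(cdef), function(l)
      phonemeTemplate(l, "consonant", 0.08, band = cdef[[l]])))
  stats::setNames(inv, c(names(vdef), names(cdef)))
}

#' Vowel/consonant class map of an inventory
#' @param inventory list of `PhonemeTemplate`s.
#' @return named character vector over phoneme labels.
#' @export
inventoryClassMap <- function(inventory = defaultPhonemeInventory()) {
  vapply(inventory, function(t) t$klass, character(1))
}

#' Number of admissible class-alternating words
#' @keywords internal
vocabularyCapacity <- function(nV, nC, lengths = 2:5) {
  sum(vapply(lengths, function(L) {
    sv <- nV^ceiling(L / 2) * nC^floor(L / 2)   # starts with vowel
    sc <- nC^ceiling(L / 2) * nV^floor(L / 2)   # starts with consonant
    if (nV == 0) sv <- 0
    if (nC == 0) sc <- 0
    # words must contain >= 1 vowel: consonant-initial length-1 would fail,
    # but lengths >= 2 alternating always include a vowel when nV > 0
    sv + sc
  }, numeric(1)))
}

#' Build a random pronounceable vocabulary
#'
#' Draws `n_words` distinct words of 2-5 phonemes with strictly
#' alternating vowel/consonant classes (hence at least one vowel each).
#' Word strings are the concatenated phoneme labels separated by nothing;
#' token ids are contiguous from 0 with PAD = 0, SOS = 1, EOS = 2.
#'
#' @param n_words number of words (>= 2).
#' @param inventory list of `PhonemeTemplate`s with both classes present.
#' @param seed RNG seed.
#' @return a [Vocabulary-class].
#' @export
buildVocabulary <- function(n_words, inventory = defaultPhonemeInventory(),
                            seed = 1L) {
  assertThat(n_words >= 2, "n_words must be >= 2")
  cls <- inventoryClassMap(inventory)
  vow <- names(cls)[cls == "vowel"]
  con <- names(cls)[cls == "consonant"]
  if (length(vow) < 1 || length(con) < 1)
    stop("inventory must contain at least one vowel and one consonant",
         call. = FALSE)
  cap <- vocabularyCapacity(length(vow), length(con))
  if (n_words > cap)
    stop("n_words (", n_words, ") exceeds the number of admissible words (",
         cap, ") for this inventory", call. = FALSE)
  withSeed(deriveSeed(seed, "vocabulary"), {
    seqs <- list(); seen <- character(0)
    while (length(seqs) < n_words) {
      L <- sample(2:5, 1L)
      first <- sample(c("vowel", "consonant"), 1L)
      classes <- rep(c(first, setdiff(c("vowel", "consonant"), first)),
                     length.out = L)
      labs <- vapply(classes, function(k)
        if (k == "vowel") sample(vow, 1L) else sample(con, 1L), character(1))
      w <- paste(labs, collapse = "")
      if (!w %in% seen) { seen <- c(seen, w); seqs <- c(seqs, list(unname(labs))) }
    }
    ids <- stats::setNames(seq(0L, n_words + 2L),
                           c("<pad>", "<sos>", "<eos>", seen))
    new("Vocabulary", words = seen, phonemeSeqs = seqs, tokenIds = ids)
  })
}

#' @keywords internal
synthPhoneme <- function(tmpl, sr = 16000, seed = NULL) {
  n <- round(tmpl$duration_s * sr)
  t <- seq_len(n) / sr
  if (tmpl$klass == "vowel") {
    harm <- seq(tmpl$f0, 8000 - tmpl$f0 / 2, by = tmpl$f0)
    amps <- vowelEnvelope(tmpl, harm)
    x <- numeric(n)
    for (j in seq_along(harm))
      x <- x + amps[j] * sin(2 * pi * harm[j] * t)
  } else {
    x <- withSeed(seed, stats::rnorm(n))
    spec <- stats::fft(x)
    f <- c(seq(0, sr / 2, length.out = n %/% 2 + 1),
           seq(-sr / 2, 0, length.out = n - n %/% 2 + 1)[c(-1, -(n - n %/% 2 + 1))])
    f <- abs(f[seq_len(n)])
    gain <- exp(-0.5 * ((f - tmpl$band[1]) / (tmpl$band[2] / 2))^2)
    x <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  }
  x <- x / max(abs(x), 1e-12) * 0.3
  ramp <- min(80L, n %/% 4L)
  if (ramp > 0) {
    w <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
    x[seq_len(ramp)] <- x[seq_len(ramp)] * w
    x[(n - ramp + 1L):n] <- x[(n - ramp + 1L):n] * rev(w)
  }
  x
}

#' Synthesize an annotated utterance from a word sequence
#'
#' Concatenates the words' phoneme templates (10 ms raised-cosine
#' cross-fade ramps at segment joins, applied inside each segment so
#' nominal durations tile exactly), inserts 0.4 s of leading and trailing
#' silence and a short 120 ms inter-word gap, and records exact half-open
#' `[start, end)` word and phoneme sample intervals.
#'
#' @param word_seq character vector of words, all present in `vocab`.
#' @param vocab a [Vocabulary-class].
#' @param inventory phoneme inventory backing `vocab`.
#' @param sample_rate audio sample rate (16000).
#' @param seed RNG seed (noise-burst consonants are seeded per segment).
#' @param id utterance identifier.
#' @param word_gap_s inter-word silence in seconds.
#' @return an [AnnotatedUtterance-class].
#' @export
synthesizeUtterance <- function(word_seq, vocab,
                                inventory = defaultPhonemeInventory(),
                                sample_rate = 16000, seed = 1L,
                                id = "utt", word_gap_s = 0.12) {
  spell <- phonemeSpelling(vocab)
  unknown <- setdiff(word_seq, names(spell))
  if (length(unknown) > 0)
    stop("unknown word(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sil <- round(0.4 * sample_rate)
  gap <- round(word_gap_s * sample_rate)
  pieces <- list(numeric(sil))
  words <- phon <- list()
  pos <- sil   # 0-based next sample index
  for (wi in seq_along(word_seq)) {
    if (wi > 1L) { pieces <- c(pieces, list(numeric(gap))); pos <- pos + gap }
    labs <- spell[[word_seq[wi]]]
    wstart <- pos
    for (pi in seq_along(labs)) {
      tmpl <- inventory[[labs[pi]]]
      if (is.null(tmpl)) stop("phoneme label '", labs[pi],
                              "' not in inventory", call. = FALSE)
      pseed <- deriveSeed(seed, paste0("ph", wi, "_", pi, "_", labs[pi]))
      x <- synthPhoneme(tmpl, sample_rate, pseed)
      pieces <- c(pieces, list(x))
      phon <- c(phon, list(data.frame(start = pos, end = pos + length(x),
                                      label = labs[pi])))
      pos <- pos + length(x)
    }
    words <- c(words, list(data.frame(start = wstart, end = pos,
                                      label = word_seq[wi])))
  }
  pieces <- c(pieces, list(numeric(sil)))
  wave <- unlist(pieces, use.names = FALSE)
  emptyAnn <- data.frame(start = integer(0), end = integer(0),
                         label = character(0))
  new("AnnotatedUtterance", wave = wave, sampleRate = sample_rate,
      words = if (length(words)) do.call(rbind, words) else emptyAnn,
      phonemes = if (length(phon)) do.call(rbind, phon) else emptyAnn,
      id = id)
}

#' Construct a forward encoding model of speech-responsive cortex
#'
#' Responsive channels receive a smooth random spectral tuning curve (a
#' Gaussian bump over mel bands plus a weaker secondary bump); responses
#' are delayed by a per-channel latency (uniform over `latency_range`
#' frames, i.e. 40-120 ms at 50 Hz by default) and convolved with a causal
#' gamma-shaped lag kernel (shape 2, scale 2 frames). Non-responsive
#' channels have all-zero weights and carry pure noise.
#'
#' @param n_channels total channel count.
#' @param n_responsive number of speech-responsive channels.
#' @param n_mels mel bands of the driving spectrogram.
#' @param noise_sd Gaussian noise SD in units of the unit-variance clean
#'   response (so channel SNR = 1 / noise_sd^2).
#' @param latency_range integer frame-lag range.
#' @param lag_shape,lag_scale gamma lag-kernel parameters in frames.
#' @param seed RNG seed.
#' @return an [EncodingModel-class].
#' @export
makeEncodingModel <- function(n_channels = 64L, n_responsive = 40L,
                              n_mels = 80L, noise_sd = 1,
                              latency_range = c(2L, 6L),
                              lag_shape = 2, lag_scale = 2, seed = 1L) {
  assertThat(n_channels >= 1, "need at least one channel")
  assertThat(n_responsive <= n_channels, "n_responsive exceeds n_channels")
  withSeed(deriveSeed(seed, "encoding"), {
    W <- matrix(0, n_channels, n_mels)
    resp <- rep(FALSE, n_channels)
    resp[sample.int(n_channels, n_responsive)] <- TRUE
    bands <- seq_len(n_mels)
    for (c in which(resp)) {
      c1 <- stats::runif(1, 1, n_mels)
      c2 <- stats::runif(1, 1, n_mels)
      w1 <- stats::runif(1, 4, 10)
      W[c, ] <- exp(-0.5 * ((bands - c1) / w1)^2) +
        0.4 * exp(-0.5 * ((bands - c2) / w1)^2)
    }
    lat <- as.integer(round(stats::runif(n_channels, latency_range[1],
                                         latency_range[2])))
    kmax <- 12L
    k <- (seq_len(kmax) - 1)^(lag_shape - 1) * exp(-(seq_len(kmax) - 1) / lag_scale)
    k[1] <- if (lag_shape > 1) 0 else k[1]
    k <- k / sum(k)
    new("EncodingModel", weights = W, lagKernel = k, latency = lat,
        noiseSd = noise_sd, responsiveMask = resp)
  })
}

#' Simulate a high-gamma recording for one utterance
#'
#' Each channel's clean response is the model-weighted log-mel energy,
#' shifted by the channel latency, convolved with the causal lag kernel and
#' standardized to unit variance; Gaussian noise with SD `noiseSd` is added
#' and the result is block z-scored (one block per utterance). Channels
#' with zero clean response (all-zero weights) carry z-scored noise, or
#' exact zeros when `noiseSd = 0` (the constant-block guard).
#'
#' @param utterance an [AnnotatedUtterance-class].
#' @param model an [EncodingModel-class].
#' @param frame_rate neural frame rate (50 Hz).
#' @param seed RNG seed for the noise draw.
#' @param return_clean if `TRUE`, attach the pre-noise clean matrix as
#'   attribute `"clean"` for diagnostics.
#' @return a [NeuralRecording-class], channels x frames with
#'   `frames = round(duration * frame_rate)`.
#' @export
simulateNeural <- function(utterance, model, frame_rate = 50, seed = 1L,
                           return_clean = FALSE) {
  nCh <- nrow(model@weights)
  assertThat(nCh >= 1, "model must have at least one channel")
  mel <- melValues(melSpectrogram(utterance))
  nFrames <- round(length(waveform(utterance)) / sampleRate(utterance) *
                   frame_rate)
  if (nrow(mel) < nFrames)
    mel <- rbind(mel, matrix(log(MEL_FLOOR), nFrames - nrow(mel), ncol(mel)))
  mel <- mel[seq_len(nFrames), , drop = FALSE]
  drive <- mel %*% t(model@weights)          # frames x channels
  clean <- matrix(0, nCh, nFrames)
  klen <- length(model@lagKernel)
  for (c in seq_len(nCh)) {
    if (!model@responsiveMask[c]) next
    lagged <- c(rep(drive[1L, c], model@latency[c]),
                drive[seq_len(nFrames - model@latency[c]), c])
    v <- stats::filter(lagged, model@lagKernel, method = "convolution",
                       sides = 1L)
    v[seq_len(klen - 1L)] <- v[klen]
    s <- stats::sd(v)
    clean[c, ] <- if (s > 1e-12) (v - mean(v)) / s else 0
  }
  hg <- withSeed(deriveSeed(seed, paste0("neural_", utterance@id)), {
    clean + model@noiseSd * matrix(stats::rnorm(nCh * nFrames), nCh, nFrames)
  })
  hg <- zscoreMatrixBlocks(hg, 1L)
  rec <- new("NeuralRecording", hg = hg, frameRate = frame_rate,
             blockStarts = 1L, channelIds = seq_len(nCh))
  if (return_clean) attr(rec, "clean") <- clean
  rec
}

#' Default simulated-study configuration
#'
#' The reference conditions of the synthetic study: 200 sentences of 3-6
#' words from a 50-word vocabulary, 64 channels of which 40 are
#' speech-responsive, encoding noise SD 0.5, and a random sentence-level
#' 70/20/10 train/validation/test split.
#'
#' @param ... named overrides of any configuration field.
#' @return configuration list for [makeDataset()].
#' @export
defaultDatasetConfig <- function(...) {
  cfg <- list(n_sentences = 200L, words_range = c(3L, 6L), n_words = 50L,
              n_channels = 64L, n_responsive = 40L, noise_sd = 0.5,
              split = c(train = 0.7, val = 0.2, test = 0.1),
              frame_rate = 50, sample_rate = 16000, word_gap_s = 0.12,
              latency_range = c(2L, 6L), lag_shape = 2, lag_scale = 2)
  o <- list(...)
  assertThat(all(names(o) %in% names(cfg)),
             paste("unknown config field:",
                   paste(setdiff(names(o), names(cfg)), collapse = ", ")))
  utils::modifyList(cfg, o)
}

#' High-SNR, linearly separable study configuration
#'
#' The clean regime used to probe linguistic decodability: the same
#' 50-word vocabulary, 400 sentences (roughly the 20 minutes of paired
#' data the framework targets) and encoding noise SD 0.1.
#'
#' @param ... named overrides.
#' @return configuration list for [makeDataset()].
#' @export
separableDatasetConfig <- function(...) {
  do.call(defaultDatasetConfig,
          utils::modifyList(list(n_sentences = 400L, noise_sd = 0.1),
                            list(...)))
}

#' Generate a paired speech/neural dataset
#'
#' Builds the vocabulary and encoding model, synthesizes `n_sentences`
#' random sentences, simulates their neural recordings, and assigns a
#' sentence-level random split at the configured fractions (sizes are
#' deterministic: `round(fraction * n)`, remainder to test). Regeneration
#' with the same config and seed is bit-identical.
#'
#' @param config see [defaultDatasetConfig()].
#' @param seed master RNG seed.
#' @param inventory phoneme inventory.
#' @return a [SyntheticDataset-class].
#' @export
makeDataset <- function(config = defaultDatasetConfig(), seed = 1L,
                        inventory = defaultPhonemeInventory()) {
  f <- config$split
  assertThat(abs(sum(f) - 1) <= 1e-9, "split fractions must sum to 1")
  vocab <- buildVocabulary(config$n_words, inventory,
                           seed = deriveSeed(seed, "vocab"))
  model <- makeEncodingModel(config$n_channels, config$n_responsive,
                             noise_sd = config$noise_sd,
                             latency_range = config$latency_range,
                             lag_shape = config$lag_shape,
                             lag_scale = config$lag_scale,
                             seed = deriveSeed(seed, "model"))
  n <- config$n_sentences
  utts <- vector("list", n)
  neural <- vector("list", n)
  for (i in seq_len(n)) {
    si <- deriveSeed(seed, paste0("sent", i))
    ws <- withSeed(si, {
      k <- sample(seq(config$words_range[1], config$words_range[2]), 1L)
      sample(vocabWords(vocab), k, replace = TRUE)
    })
    utts[[i]] <- synthesizeUtterance(ws, vocab, inventory,
                                     config$sample_rate, seed = si,
                                     id = sprintf("utt%03d", i),
                                     word_gap_s = config$word_gap_s)
    neural[[i]] <- simulateNeural(utts[[i]], model, config$frame_rate,
                                  seed = si)
  }
  nTrain <- round(f[["train"]] * n)
  nVal <- round(f[["val"]] * n)
  nTest <- n - nTrain - nVal
  if (nVal == 0 || nTest == 0)
    warning("empty validation or test split")
  lab <- rep(c("train", "val", "test"), c(nTrain, nVal, nTest))
  split <- withSeed(deriveSeed(seed, "split"), lab[order(sample.int(n))])
  new("SyntheticDataset", utterances = utts, neural = neural, split = split,
      vocab = vocab, model = model, seed = as.integer(seed),
      config = config)
}

#' Word sequences of every trial
#' @param dataset a [SyntheticDataset-class].
#' @return list of character vectors.
#' @export
datasetWordSequences <- function(dataset) {
  lapply(trialUtterances(dataset), function(u) wordIntervals(u)$label)
}

#' Indices of one split
#' @param dataset a [SyntheticDataset-class].
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return integer trial indices.
#' @export
splitIndices <- function(dataset, split) {
  which(splitLabels(dataset) == split)
}
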