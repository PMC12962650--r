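## Quantitative evaluation: edit-distance alignment, WER/PER, phoneme
## confusion and class clarity, aligned mel R^2, additive-noise references
## and the Gaussian-noise-replacement causality control.

#' Minimal edit-distance alignment
#'
#' Levenshtein dynamic program with unit costs and deterministic
#' traceback preference match > substitute > delete > insert. Applying the
#' returned operations to `ref` yields `hyp`, and the distance (number of
#' substitutions + insertions + deletions) is minimal.
#'
#' @param ref,hyp character vectors of symbols (words or phonemes); empty
#'   sequences allowed.
#' @return list with `distance`, and `ops` -- a data.frame with columns
#'   `op` (`match`/`sub`/`del`/`ins`), `ref` and `hyp` symbols (`NA` where
#'   not applicable).
#' @export
editOps <- function(ref, hyp) {
  n <- length(ref); m <- length(hyp)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    cost <- as.integer(ref[i] != hyp)
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + cost[j],       # match/sub
                               D[i, j + 1L] + 1L,        # delete ref[i]
                               D[i + 1L, j] + 1L)        # insert hyp[j]
    }
  }
  ops <- list(); i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && D[i + 1L, j + 1L] == D[i, j] + (ref[i] != hyp[j])) {
      ops[[length(ops) + 1L]] <-
        data.frame(op = if (ref[i] == hyp[j]) "match" else "sub",
                   ref = ref[i], hyp = hyp[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      ops[[length(ops) + 1L]] <- data.frame(op = "del", ref = ref[i], hyp = NA)
      i <- i - 1L
    } else {
      ops[[length(ops) + 1L]] <- data.frame(op = "ins", ref = NA, hyp = hyp[j])
      j <- j - 1L
    }
  }
  ops <- if (length(ops))
    do.call(rbind, rev(ops))
  else data.frame(op = character(0), ref = character(0), hyp = character(0))
  list(distance = D[n + 1L, m + 1L], ops = ops)
}

#' Edit-distance error rate
#'
#' `Edit(ref, hyp) / length(ref)`; the same routine serves WER (word
#' symbols) and PER (phoneme symbols). May exceed 1 when the hypothesis
#' carries many insertions.
#'
#' @param ref non-empty reference symbol sequence.
#' @param hyp hypothesis symbol sequence.
#' @return non-negative rate.
#' @export
errorRate <- function(ref, hyp) {
  if (length(ref) == 0)
    stop("error rate undefined for an empty reference", call. = FALSE)
  editOps(ref, hyp)$distance / length(ref)
}

#' Accumulate phoneme confusions over aligned sequence pairs
#'
#' Matches and substitutions are tallied into the P x P matrix (reference
#' rows, hypothesis columns); insertions and deletions go into the
#' margins, all per the [editOps()] alignment.
#'
#' @param pairs list of `list(ref = , hyp = )` phoneme sequence pairs.
#' @param class_map named character vector mapping every symbol to
#'   `"vowel"` or `"consonant"` (see [inventoryClassMap()]).
#' @return a [ConfusionMatrix-class].
#' @export
accumulateConfusions <- function(pairs, class_map = inventoryClassMap()) {
  syms <- names(class_map)
  P <- length(syms)
  counts <- matrix(0, P, P, dimnames = list(syms, syms))
  ins <- stats::setNames(numeric(P), syms)
  del <- stats::setNames(numeric(P), syms)
  for (pr in pairs) {
    bad <- setdiff(c(pr$ref, pr$hyp), syms)
    if (length(bad) > 0)
      stop("symbol(s) not in class map: ", paste(bad, collapse = ", "),
           call. = FALSE)
    ops <- editOps(pr$ref, pr$hyp)$ops
    for (r in seq_len(nrow(ops))) {
      switch(ops$op[r],
             match = , sub = {
               counts[ops$ref[r], ops$hyp[r]] <-
                 counts[ops$ref[r], ops$hyp[r]] + 1
             },
             del = { del[ops$ref[r]] <- del[ops$ref[r]] + 1 },
             ins = { ins[ops$hyp[r]] <- ins[ops$hyp[r]] + 1 })
    }
  }
  new("ConfusionMatrix", counts = counts, insertions = ins, deletions = del,
      classMap = class_map)
}

#' Phoneme class clarity (PCC)
#'
#' Ratio of within-class to between-class substitution counts: how often a
#' misrecognized vowel is confused with another vowel (and likewise for
#' consonants) rather than crossing classes. High values mean errors are
#' phonologically plausible. Zero between-class substitutions yield `Inf`
#' (flagged, not an error); zero substitutions overall yield `NaN` with
#' attribute `flag = "undefined"`.
#'
#' @param conf a [ConfusionMatrix-class] with at least one substitution.
#' @return scalar ratio (possibly `Inf`/`NaN`, see details).
#' @export
pcc <- function(conf) {
  cm <- confusionCounts(conf)
  cls <- classMap(conf)[rownames(cm)]
  off <- cm; diag(off) <- 0
  same <- outer(cls, cls, "==")
  within <- sum(off[same])
  between <- sum(off[!same])
  if (within + between == 0)
    return(structure(NaN, flag = "undefined"))
  if (between == 0) return(structure(Inf, flag = "no-between-class-errors"))
  within / between
}

#' Chance level of the phoneme class clarity
#'
#' Expected within/between substitution ratio when each substituted
#' reference phoneme is replaced uniformly at random by one of the other
#' P - 1 symbols, weighted by the observed per-reference-symbol error
#' counts: `sum_r e_r (n_class(r) - 1) / sum_r e_r (P - n_class(r))`.
#'
#' @param x a [ConfusionMatrix-class] (error counts taken from its
#'   off-diagonal row sums), or a named class map as from
#'   [inventoryClassMap()].
#' @param error_counts named per-reference-symbol substitution counts;
#'   required when `x` is a class map, defaults to uniform if missing
#'   there.
#' @return scalar chance PCC.
#' @export
chancePcc <- function(x, error_counts = NULL) {
  if (is(x, "ConfusionMatrix")) {
    cm <- confusionCounts(x)
    cls <- classMap(x)[rownames(cm)]
    off <- cm; diag(off) <- 0
    if (is.null(error_counts)) error_counts <- rowSums(off)
  } else {
    cls <- x
    if (is.null(error_counts))
      error_counts <- stats::setNames(rep(1, length(cls)), names(cls))
  }
  if (length(unique(cls)) < 2)
    stop("chance PCC undefined for a single-class inventory", call. = FALSE)
  P <- length(cls)
  nClass <- table(cls)
  e <- error_counts[names(cls)]
  e[is.na(e)] <- 0
  within <- sum(e * (nClass[cls] - 1))
  between <- sum(e * (P - nClass[cls]))
  as.numeric(within / between)
}

#' @keywords internal
sliceResample <- function(mel, from, to, outFrames) {
  # half-open frame slice [from, to) resampled to outFrames rows
  idx <- seq(from, to - 1L)
  seg <- mel[idx, , drop = FALSE]
  if (nrow(seg) == outFrames) return(seg)
  if (nrow(seg) == 1L) return(seg[rep(1L, outFrames), , drop = FALSE])
  at <- seq(1, nrow(seg), length.out = outFrames)
  apply(seg, 2L, function(col) stats::approx(seq_along(col), col, at)$y)
}

#' Aligned mel-spectrogram R-squared
#'
#' Word-by-word temporal alignment followed by the squared Pearson
#' correlation between log-mel spectrograms. For every reference word
#' interval the corresponding hypothesis span is located (the hypothesis'
#' own word annotations when it is an [AnnotatedUtterance-class], else
#' proportional mapping of the reference boundaries), linearly resampled
#' to the reference segment's frame count, and the voiced segments are
#' concatenated and flattened before correlating -- silent and non-speech
#' regions are excluded.
#'
#' @param ref an [AnnotatedUtterance-class] with word intervals.
#' @param hyp waveform, [AnnotatedUtterance-class], [MelSpectrogram-class]
#'   or mel matrix (frames aligned proportionally to `ref`).
#' @param word_subset optional integer indices of reference words to score
#'   (used by the noise-replacement control).
#' @return squared Pearson correlation in [0, 1]; `NaN` with attribute
#'   `flag` when no voiced segments exist.
#' @export
alignedMelR2 <- function(ref, hyp, word_subset = NULL) {
  w <- wordIntervals(ref)
  if (!is.null(word_subset)) w <- w[word_subset, , drop = FALSE]
  if (nrow(w) == 0) return(structure(NaN, flag = "no-voiced-segments"))
  melR <- melValues(melSpectrogram(ref))
  hypAnn <- NULL
  if (is(hyp, "AnnotatedUtterance")) {
    hypAnn <- wordIntervals(hyp)
    if (!is.null(word_subset) && nrow(hypAnn) >= max(word_subset))
      hypAnn <- hypAnn[word_subset, , drop = FALSE]
    melH <- melValues(melSpectrogram(hyp))
    srH <- sampleRate(hyp)
  } else {
    melH <- asMelMatrix(hyp)
    srH <- 16000
  }
  nR <- nrow(melR); nH <- nrow(melH)
  srR <- sampleRate(ref)
  refSeg <- hypSeg <- list()
  for (k in seq_len(nrow(w))) {
    f1 <- max(1L, floor(w$start[k] / srR * 50) + 1L)
    f2 <- min(nR + 1L, floor(w$end[k] / srR * 50) + 1L)
    if (f2 - f1 < 1L) next
    if (!is.null(hypAnn) && nrow(hypAnn) == nrow(w)) {
      h1 <- max(1L, floor(hypAnn$start[k] / srH * 50) + 1L)
      h2 <- min(nH + 1L, floor(hypAnn$end[k] / srH * 50) + 1L)
    } else {
      h1 <- max(1L, floor((f1 - 1L) / nR * nH) + 1L)
      h2 <- min(nH + 1L, floor((f2 - 1L) / nR * nH) + 1L)
    }
    if (h2 - h1 < 1L) next
    refSeg[[length(refSeg) + 1L]] <- melR[f1:(f2 - 1L), , drop = FALSE]
    hypSeg[[length(hypSeg) + 1L]] <- sliceResample(melH, h1, h2, f2 - f1)
  }
  if (length(refSeg) == 0) return(structure(NaN, flag = "no-voiced-segments"))
  a <- as.numeric(do.call(rbind, refSeg))
  b <- as.numeric(do.call(rbind, hypSeg))
  safeCor(a, b)^2
}

#' Toy template-matching speech recognizer
#'
#' Deterministic stand-in for a large ASR model on the synthetic
#' vocabulary: every mel frame is assigned to the nearest phoneme template
#' (cosine similarity of linear mel energies against the templates'
#' spectral profiles, with a silence template), runs are collapsed
#' (minimum run length 2 frames), word segments are split at silence runs,
#' and each segment is mapped to the vocabulary word with the smallest
#' phoneme edit distance.
#'
#' @param x waveform or [AnnotatedUtterance-class].
#' @param vocab a [Vocabulary-class].
#' @param inventory phoneme inventory backing `vocab`.
#' @param silence_gap minimum silence run (frames) splitting words.
#' @return list with `words` (recognized word strings) and `phonemes`
#'   (the collapsed frame-level phoneme sequence).
#' @export
toyRecognize <- function(x, vocab, inventory = defaultPhonemeInventory(),
                         silence_gap = 2L) {
  mel <- melValues(melSpectrogram(x))
  lin <- exp(mel)
  profs <- vapply(inventory, function(t) t$spectral_profile,
                  numeric(ncol(mel)))
  profs <- sweep(profs, 2L, sqrt(colSums(profs^2)), "/")
  energy <- rowMeans(mel)
  # adaptive silence threshold: noise floors shift with added noise, so
  # anchor on the utterance's own energy range rather than the log floor
  lo <- min(energy)
  hi <- stats::quantile(energy, 0.95, names = FALSE)
  silent <- energy < max(lo + 0.3 * (hi - lo), log(MEL_FLOOR) + 0.75)
  lab <- rep(NA_character_, nrow(mel))
  voiced <- which(!silent)
  if (length(voiced) > 0) {
    V <- lin[voiced, , drop = FALSE]
    V <- V / pmax(sqrt(rowSums(V^2)), 1e-12)
    sim <- V %*% profs
    lab[voiced] <- colnames(sim)[max.col(sim, ties.method = "first")]
  }
  lab[silent] <- "<sil>"
  r <- rle(lab)
  keep <- r$lengths >= 2L | r$values == "<sil>"
  runs <- data.frame(value = r$values[keep], len = r$lengths[keep])
  # split into word segments at silence runs of at least silence_gap
  segs <- list(); cur <- character(0)
  for (i in seq_len(nrow(runs))) {
    if (runs$value[i] == "<sil>" && runs$len[i] >= silence_gap) {
      if (length(cur)) { segs <- c(segs, list(cur)); cur <- character(0) }
    } else if (runs$value[i] != "<sil>") {
      cur <- c(cur, runs$value[i])
    }
  }
  if (length(cur)) segs <- c(segs, list(cur))
  spell <- phonemeSpelling(vocab)
  words <- vapply(segs, function(ph) {
    d <- vapply(spell, function(s) editOps(s, ph)$distance, numeric(1))
    names(spell)[which.min(d)]
  }, character(1))
  list(words = as.character(words),
       phonemes = unlist(segs, use.names = FALSE) %||% character(0))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian-noise replacement causality control
#'
#' Replaces the designated span of the neural input (first half, second
#' half, or all frames) with standard Gaussian noise, re-decodes the mel
#' spectrogram with the trained acoustic adaptor, and scores the aligned
#' mel R^2 separately over the reference words whose midpoints fall in
#' each temporal half. A reconstruction that is causally driven by the
#' neural input loses fidelity exactly over the corrupted span.
#'
#' @param adaptor trained acoustic adaptor (see [trainAcoustic()]).
#' @param neural channels x frames matrix (selected channels) or a
#'   [NeuralRecording-class].
#' @param reference the [AnnotatedUtterance-class] the recording encodes.
#' @param mode `"first_half"`, `"second_half"`, or `"all"`.
#' @param seed RNG seed for the replacement noise.
#' @return named numeric: R^2 over first-half and second-half words.
#' @export
noiseReplacementControl <- function(adaptor, neural, reference,
                                    mode = c("first_half", "second_half", "all"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  X <- if (is(neural, "NeuralRecording")) hgMatrix(neural) else neural
  Tn <- ncol(X)
  span <- switch(mode,
                 first_half = seq_len(floor(Tn / 2)),
                 second_half = (floor(Tn / 2) + 1L):Tn,
                 all = seq_len(Tn))
  X[, span] <- withSeed(deriveSeed(seed, "noise-replacement"),
                        stats::rnorm(nrow(X) * length(span)))
  pm <- predictMel(adaptor, X)
  w <- wordIntervals(reference)
  mid <- (w$start + w$end) / 2 / sampleRate(reference) * 50
  firstWords <- which(mid < Tn / 2)
  secondWords <- which(mid >= Tn / 2)
  r2 <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    as.numeric(alignedMelR2(reference, pm, word_subset = idx))
  }
  c(first_half = r2(firstWords), second_half = r2(secondWords))
}

#' Additive-noise reference curve
#'
#' Each original utterance is corrupted with white noise at the requested
#' SNR levels and scored against itself, yielding the reference lines
#' against which decoded speech is compared (R^2 via [alignedMelR2()], WER
#' and PER via [toyRecognize()]).
#'
#' @param utterances list of [AnnotatedUtterance-class] objects.
#' @param snr_levels numeric dB levels.
#' @param metric one of `"mel_r2"`, `"wer"`, `"per"`.
#' @param vocab,inventory vocabulary for the recognizer metrics.
#' @param seed RNG seed.
#' @return named numeric vector, mean metric per SNR level.
#' @export
noiseReferenceCurve <- function(utterances, snr_levels = c(-10, -5, 0),
                                metric = c("mel_r2", "wer", "per"),
                                vocab = NULL,
                                inventory = defaultPhonemeInventory(),
                                seed = 1L) {
  metric <- match.arg(metric)
  if (metric %in% c("wer", "per"))
    assertThat(!is.null(vocab), "vocab required for wer/per metrics")
  out <- stats::setNames(numeric(length(snr_levels)),
                         paste0(snr_levels, "dB"))
  for (li in seq_along(snr_levels)) {
    vals <- vapply(seq_along(utterances), function(i) {
      u <- utterances[[i]]
      # one noise draw per utterance, rescaled across levels, so each
      # utterance's curve is monotone by construction
      noisy <- addNoiseAtSnr(waveform(u), snr_levels[li],
                             seed = deriveSeed(seed, paste0("nrc_", i)))
      if (metric == "mel_r2") return(as.numeric(alignedMelR2(u, noisy)))
      rec <- toyRecognize(noisy, vocab, inventory)
      if (metric == "wer") errorRate(wordIntervals(u)$label, rec$words)
      else errorRate(phonemeIntervals(u)$label, rec$phonemes)
    }, numeric(1))
    out[li] <- mean(vals, na.rm = TRUE)
  }
  out
}

#' Evaluate decoded outputs against references
#'
#' Per-trial aligned mel R^2, WER and PER, pooled phoneme confusion
#' matrix, PCC with its chance level, and mean +/- standard error
#' (sd / sqrt(n) across trials; `NA` for a single trial).
#'
#' @param outputs list of decoded waveforms / utterances / mel matrices.
#' @param references list of reference [AnnotatedUtterance-class] objects.
#' @param vocab a [Vocabulary-class] for the recognizer.
#' @param inventory phoneme inventory.
#' @param decoded_words optional list of decoded word sequences (from the
#'   linguistic pathway) to score WER directly instead of recognizing
#'   `outputs`.
#' @return an [EvalReport-class].
#' @export
evaluateDataset <- function(outputs, references, vocab,
                            inventory = defaultPhonemeInventory(),
                            decoded_words = NULL) {
  assertThat(length(outputs) == length(references),
             "outputs and references must align")
  n <- length(outputs)
  r2 <- wer <- per <- numeric(n)
  pairs <- list()
  for (i in seq_len(n)) {
    ref <- references[[i]]
    r2[i] <- as.numeric(alignedMelR2(ref, outputs[[i]]))
    hyp <- if (is.matrix(outputs[[i]]) || is(outputs[[i]], "MelSpectrogram"))
      NULL else outputs[[i]]
    rec <- if (is.null(hyp)) NULL else toyRecognize(hyp, vocab, inventory)
    hypWords <- if (!is.null(decoded_words)) decoded_words[[i]]
      else if (!is.null(rec)) rec$words else character(0)
    hypPhon <- if (!is.null(rec)) rec$phonemes
      else unlist(phonemeSpelling(vocab)[hypWords], use.names = FALSE) %||%
        character(0)
    wer[i] <- errorRate(wordIntervals(ref)$label, hypWords)
    per[i] <- errorRate(phonemeIntervals(ref)$label, hypPhon)
    pairs[[i]] <- list(ref = phonemeIntervals(ref)$label, hyp = hypPhon)
  }
  conf <- accumulateConfusions(pairs, inventoryClassMap(inventory))
  pccVal <- suppressWarnings(as.numeric(pcc(conf)))
  chance <- tryCatch(chancePcc(conf), error = function(e) NA_real_)
  perTrial <- data.frame(trial = seq_len(n), mel_r2 = r2, wer = wer,
                         per = per)
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  summ <- data.frame(metric = c("mel_r2", "wer", "per"),
                     mean = c(mean(r2, na.rm = TRUE), mean(wer), mean(per)),
                     se = c(se(r2[!is.na(r2)]), se(wer), se(per)),
                     n = n)
  new("EvalReport", perTrial = perTrial, summary = summ, confusion = conf,
      pcc = c(pcc = pccVal, chance = chance))
}

#' Write an evaluation report as TSV + JSON
#'
#' @param report an [EvalReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "per_trial.tsv")
  utils::write.table(perTrialMetrics(report), tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(summary = reportSummary(report),
                            pcc = as.list(report@pcc)),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
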