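## Raw voltage -> z-scored high-gamma at 50 Hz, and sentence onset location.

#' RawRecording: wideband voltage traces
#'
#' @slot traces channels x samples voltage matrix.
#' @slot sampleRate sampling rate in Hz.
#' @slot blockBoundaries 1-based sample indices where recording blocks
#'   begin (first element 1).
#' @exportClass RawRecording
setClass("RawRecording",
  representation(traces = "matrix", sampleRate = "numeric",
                 blockBoundaries = "integer"))

setValidity("RawRecording", function(object) {
  if (object@sampleRate <= 0) return("sampleRate must be positive")
  b <- object@blockBoundaries
  if (length(b) < 1 || b[1] != 1L) return("blockBoundaries must start at 1")
  if (is.unsorted(b, strictly = TRUE)) return("blockBoundaries must be sorted")
  if (max(b) > ncol(object@traces)) return("blockBoundaries out of range")
  TRUE
})

#' Construct a RawRecording
#' @param traces channels x samples matrix.
#' @param sample_rate Hz.
#' @param block_boundaries 1-based sample indices of block starts.
#' @return a [RawRecording-class].
#' @export
rawRecording <- function(traces, sample_rate, block_boundaries = 1L) {
  new("RawRecording", traces = as.matrix(traces),
      sampleRate = sample_rate,
      blockBoundaries = as.integer(block_boundaries))
}

#' Z-score a matrix per channel per block (constant-block guard)
#' @keywords internal
zscoreMatrixBlocks <- function(m, starts) {
  nFr <- ncol(m)
  ends <- c(starts[-1] - 1L, nFr)
  for (b in seq_along(starts)) {
    idx <- starts[b]:ends[b]
    sub <- m[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, stats::sd)
    z <- (sub - mu) / ifelse(sdv < 1e-12, 1, sdv)
    z[sdv < 1e-12, ] <- 0
    m[, idx] <- z
  }
  m
}

#' Block-wise z-scoring
#'
#' Per channel and per recording block, centre to mean 0 and scale to
#' standard deviation 1; blocks that are constant within floating point
#' (sd below 1e-12) map to zeros. Idempotent.
#'
#' @param hg channels x frames matrix, or a [NeuralRecording-class].
#' @param boundaries 1-based frame indices of block starts (ignored for a
#'   `NeuralRecording`, which carries its own).
#' @return object of the same kind as `hg`.
#' @export
zscoreBlocks <- function(hg, boundaries = 1L) {
  if (is(hg, "NeuralRecording")) {
    hg@hg <- zscoreMatrixBlocks(hg@hg, blockStarts(hg))
    return(hg)
  }
  starts <- as.integer(boundaries)
  assertThat(starts[1] == 1L && !is.unsorted(starts, strictly = TRUE) &&
             max(starts) <= ncol(hg), "invalid block boundaries")
  zscoreMatrixBlocks(hg, starts)
}

#' Extract the z-scored high-gamma envelope at 50 Hz
#'
#' Per channel: the analytic amplitude (FFT-based Hilbert transform) of
#' each of `n_filters` Gaussian bandpass filters with centre frequencies
#' log-spaced over `band`, averaged across filters, polyphase-resampled to
#' `target_rate`, then block z-scored. The Gaussian filters have standard
#' deviation 0.195 x centre frequency (bandwidth 0.39 x centre).
#'
#' @param raw a [RawRecording-class].
#' @param band high-gamma band limits in Hz.
#' @param n_filters number of Gaussian sub-band filters.
#' @param target_rate output frame rate in Hz.
#' @return a [NeuralRecording-class] with
#'   `floor(samples * target_rate / sample_rate)` frames.
#' @export
extractHighGamma <- function(raw, band = c(70, 150), n_filters = 8L,
                             target_rate = 50) {
  sr <- raw@sampleRate
  if (sr <= 2 * band[2])
    stop("sample rate ", sr, " Hz undersamples the ", band[1], "-", band[2],
         " Hz band", call. = FALSE)
  n <- ncol(raw@traces)
  nCh <- nrow(raw@traces)
  nFrames <- floor(n * target_rate / sr)
  centers <- exp(seq(log(band[1]), log(band[2]), length.out = n_filters))
  freqs <- (seq_len(n) - 1) / n * sr
  freqs <- ifelse(freqs > sr / 2, freqs - sr, freqs)
  analytic <- ifelse(freqs > 0, 2, ifelse(freqs == 0, 1, 0))
  out <- matrix(0, nCh, nFrames)
  for (c in seq_len(nCh)) {
    X <- stats::fft(raw@traces[c, ])
    amp <- numeric(n)
    for (fc in centers) {
      gain <- exp(-0.5 * ((abs(freqs) - fc) / (0.195 * fc))^2)
      amp <- amp + Mod(stats::fft(X * gain * analytic, inverse = TRUE)) / n
    }
    amp <- amp / n_filters
    env <- signal::resample(amp, p = target_rate, q = sr)
    out[c, ] <- env[seq_len(nFrames)]
  }
  starts <- unique(pmin(floor((raw@blockBoundaries - 1L) * target_rate / sr) + 1L,
                        nFrames))
  out <- zscoreMatrixBlocks(out, starts)
  new("NeuralRecording", hg = out, frameRate = target_rate,
      blockStarts = as.integer(starts), channelIds = seq_len(nCh))
}

#' Detect sentence onsets preceded by silence
#'
#' A speech-initiation time qualifies as an onset when the silent gap
#' before it strictly exceeds `min_silence`. The first speech segment is
#' the boundary case: its gap is the pre-roll from the start of the
#' recording, and a pre-roll of at least `min_silence` counts (so a
#' recording opening with exactly the 0.4 s stimulus-protocol silence
#' yields an onset, while a recording starting mid-speech yields none).
#' Word annotations take precedence; otherwise a 10 ms RMS envelope is
#' thresholded at 2 percent of its maximum.
#'
#' @param x an [AnnotatedUtterance-class], or a numeric waveform.
#' @param min_silence minimum preceding silence in seconds (strict).
#' @param sr sample rate when `x` is a bare waveform.
#' @return numeric vector of onset times in seconds (possibly empty).
#' @export
detectOnsets <- function(x, min_silence = 0.4, sr = 16000) {
  if (is(x, "AnnotatedUtterance")) {
    w <- wordIntervals(x)
    if (nrow(w) > 0) {
      segs <- cbind(w$start, w$end) / sampleRate(x)
    } else return(numeric(0))
  } else {
    win <- max(1L, round(0.01 * sr))
    nw <- floor(length(x) / win)
    if (nw == 0) return(numeric(0))
    rms <- sqrt(colMeans(matrix(x[seq_len(nw * win)]^2, nrow = win)))
    on <- rms > 0.02 * max(rms)
    if (!any(on)) return(numeric(0))
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- cbind((starts[r$values] - 1L) * win, ends[r$values] * win) / sr
  }
  o <- order(segs[, 1])
  segs <- segs[o, , drop = FALSE]
  onsets <- numeric(0)
  prevEnd <- 0
  for (i in seq_len(nrow(segs))) {
    gap <- segs[i, 1] - prevEnd
    ok <- if (i == 1L) gap >= min_silence - 1e-12 else gap > min_silence
    if (ok) onsets <- c(onsets, segs[i, 1])
    prevEnd <- max(prevEnd, segs[i, 2])
  }
  onsets
}

#' Synthesize a wideband "raw mode" carrier recording
#'
#' Exercises the preprocessing chain: each channel of a 50 Hz neural
#' envelope modulates the amplitude of a channel-specific carrier tone
#' inside the 70-150 Hz band, sampled at `sample_rate`. Recovering the
#' high-gamma envelope from this recording should reproduce the generating
#' envelope.
#'
#' @param rec a [NeuralRecording-class] (the generative envelope).
#' @param sample_rate carrier sampling rate in Hz.
#' @param seed RNG seed for carrier frequencies.
#' @return a [RawRecording-class].
#' @export
simulateRawRecording <- function(rec, sample_rate = 1000, seed = 1L) {
  env <- hgMatrix(rec)
  nCh <- nrow(env)
  nFrames <- ncol(env)
  nSamp <- round(nFrames / frameRate(rec) * sample_rate)
  t <- seq_len(nSamp) / sample_rate
  carrierF <- withSeed(deriveSeed(seed, "carrier"),
                       stats::runif(nCh, 85, 135))
  frameTimes <- (seq_len(nFrames) - 0.5) / frameRate(rec)
  traces <- matrix(0, nCh, nSamp)
  for (c in seq_len(nCh)) {
    e <- env[c, ]
    e <- e - min(e) + 0.2      # positive modulation depth
    ei <- stats::approx(frameTimes, e, xout = t, rule = 2)$y
    traces[c, ] <- ei * sin(2 * pi * carrierF[c] * t)
  }
  rawRecording(traces, sample_rate,
               as.integer(round((blockStarts(rec) - 1L) / frameRate(rec) *
                                sample_rate) + 1L))
}
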