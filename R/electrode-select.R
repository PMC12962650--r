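## Speech-responsive electrode selection by paired pre/post-onset t-test.

#' Paired pre/post-onset responsiveness test
#'
#' For each channel, a paired one-sided Student t-test of the per-onset
#' mean high-gamma in the post-onset window (400-600 ms) against the
#' pre-onset window (-200-0 ms), Bonferroni corrected across channels at
#' family alpha 0.01. Windows are half-open in frames at 50 Hz: pre is
#' frames [-10, 0) and post [20, 30) relative to the onset frame. Onsets
#' whose windows leave the recording or cross a block boundary are dropped
#' (with a message); fewer than 2 usable onsets is an error.
#'
#' @param rec a [NeuralRecording-class].
#' @param onsets onset times in seconds (e.g. from [detectOnsets()]).
#' @param pre_window,post_window window limits in seconds relative to
#'   onset.
#' @param alpha family-wise alpha before Bonferroni correction.
#' @return a [ResponsivenessResult-class].
#' @export
responsivenessTest <- function(rec, onsets, pre_window = c(-0.2, 0),
                               post_window = c(0.4, 0.6), alpha = 0.01) {
  fr <- frameRate(rec)
  hg <- hgMatrix(rec)
  nFr <- ncol(hg)
  nCh <- nrow(hg)
  oFrame <- round(onsets * fr) + 1L        # 1-based onset frame
  preIdx <- function(o) (o + round(pre_window[1] * fr)):(o + round(pre_window[2] * fr) - 1L)
  postIdx <- function(o) (o + round(post_window[1] * fr)):(o + round(post_window[2] * fr) - 1L)
  blocks <- c(blockStarts(rec), nFr + 1L)
  blockOf <- function(f) findInterval(f, blocks)
  usable <- vapply(oFrame, function(o) {
    pr <- preIdx(o); po <- postIdx(o)
    all(pr >= 1L) && all(po <= nFr) &&
      blockOf(pr[1]) == blockOf(po[length(po)])
  }, logical(1))
  if (any(!usable))
    message(sum(!usable), " onset(s) dropped (windows out of bounds or ",
            "crossing a block boundary)")
  oFrame <- oFrame[usable]
  if (length(oFrame) < 2L)
    stop("fewer than 2 usable onsets; responsiveness test undefined",
         call. = FALSE)
  nOn <- length(oFrame)
  d <- matrix(0, nCh, nOn)
  for (k in seq_len(nOn)) {
    d[, k] <- rowMeans(hg[, postIdx(oFrame[k]), drop = FALSE]) -
      rowMeans(hg[, preIdx(oFrame[k]), drop = FALSE])
  }
  mu <- rowMeans(d)
  sdv <- apply(d, 1L, stats::sd)
  tstat <- ifelse(sdv < 1e-12 & abs(mu) < 1e-12, 0,
                  mu / (sdv / sqrt(nOn)))
  p <- stats::pt(tstat, df = nOn - 1L, lower.tail = FALSE)
  corr <- alpha / nCh
  new("ResponsivenessResult", statistic = as.numeric(tstat),
      pValue = as.numeric(p), alpha = alpha, correctedAlpha = corr,
      selected = !is.na(p) & p < corr, nOnsets = as.integer(nOn),
      channelIds = channelIds(rec))
}

#' Select speech-responsive channels
#'
#' Sorted ids of the channels passing the Bonferroni-corrected test.
#' Downstream decoding consumes only these rows; an empty selection is a
#' hard error because decoding is undefined without responsive channels.
#'
#' @param result a [ResponsivenessResult-class].
#' @return sorted integer channel ids.
#' @export
selectElectrodes <- function(result) {
  ids <- sort(channelIds(result)[selectedMask(result)])
  if (length(ids) == 0)
    stop("no speech-responsive electrodes selected; lower noise, add ",
         "onsets, or check onset alignment -- decoding is undefined ",
         "without responsive channels", call. = FALSE)
  ids
}
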