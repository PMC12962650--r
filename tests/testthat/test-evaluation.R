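test_that("edit alignment matches brute force on all short pairs", {
  syms <- c("a", "b", "c")
  pool <- unlist(lapply(0:3, function(L)
    if (L == 0) list(character(0))
    else apply(expand.grid(rep(list(syms), L)), 1,
               function(r) as.character(r), simplify = FALSE)),
    recursive = FALSE)
  for (ref in pool) for (hyp in pool) {
    eo <- editOps(ref, hyp)
    expect_equal(eo$distance, bruteEditDistance(ref, hyp))
    # ops reconstruct hyp from ref
    out <- character(0)
    for (r in seq_len(nrow(eo$ops))) {
      op <- eo$ops[r, ]
      if (op$op %in% c("match", "sub")) out <- c(out, op$hyp)
      if (op$op == "ins") out <- c(out, op$hyp)
    }
    expect_identical(out, hyp)
    expect_equal(sum(eo$ops$op %in% c("sub", "ins", "del")), eo$distance)
  }
})

test_that("edit alignment prefers match/substitution in traceback", {
  eo <- editOps(c("a", "b", "c"), c("a", "x", "c"))
  expect_equal(eo$distance, 1)
  expect_identical(eo$ops$op, c("match", "sub", "match"))
  expect_identical(eo$ops$hyp[2], "x")
})

test_that("error rate divides by reference length and may exceed 1", {
  expect_equal(errorRate(c("w1", "w2"), c("w1", "w2")), 0)
  expect_equal(errorRate(c("a", "b", "c"), c("a", "c")), 1 / 3)
  expect_equal(errorRate("a", c("b", "c")), 2)
  expect_error(errorRate(character(0), "a"), "empty reference")
})

test_that("confusion accumulation conserves operation counts", {
  cm <- c(a = "vowel", b = "consonant", c = "consonant")
  pairs <- list(list(ref = c("a", "b"), hyp = c("a", "c")),
                list(ref = c("a", "b", "c"), hyp = c("a", "b", "c", "b")),
                list(ref = c("c", "c"), hyp = "c"))
  conf <- accumulateConfusions(pairs, cm)
  counts <- confusionCounts(conf)
  m <- confusionMargins(conf)
  expect_equal(counts["a", "a"], 2)
  expect_equal(counts["b", "c"], 1)
  expect_equal(sum(m$insertions), 1)
  expect_equal(sum(m$deletions), 1)
  # conservation: total tallied ops equal summed alignment lengths
  total <- sum(counts) + sum(m$insertions) + sum(m$deletions)
  expected <- sum(vapply(pairs, function(p)
    nrow(editOps(p$ref, p$hyp)$ops), numeric(1)))
  expect_equal(total, expected)
  expect_error(accumulateConfusions(list(list(ref = "z", hyp = "a")), cm),
               "not in class map")
  # all-correct corpus: diagonal only
  confOk <- accumulateConfusions(list(list(ref = c("a", "b"),
                                           hyp = c("a", "b"))), cm)
  expect_equal(sum(confusionCounts(confOk)) -
                 sum(diag(confusionCounts(confOk))), 0)
})

test_that("pcc is the within/between substitution ratio with flagged edges", {
  cm <- c(v1 = "vowel", v2 = "vowel", c1 = "consonant", c2 = "consonant")
  counts <- matrix(0, 4, 4, dimnames = list(names(cm), names(cm)))
  counts["v1", "v2"] <- 3   # within
  counts["v1", "c1"] <- 2   # between
  conf <- new("ConfusionMatrix", counts = counts,
              insertions = setNames(numeric(4), names(cm)),
              deletions = setNames(numeric(4), names(cm)), classMap = cm)
  expect_equal(pcc(conf), 1.5)
  counts2 <- counts * 0; counts2["v1", "c1"] <- 5
  conf2 <- new("ConfusionMatrix", counts = counts2,
               insertions = setNames(numeric(4), names(cm)),
               deletions = setNames(numeric(4), names(cm)), classMap = cm)
  expect_equal(pcc(conf2), 0)
  counts3 <- counts * 0; counts3["v1", "v2"] <- 5
  conf3 <- new("ConfusionMatrix", counts = counts3,
               insertions = setNames(numeric(4), names(cm)),
               deletions = setNames(numeric(4), names(cm)), classMap = cm)
  expect_true(is.infinite(pcc(conf3)))
  counts4 <- counts * 0; diag(counts4) <- 2
  conf4 <- new("ConfusionMatrix", counts = counts4,
               insertions = setNames(numeric(4), names(cm)),
               deletions = setNames(numeric(4), names(cm)), classMap = cm)
  expect_true(is.nan(pcc(conf4)))
})

test_that("chance pcc: counting identities and Monte-Carlo agreement", {
  cm <- c(v1 = "vowel", v2 = "vowel", c1 = "consonant", c2 = "consonant")
  expect_equal(chancePcc(cm), 0.5)   # (1/3) / (2/3)
  two <- c(v = "vowel", c = "consonant")
  expect_equal(chancePcc(two), 0)
  expect_error(chancePcc(c(v1 = "vowel", v2 = "vowel")), "single-class")
  # uniform-substitution simulation oracle
  withr::with_seed(21, {
    cls <- inventoryClassMap()
    e <- setNames(sample(1:30, length(cls), replace = TRUE), names(cls))
    sim <- simUniformSubstitution(cls, e, 5e5)
    expect_lt(abs(chancePcc(cls, e) - sim) / sim, 0.02)
  })
})

test_that("uniform random substitutions give pcc at the chance level", {
  withr::with_seed(31, {
    cls <- inventoryClassMap()
    P <- length(cls)
    n <- 1e5
    others <- vapply(names(cls), function(s) setdiff(names(cls), s),
                     character(P - 1))
    refs <- sample(names(cls), n, replace = TRUE)
    hyps <- others[cbind(sample.int(P - 1, n, replace = TRUE),
                         match(refs, names(cls)))]
    counts <- table(factor(refs, names(cls)), factor(hyps, names(cls)))
    conf <- new("ConfusionMatrix", counts = unclass(as.matrix(counts)),
                insertions = setNames(numeric(P), names(cls)),
                deletions = setNames(numeric(P), names(cls)),
                classMap = cls)
    expect_lt(abs(pcc(conf) - chancePcc(conf)) / chancePcc(conf), 0.05)
  })
})

test_that("aligned mel R2: self-identity, stretch tolerance, null level", {
  u <- tinyUtterance()
  expect_equal(alignedMelR2(u, waveform(u)), 1, tolerance = 1e-9)
  # uniform time stretch of the spectrogram is realigned by interpolation;
  # interpolation of noise-carrying frames bounds the score below the
  # self-identity value
  m <- melValues(melSpectrogram(u))
  for (fac in c(0.8, 1.2)) {
    idx <- seq(1, nrow(m), length.out = round(nrow(m) * fac))
    mst <- apply(m, 2, function(col) approx(seq_along(col), col, idx)$y)
    expect_gt(alignedMelR2(u, mst), 0.75)
  }
  # the unstretched matrix path reproduces the self-identity
  expect_gt(alignedMelR2(u, m), 0.999)
  # independent white noise scores far below matched speech
  nulls <- vapply(1:5, function(s)
    as.numeric(alignedMelR2(u, withSeedWave(length(waveform(u)), s))),
    numeric(1))
  expect_lt(mean(nulls), 0.4)
  # no voiced segments flagged as NaN
  empty <- synthesizeUtterance(character(0), tinyVocab())
  expect_true(is.nan(suppressWarnings(alignedMelR2(empty,
                                                   waveform(empty)))))
})

test_that("toy recognizer has a zero error floor on clean synthesis", {
  v <- tinyVocab()
  withr::with_seed(41, {
    wer <- per <- numeric(6)
    for (k in 1:6) {
      ws <- sample(vocabWords(v), sample(2:4, 1), replace = TRUE)
      u <- synthesizeUtterance(ws, v, seed = k + 100)
      r <- toyRecognize(u, v)
      wer[k] <- errorRate(wordIntervals(u)$label, r$words)
      per[k] <- errorRate(phonemeIntervals(u)$label, r$phonemes)
    }
    expect_equal(mean(wer), 0)
    expect_equal(mean(per), 0)
  })
})

test_that("noise reference curves are monotone in SNR", {
  v <- tinyVocab()
  withr::with_seed(51, {
    utts <- lapply(1:6, function(k)
      synthesizeUtterance(sample(vocabWords(v), 3), v, seed = k,
                          id = paste0("u", k)))
  })
  r2 <- noiseReferenceCurve(utts, c(0, 5, 10, 20), "mel_r2", seed = 1)
  expect_true(all(diff(r2) >= -0.02))
  # near-identity: bounded below 1 by log-floor cells of the sparse
  # template spectra, where -60 dB perturbations still move the log value
  expect_gte(noiseReferenceCurve(utts[1:2], 60, "mel_r2", seed = 1)[1], 0.8)
  wer <- noiseReferenceCurve(utts, c(0, 5, 10, 20), "wer", vocab = v,
                             seed = 1)
  expect_true(all(diff(wer) <= 0.02))
  # determinism
  expect_identical(noiseReferenceCurve(utts[1:2], c(-5, 0), "mel_r2",
                                       seed = 3),
                   noiseReferenceCurve(utts[1:2], c(-5, 0), "mel_r2",
                                       seed = 3))
})

test_that("evaluateDataset aggregates per-trial metrics with correct s.e.", {
  v <- tinyVocab()
  withr::with_seed(61, {
    refs <- lapply(1:4, function(k)
      synthesizeUtterance(sample(vocabWords(v), 2), v, seed = k,
                          id = paste0("r", k)))
  })
  rep0 <- evaluateDataset(lapply(refs, waveform), refs, v)
  s <- reportSummary(rep0)
  expect_equal(s$mean[s$metric == "wer"], 0)
  expect_equal(s$mean[s$metric == "per"], 0)
  expect_equal(s$mean[s$metric == "mel_r2"], 1, tolerance = 1e-9)
  # mean/se agree with direct recomputation
  pt <- perTrialMetrics(rep0)
  expect_equal(s$se[s$metric == "wer"], sd(pt$wer) / sqrt(nrow(pt)))
  # single trial: se undefined
  rep1 <- evaluateDataset(list(waveform(refs[[1]])), refs[1], v)
  expect_true(is.na(reportSummary(rep1)$se[1]))
  expect_error(evaluateDataset(list(), refs, v), "align")
})
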