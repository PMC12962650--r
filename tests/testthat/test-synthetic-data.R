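test_that("vocabulary construction is deterministic and pronounceable", {
  v1 <- buildVocabulary(8, seed = 0)
  v2 <- buildVocabulary(8, seed = 0)
  expect_identical(vocabWords(v1), vocabWords(v2))
  expect_identical(phonemeSpelling(v1), phonemeSpelling(v2))
  v50 <- buildVocabulary(50, seed = 3)
  expect_length(unique(vocabWords(v50)), 50L)
  cls <- inventoryClassMap()
  for (ph in phonemeSpelling(v50)) {
    expect_true(any(cls[ph] == "vowel"))             # >= 1 vowel
    expect_true(all(ph %in% names(cls)))
    expect_true(length(ph) >= 2 && length(ph) <= 5)
    expect_true(all(cls[ph][-1] != cls[ph][-length(ph)]))  # alternation
  }
  ids <- sort(unname(tokenIds(v50)))
  expect_identical(ids, 0:52)
})

test_that("capacity check matches exhaustive enumeration on a 3-phoneme inventory", {
  inv <- defaultPhonemeInventory()[c("aa", "s", "m")]   # 1 vowel, 2 consonants
  # oracle: enumerate all class-alternating words of length 2..5 with >= 1 vowel
  cls <- inventoryClassMap(inv)
  labs <- names(cls)
  count <- 0L
  enum <- function(seq) {
    if (length(seq) >= 2 && any(cls[seq] == "vowel")) count <<- count + 1L
    if (length(seq) >= 5) return()
    for (l in labs)
      if (length(seq) == 0 || cls[l] != cls[seq[length(seq)]])
        enum(c(seq, l))
  }
  enum(character(0))
  expect_equal(duovox:::vocabularyCapacity(1, 2), count)
  expect_error(buildVocabulary(count + 1L, inv, seed = 1), "admissible")
  expect_error(buildVocabulary(4, inv[c("s", "m")], seed = 1),
               "vowel and one consonant")
})

test_that("utterance synthesis honours duration/annotation contracts", {
  v <- tinyVocab()
  empty <- synthesizeUtterance(character(0), v)
  expect_length(waveform(empty), round(0.8 * 16000))
  expect_equal(nrow(wordIntervals(empty)), 0L)
  # a word's interval length is the sum of its phoneme durations
  u <- tinyUtterance()
  spell <- phonemeSpelling(v)
  inv <- defaultPhonemeInventory()
  w <- wordIntervals(u)
  for (k in seq_len(nrow(w))) {
    expectLen <- sum(vapply(spell[[w$label[k]]],
                            function(l) round(inv[[l]]$duration_s * 16000),
                            numeric(1)))
    expect_equal(w$end[k] - w$start[k], expectLen)
  }
  ph <- phonemeIntervals(u)
  expect_true(all(ph$end > ph$start))
  expect_error(synthesizeUtterance("nosuchword", v), "unknown word")
})

test_that("vowel segments peak at the template's dominant mel band", {
  v <- tinyVocab()
  u <- tinyUtterance()
  inv <- defaultPhonemeInventory()
  mel <- melValues(melSpectrogram(u))
  ph <- phonemeIntervals(u)
  cls <- inventoryClassMap(inv)
  vowels <- ph[cls[ph$label] == "vowel", ]
  for (k in seq_len(nrow(vowels))) {
    f1 <- floor(vowels$start[k] / 320) + 2L
    f2 <- floor(vowels$end[k] / 320) - 1L
    if (f2 <= f1) next
    seg <- colMeans(mel[f1:f2, ])
    # oracle: direct mel filterbank projection of the template spectrum
    prof <- inv[[vowels$label[k]]]$spectral_profile
    # harmonic quantization of the formant peak allows a small offset;
    # compare in frequency terms
    cf <- melCenterFrequencies()
    expect_lt(abs(cf[which.max(seg)] - cf[which.max(prof)]), 160)
  }
})

test_that("neural simulation follows the lagged encoding model", {
  v <- tinyVocab()
  u <- tinyUtterance()
  em <- makeEncodingModel(6L, 4L, noise_sd = 0, seed = 2)
  rec <- simulateNeural(u, em, seed = 3)
  expect_equal(ncol(hgMatrix(rec)),
               round(length(waveform(u)) / 16000 * 50))
  # oracle: direct convolution recomputation for a responsive channel
  ch <- which(responsiveMask(em))[1]
  mel <- melValues(melSpectrogram(u))
  drive <- as.numeric(mel %*% em@weights[ch, ])
  lag <- em@latency[ch]
  lagged <- c(rep(drive[1], lag), drive[seq_len(length(drive) - lag)])
  sm <- as.numeric(stats::filter(lagged, em@lagKernel, method = "convolution",
                                 sides = 1))
  sm[seq_along(em@lagKernel)] <- sm[length(em@lagKernel)]
  n <- min(length(sm), ncol(hgMatrix(rec)))
  expect_gt(cor(sm[1:n], hgMatrix(rec)[ch, 1:n]), 0.99)
  # zero-weight channels with zero noise collapse to zeros
  emz <- makeEncodingModel(4L, 0L, noise_sd = 0, seed = 2)
  recz <- simulateNeural(u, emz, seed = 3)
  expect_true(all(hgMatrix(recz) == 0))
  # determinism
  expect_identical(hgMatrix(simulateNeural(u, em, seed = 9)),
                   hgMatrix(simulateNeural(u, em, seed = 9)))
})

test_that("datasets split at the configured fractions, disjointly", {
  ds <- tinyDataset()
  tab <- table(splitLabels(ds))
  expect_equal(as.integer(tab[c("train", "val", "test")]),
               c(round(0.7 * 24), round(0.2 * 24),
                 24 - round(0.7 * 24) - round(0.2 * 24)))
  expect_error(makeDataset(defaultDatasetConfig(
    n_sentences = 4L, split = c(train = 0.6, val = 0.3, test = 0.2))),
    "sum to 1")
  expect_warning(ds1 <- makeDataset(defaultDatasetConfig(
    n_sentences = 6L, n_channels = 4L, n_responsive = 2L, n_words = 6L,
    split = c(train = 1, val = 0, test = 0)), seed = 1), "empty")
  expect_true(all(splitLabels(ds1) == "train"))
  # different seeds: different member sets, identical split sizes
  cfg <- defaultDatasetConfig(n_sentences = 10L, n_channels = 4L,
                              n_responsive = 2L, n_words = 6L)
  dsa <- makeDataset(cfg, seed = 1); dsb <- makeDataset(cfg, seed = 2)
  expect_equal(table(splitLabels(dsa)), table(splitLabels(dsb)))
})

test_that("dataset regeneration with the same seed is bit-identical", {
  cfg <- defaultDatasetConfig(n_sentences = 4L, n_channels = 6L,
                              n_responsive = 4L, n_words = 6L,
                              words_range = c(2L, 3L))
  d1 <- suppressWarnings(makeDataset(cfg, seed = 5))
  d2 <- suppressWarnings(makeDataset(cfg, seed = 5))
  expect_identical(lapply(trialUtterances(d1), waveform),
                   lapply(trialUtterances(d2), waveform))
  expect_identical(lapply(trialNeural(d1), hgMatrix),
                   lapply(trialNeural(d2), hgMatrix))
  expect_identical(splitLabels(d1), splitLabels(d2))
})

test_that("simulated channel SNR tracks the configured noise level", {
  v <- buildVocabulary(8, seed = 2)
  em <- makeEncodingModel(8L, 6L, noise_sd = 0.5, seed = 4)
  ratios <- replicate(30, {
    ws <- sample(vocabWords(v), 3)
    u <- synthesizeUtterance(ws, v, seed = sample.int(1e6, 1))
    rec <- simulateNeural(u, em, seed = sample.int(1e6, 1),
                          return_clean = TRUE)
    cl <- attr(rec, "clean")
    resp <- which(responsiveMask(em))
    mean(apply(cl[resp, , drop = FALSE], 1, var))
  })
  # clean responses are standardized to unit variance, so SNR = 1/noise_sd^2
  expect_lt(abs(mean(ratios) / 0.5^2 - 1 / 0.5^2) * 0.5^2, 0.1)
  expect_lt(abs(mean(ratios) - 1), 0.1)
})
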