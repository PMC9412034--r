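test_that("comparison pairs stay within the three lead groups", {
  p <- comparisonPairs()
  expect_equal(nrow(p), 21L)
  expect_equal(nrow(comparisonPairs("limb")), 3L)
  expect_equal(nrow(comparisonPairs("augmented")), 3L)
  expect_equal(nrow(comparisonPairs("precordial")), 15L)
  expect_equal(anyDuplicated(paste(p$a, p$b)), 0L)
  ord <- match(p$a, leadNames()) < match(p$b, leadNames())
  expect_true(all(ord))
  groups <- list(c("I", "II", "III"), c("aVR", "aVL", "aVF"),
                 paste0("V", 1:6))
  sameGroup <- mapply(function(a, b)
    any(vapply(groups, function(g) a %in% g && b %in% g, logical(1L))),
    p$a, p$b)
  expect_true(all(sameGroup))
})

test_that("precordial transition codes the first polarity change", {
  seg <- leadMatrix(40L)
  # positive lobes everywhere, then flip V3..V6 negative: change at V3 = 0.4
  for (l in leadNames()) seg[l, ] <- gaussPulse(40L, 20L, 4)
  for (l in c("V3", "V4", "V5", "V6")) seg[l, ] <- -seg[l, ]
  expect_equal(precordialTransition(seg), 0.4)
  # change only at V6 codes 1.0, same as the no-change sentinel
  seg2 <- leadMatrix(40L)
  for (l in leadNames()) seg2[l, ] <- gaussPulse(40L, 20L, 4)
  seg2["V6", ] <- -seg2["V6", ]
  expect_equal(precordialTransition(seg2), 1.0)
  expect_equal(precordialTransition(abs(seg2)), 1.0)
  # negative-first beats: transition is relative to V1's polarity
  seg3 <- -seg
  expect_equal(precordialTransition(seg3), 0.4)
})

test_that("the three feature families have the enumerated sizes", {
  b <- randomBeats[[5L]]
  seg <- normalizeAndAlign(b)
  sf <- extractSignalFeatures(seg, b@qrsOnset, b@qrsOffset)
  expect_length(sf, 2L + 8L * 12L + 3L * 21L)  # 161
  decomps <- lapply(seq_len(12L), function(l)
    waveletTransform(signalMatrix(seg)[l, ], 1:4))
  fids <- lapply(decomps, function(d)
    tryCatch(detectFiducials(d, seg@rIndex), error = function(e) NULL))
  wf <- extractWaveletFeatures(seg, decomps, fids)
  expect_length(wf, 1L + 6L * 12L + 3L * 21L)  # 136
  spectra <- lapply(seq_len(12L), function(l)
    welchPsd(signalMatrix(seg)[l, ], seg@fs))
  pf <- extractSpectralFeatures(seg, spectra)
  expect_length(pf, 7L * 12L)  # 84
  expect_false(anyNA(c(sf, wf, pf)))
  # QRS duration is reported in milliseconds
  expect_equal(unname(sf["signal.qrsDuration"]),
               (b@qrsOffset - b@qrsOnset) / b@fs * 1000)
})

test_that("degenerate leads and identical pairs give the documented values", {
  b <- randomBeats[[6L]]
  seg <- normalizeAndAlign(b)
  x <- signalMatrix(seg)
  x["III", ] <- 0                      # an all-zero lead
  x["II", ] <- x["I", ]                # identical pair within the limb group
  seg2 <- seg
  seg2@signal <- x
  sf <- extractSignalFeatures(seg2, b@qrsOnset, b@qrsOffset)
  expect_equal(unname(sf["signal.polarity.III"]), 1)
  expect_equal(unname(sf["signal.amplitude.III"]), 0)
  expect_equal(unname(sf["signal.area.III"]), 0)
  expect_equal(unname(sf["signal.absArea.III"]), 0)
  expect_equal(unname(sf["signal.diffMax.I_II"]), 0)
  expect_equal(unname(sf["signal.diffArea.I_II"]), 0)
  expect_equal(unname(sf["signal.xcorr.I_II"]), 1)
})

test_that("polarity features are anti-symmetric under lead negation", {
  b <- randomBeats[[7L]]
  seg <- normalizeAndAlign(b)
  sf <- extractSignalFeatures(seg, b@qrsOnset, b@qrsOffset)
  segN <- seg
  segN@signal["V4", ] <- -segN@signal["V4", ]
  sfN <- extractSignalFeatures(segN, b@qrsOnset, b@qrsOffset)
  expect_equal(unname(sfN["signal.polarity.V4"]),
               -unname(sf["signal.polarity.V4"]))
  expect_equal(unname(sfN["signal.maxAbsSigned.V4"]),
               -unname(sf["signal.maxAbsSigned.V4"]))
  expect_equal(unname(sfN["signal.vmax.V4"]), -unname(sf["signal.vmin.V4"]))
})

test_that("wavelet features respect their bounds and the R/S contract", {
  b <- randomBeats[[8L]]
  seg <- normalizeAndAlign(b)
  decomps <- lapply(seq_len(12L), function(l)
    waveletTransform(signalMatrix(seg)[l, ], 1:4))
  fids <- lapply(decomps, function(d)
    tryCatch(detectFiducials(d, seg@rIndex), error = function(e) NULL))
  wf <- extractWaveletFeatures(seg, decomps, fids)
  frag <- wf[grep("fragmentation", names(wf))]
  expect_true(all(frag >= -1 - 1e-9 & frag <= 1 + 1e-9))

  # |R| = |S| symmetric biphasic beat: ratio 1 on that lead
  L <- 160L
  bi <- gaussPulse(L, 70L, 8, 1) - gaussPulse(L, 100L, 8, 1)
  segB <- seg
  segB@signal["V5", ] <- bi / max(abs(segB@signal))
  dB <- lapply(seq_len(12L), function(l)
    waveletTransform(signalMatrix(segB)[l, ], 1:4))
  fB <- lapply(dB, function(d)
    tryCatch(detectFiducials(d, segB@rIndex), error = function(e) NULL))
  wfB <- extractWaveletFeatures(segB, dB, fB)
  expect_equal(unname(wfB["wavelet.rsRatio.V5"]), 1, tolerance = 0.05)
})

test_that("spectral features locate a planted tone in the right band", {
  b <- randomBeats[[9L]]
  seg <- normalizeAndAlign(b)
  # replace one lead with a pure 30 Hz tone
  tone <- sin(2 * pi * 30 * (0:159) / 1000)
  segT <- seg
  segT@signal["V1", ] <- tone / max(abs(segT@signal))
  spectra <- lapply(seq_len(12L), function(l)
    welchPsd(signalMatrix(segT)[l, ], segT@fs))
  pf <- extractSpectralFeatures(segT, spectra)
  df <- diff(spectra[[7L]]$frequencies[1:2])
  expect_lte(abs(unname(pf["spectral.fundamental.V1"]) - 30), df)
  bandNames <- sprintf("spectral.band%s.V1",
                       c("0_3", "3_6", "6_9", "9_12", "12_25", "25_50"))
  bands <- pf[bandNames]
  expect_equal(names(which.max(bands)), "spectral.band25_50.V1")

  # an all-zero lead has zero band powers
  segZ <- seg
  segZ@signal["III", ] <- 0
  spz <- lapply(seq_len(12L), function(l)
    welchPsd(signalMatrix(segZ)[l, ], segZ@fs))
  pz <- extractSpectralFeatures(segZ, spz)
  expect_true(all(pz[sprintf("spectral.band%s.III",
                             c("0_3", "3_6", "6_9", "9_12", "12_25",
                               "25_50"))] == 0))
})

test_that("the full battery yields a fixed 381-column matrix", {
  small <- methods::new("ECGDataset", records = records(tinyDb)[1:6],
                        provenance = "simulated_style", metadata = list())
  fm <- extractFeatureMatrix(small)
  expect_equal(dim(fm$x), c(6L, 381L))
  expect_false(anyNA(fm$x))
  fm2 <- extractFeatureMatrix(small)
  expect_identical(colnames(fm$x), colnames(fm2$x))
  expect_equal(fm$x, fm2$x)
  # mixed sampling rates are rejected at dataset construction already
  odd <- records(tinyDb)[1:2]
  odd[[2L]]@fs <- 500
  expect_error(methods::new("ECGDataset", records = odd,
                            provenance = "user", metadata = list()),
               "share the sampling rate")
})
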