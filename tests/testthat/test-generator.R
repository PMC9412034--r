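test_that("beat generation is deterministic and validates its inputs", {
  cfg <- generatorConfig(seed = 9L)
  b1 <- generateBeat(3L, "LVOT", "NCC", 5L, cfg)
  b2 <- generateBeat(3L, "LVOT", "NCC", 5L, cfg)
  expect_identical(signalMatrix(b1), signalMatrix(b2))
  expect_identical(b1@qrsOnset, b2@qrsOnset)

  expect_error(generateBeat(1L, "LVOT", "not-a-site", 1L, cfg),
               "unknown sublocation")
  expect_error(generateBeat(1L, "RVOT", "LCC", 1L, cfg),
               "does not belong")
  expect_error(generateBeat(99L, "LVOT", "LCC", 1L, cfg), "outside")
  expect_error(generatorConfig(classSeparation = -1), "nonnegative")
})

test_that("chamber controls the precordial signature", {
  # RVOT beats: V1 dominant deflection negative, late or absent transition
  sc <- sublocationChamber()
  rvSubs <- names(sc)[sc == "RVOT"]
  lvSubs <- names(sc)[sc == "LVOT"]
  cfg <- generatorConfig(seed = 8L)
  for (s in rvSubs) {
    b <- generateBeat(2L, "RVOT", s, 3L, cfg)
    v1 <- signalMatrix(b)["V1", ]
    expect_lt(v1[which.max(abs(v1))], 0)
    expect_identical(b@chamber, "RVOT")
  }
  # LVOT beats transition earlier than RVOT beats on average
  trans <- function(subs, ch) {
    mean(vapply(subs, function(s)
      precordialTransition(normalizeAndAlign(generateBeat(1L, ch, s, 1L, cfg))),
      numeric(1L)))
  }
  expect_lt(trans(lvSubs, "LVOT"), trans(rvSubs, "RVOT"))
})

test_that("fiducial invariants hold on generated beats", {
  for (b in randomBeats[1:25]) {
    nT <- ncol(signalMatrix(b))
    expect_true(1L <= b@qrsOnset && b@qrsOnset < b@rPeak &&
                b@rPeak < b@qrsOffset && b@qrsOffset <= nT + 1L)
  }
})

test_that("the factorial database covers every design cell exactly once", {
  expect_equal(nRecords(tinyDb), 3L * 12L * 2L)
  expect_identical(provenance(tinyDb), "simulated_style")
  # record ids encode the (anatomy, soo entry, electrode) design cell;
  # uniqueness means every cell is emitted exactly once
  expect_equal(anyDuplicated(recordIds(tinyDb)), 0L)
  perAnatomy <- table(vapply(records(tinyDb), function(r) r@anatomyId,
                             integer(1L)))
  expect_true(all(perAnatomy == 12L * 2L))
  # chamber counts follow the 7:5 LVOT:RVOT design
  ch <- chamberLabels(tinyDb)
  expect_equal(sum(ch == "LVOT"), 3L * 7L * 2L)
  expect_equal(sum(ch == "RVOT"), 3L * 5L * 2L)
  # database generation is deterministic
  db2 <- generateDatabase(tinyCfg)
  expect_identical(signalMatrix(getRecord(tinyDb, 17L)),
                   signalMatrix(getRecord(db2, 17L)))
  # degenerate single-cell design
  one <- generateDatabase(generatorConfig(
    nAnatomies = 1L, sooList = defaultSooList()[1L, ],
    nElectrodeConfigs = 1L, seed = 1L))
  expect_equal(nRecords(one), 1L)
})

test_that("strong class separation dwarfs within-chamber spread in V2", {
  cfg <- generatorConfig(classSeparation = 2, seed = 7L)
  sc <- sublocationChamber()
  lateMean <- function(rec) {
    v <- signalMatrix(rec)["V2", ]
    r <- rec@rPeak
    mean(v[(r + 15L):min(r + 70L, length(v))])
  }
  mc <- function(ch) {
    subs <- names(sc)[sc == ch]
    withr::with_seed(3L, vapply(1:200, function(i)
      lateMean(generateBeat(sample(16L, 1L), ch, sample(subs, 1L),
                            sample(13L, 1L), cfg)), numeric(1L)))
  }
  lv <- mc("LVOT"); rv <- mc("RVOT")
  gap <- abs(mean(lv) - mean(rv))
  pooledSd <- sqrt((stats::var(lv) + stats::var(rv)) / 2)
  expect_gt(gap, 3 * pooledSd)
})

test_that("a trivial V2 threshold classifier finds the chamber signal", {
  db <- generateDatabase(generatorConfig(nAnatomies = 8L,
                                         nElectrodeConfigs = 4L, seed = 11L))
  lateMean <- function(rec) {
    v <- signalMatrix(rec)["V2", ]
    r <- rec@rPeak
    mean(v[(r + 15L):min(r + 70L, length(v))])
  }
  lm2 <- vapply(records(db), lateMean, numeric(1L))
  ch <- chamberLabels(db)
  thr <- (mean(lm2[ch == "LVOT"]) + mean(lm2[ch == "RVOT"])) / 2
  pred <- ifelse(lm2 > thr, "LVOT", "RVOT")
  expect_gt(balancedAccuracy(ch, pred), 0.8)
})

test_that("adjacent sublocations are morphologically closer than distant ones", {
  cfg <- generatorConfig(nAnatomies = 8L, nElectrodeConfigs = 6L, seed = 5L)
  subs <- sublocationLevels()
  sc <- sublocationChamber()
  beatMats <- withr::with_seed(21L, lapply(subs, function(s) {
    t(vapply(1:50, function(i)
      as.vector(signalMatrix(generateBeat(sample(8L, 1L), sc[[s]], s,
                                          sample(6L, 1L), cfg))),
      numeric(12L * 300L)))
  }))
  names(beatMats) <- subs
  crossDist <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    mean(sqrt(pmax(d2, 0)))
  }
  g <- defaultAdjacencyGraph()
  adj <- matrix(FALSE, 9L, 9L, dimnames = list(subs, subs))
  for (k in seq_len(nrow(g))) {
    adj[g$from[k], g$to[k]] <- TRUE
    adj[g$to[k], g$from[k]] <- TRUE
  }
  dAdj <- c(); dNon <- c()
  for (i in 1:8) for (j in (i + 1):9) {
    d <- crossDist(beatMats[[i]], beatMats[[j]])
    if (adj[i, j]) dAdj <- c(dAdj, d) else dNon <- c(dNon, d)
  }
  expect_lt(mean(dAdj), mean(dNon))
})

test_that("clinical-like generation matches its sampling contract", {
  expect_error(generateClinicalLike(0, 0.3), "positive count")
  expect_error(generateClinicalLike(10, 1.2), "strictly between")

  # class counts: binomial expectation within 3 sigma at the 77:257 ratio
  cfg <- generatorConfig(nAnatomies = 4L, nElectrodeConfigs = 3L, seed = 77L)
  cl <- generateClinicalLike(334L, 77 / 334, cfg)
  expect_equal(nRecords(cl), 334L)
  expect_identical(provenance(cl), "clinical_like")
  nLv <- sum(chamberLabels(cl) == "LVOT")
  sigma <- sqrt(334 * (77 / 334) * (1 - 77 / 334))
  expect_lt(abs(nLv - 77), 3 * sigma)

  # signals are finite, and determinism holds given the seed
  expect_false(any(vapply(records(cl), function(r)
    anyNA(signalMatrix(r)) || any(!is.finite(signalMatrix(r))),
    logical(1L))))
  cl2 <- generateClinicalLike(334L, 77 / 334, cfg)
  expect_identical(signalMatrix(getRecord(cl, 5L)),
                   signalMatrix(getRecord(cl2, 5L)))

  # degenerate noise-free limit reduces to pure generator output
  cfg0 <- generatorConfig(nAnatomies = 4L, nElectrodeConfigs = 3L,
                          seed = 78L, noiseSd = 0)
  cl0 <- generateClinicalLike(20L, 0.5, cfg0, wanderAmplitude = 0,
                              gainRange = c(1, 1))
  r <- getRecord(cl0, 1L)
  base <- generateBeat(r@anatomyId, r@chamber, r@sublocation,
                       r@electrodeConfigId, cfg0)
  expect_equal(signalMatrix(r), signalMatrix(base), tolerance = 1e-12)
})
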