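test_that("balanced accuracy equals the mean of per-class recalls", {
  expect_equal(balancedAccuracy(c("A", "B", "A"), c("A", "B", "A")), 1)
  # constant predictor with two classes present: 0.5
  expect_equal(balancedAccuracy(c("A", "A", "B", "B"), rep("A", 4L)), 0.5)
  # contingency TP=9 FN=1 / TN=3 FP=7: (0.9 + 0.3) / 2
  yTrue <- c(rep("pos", 10L), rep("neg", 10L))
  yPred <- c(rep("pos", 9L), "neg", rep("pos", 7L), rep("neg", 3L))
  expect_equal(balancedAccuracy(yTrue, yPred), 0.6)
  # equals plain accuracy on exactly balanced classes
  withr::with_seed(2L, {
    yt <- rep(c("A", "B"), each = 30L)
    yp <- sample(c("A", "B"), 60L, replace = TRUE)
  })
  expect_equal(balancedAccuracy(yt, yp), mean(yt == yp))
  expect_error(balancedAccuracy(character(0), character(0)), "empty")
  expect_error(balancedAccuracy("A", c("A", "B")), "mismatch")
})

test_that("SVM training separates, permutes and weights correctly", {
  withr::with_seed(5L, {
    x <- rbind(matrix(stats::rnorm(40L), 20L),
               matrix(stats::rnorm(40L, mean = 3), 20L))
    xt <- matrix(stats::rnorm(60L, mean = 1.5), 30L)
  })
  y <- rep(c("A", "B"), each = 20L)
  m <- trainSvm(x, y, C = 10)
  expect_true(all(predict(m, x) == y))          # separable training set
  expect_error(trainSvm(x, rep("A", 40L)), "single class")

  p <- withr::with_seed(6L, sample(40L))
  mp <- trainSvm(x[p, ], y[p], C = 10)
  expect_identical(predict(m, xt), predict(mp, xt))

  # the weighted dual solution agrees with libsvm at unit weights
  mw <- trainSvm(x, y, C = 10, weights = rep(1, 40L))
  expect_identical(predict(m, xt), predict(mw, xt))

  # duplicating every sample at half weight leaves the decision unchanged
  g <- 1 / (ncol(x) * mean(apply(x, 2L, stats::var)))
  mHalf <- trainSvm(rbind(x, x), c(y, y), gamma = g,
                    weights = rep(0.5, 80L))
  mUnit <- trainSvm(x, y, gamma = g, weights = rep(1, 40L))
  dHalf <- predict(mHalf, xt, type = "decision")
  dUnit <- predict(mUnit, xt, type = "decision")
  expect_lt(max(abs(dHalf - dUnit)), 0.02)
})

test_that("stratified cross-validation partitions and stratifies", {
  withr::with_seed(9L, {
    x <- matrix(stats::rnorm(200L), 100L)
    y <- rep(c("A", "B"), times = c(60L, 40L))
  })
  cv <- crossValidate(x, y, folds = 5L, seed = 1L)
  expect_length(cv$foldAccuracies, 5L)
  # every sample tested exactly once
  expect_equal(sort(unique(cv$foldAssignment)), 1:5)
  expect_equal(length(cv$foldAssignment), 100L)
  # per-fold class proportions within one sample of the global split
  for (f in 1:5) {
    sel <- cv$foldAssignment == f
    expect_lte(abs(sum(y[sel] == "A") - 12), 1)
    expect_lte(abs(sum(y[sel] == "B") - 8), 1)
  }
  expect_error(crossValidate(x[1:6, ], y[c(1:3, 61:63)], folds = 5L),
               "fewer samples")
})

test_that("the pipeline classifies well-separated generator data in CV", {
  db <- generateDatabase(generatorConfig(nAnatomies = 4L,
                                         nElectrodeConfigs = 2L,
                                         classSeparation = 2, seed = 6L))
  rawRep <- extractRawMatrix(db)
  cv <- crossValidate(rawRep$x, rawRep$chamber, folds = 5L, seed = 2L)
  expect_gt(cv$cvAccuracy, 0.9)
})

test_that("lead-subset search bookkeeping matches the combinatorics", {
  db <- generateDatabase(generatorConfig(nAnatomies = 3L,
                                         nElectrodeConfigs = 2L, seed = 13L))
  tr <- extractRawMatrix(db)
  te <- extractRawMatrix(generateClinicalLike(
    40L, 0.4, generatorConfig(nAnatomies = 3L, nElectrodeConfigs = 2L,
                              seed = 14L, noiseSd = 0.05)))
  # restrict to 4 leads: 2^4 - 1 subsets, each lead in 2^3 of them
  leads4 <- c("I", "V1", "V2", "V5")
  cols <- unlist(lapply(leads4, function(l) grep(paste0("raw\\.", l, "\\."),
                                                 colnames(tr$x))))
  res <- exhaustiveLeadSearch(tr$x[, cols], tr$chamber,
                              tests = list(clin = list(x = te$x[, cols],
                                                       y = te$chamber)),
                              leads = leads4, nBins = 10L, fast = TRUE)
  expect_equal(nrow(res$table), 15L)
  expect_true(all(lengths(res$perLead) == 8L))
  expect_true(all(res$table$clin >= 0 & res$table$clin <= 1))
  # two-lead toy: 3 subsets
  leads2 <- c("V2", "V3")
  cols2 <- unlist(lapply(leads2, function(l) grep(paste0("raw\\.", l, "\\."),
                                                  colnames(tr$x))))
  res2 <- exhaustiveLeadSearch(tr$x[, cols2], tr$chamber,
                               tests = list(clin = list(x = te$x[, cols2],
                                                        y = te$chamber)),
                               leads = leads2, nBins = 10L, fast = TRUE)
  expect_equal(nrow(res2$table), 3L)
})

test_that("extra-trees ranking finds a planted separating feature", {
  withr::with_seed(8L, {
    n <- 120L
    y <- rep(c("A", "B"), each = n / 2L)
    noise <- matrix(stats::rnorm(n * 50L), n)
    colnames(noise) <- paste0("noise", 1:50)
    planted <- ifelse(y == "A", 1, -1) + stats::rnorm(n, sd = 0.05)
  })
  x <- cbind(planted = planted, noise)
  rk <- rankFeaturesExtraTrees(x, y, nTrees = 200L, seed = 1L)
  expect_identical(rk$feature[1L], "planted")
  expect_true(all(rk$importance >= 0))
  expect_equal(sum(rk$importance), 1, tolerance = 1e-9)
  # top-k slice comes back in descending order
  top <- utils::head(rk, 5L)
  expect_true(!is.unsorted(rev(top$importance)))
  # deterministic given the seed
  rk2 <- rankFeaturesExtraTrees(x, y, nTrees = 200L, seed = 1L)
  expect_identical(rk$feature, rk2$feature)
  # constant matrix: all-zero importances with a warning
  expect_warning(rkz <- rankFeaturesExtraTrees(matrix(1, 20L, 3L),
                                               rep(c("A", "B"), 10L)),
                 "constant")
  expect_true(all(rkz$importance == 0))
})

test_that("PCA cumulative variance is monotone and rank-limited", {
  withr::with_seed(3L, x <- matrix(stats::rnorm(300L), 30L))
  cv <- pcaCumulativeVariance(x)
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[length(cv)], 1, tolerance = 1e-9)
  # a rank-10 matrix reaches full variance within 10 components
  wide <- x %*% matrix(stats::rnorm(10L * 40L), 10L)
  cvw <- pcaCumulativeVariance(wide)
  expect_equal(cvw[10L], 1, tolerance = 1e-9)
  # appending a duplicated column cannot extend the effective rank
  dup <- cbind(wide, wide[, 1L])
  expect_equal(pcaCumulativeVariance(dup)[10L], 1, tolerance = 1e-9)
  expect_error(pcaCumulativeVariance(x[1L, , drop = FALSE]), "two rows")
})

test_that("scenario composition, weighting and disjointness are enforced", {
  aug <- augmentDataset(tinyDb, mixupConfig(ratio = 1L, seed = 2L))
  clTe <- generateClinicalLike(40L, 0.4, generatorConfig(
    nAnatomies = 3L, nElectrodeConfigs = 2L, seed = 15L, noiseSd = 0.05))
  r1 <- runScenario("sc1", "raw10", simulated = tinyDb, augmented = aug,
                    tests = list(clin = clTe), seed = 1L)
  expect_equal(r1@trainSize, nRecords(tinyDb) + nRecords(aug))
  expect_true(r1@spec$weighted)
  expect_length(r1@foldAccuracies, 5L)
  ba <- r1@testResults$clin$balancedAccuracy
  expect_true(ba >= 0 && ba <= 1)
  expect_equal(sum(r1@testResults$clin$confusion), nRecords(clTe))

  clTr <- generateClinicalLike(40L, 0.4, generatorConfig(
    nAnatomies = 3L, nElectrodeConfigs = 2L, seed = 16L, noiseSd = 0.05))
  r3 <- runScenario("sc3", "raw10", simulated = tinyDb,
                    clinicalTrain = clTr, tests = list(clin = clTe),
                    seed = 1L)
  expect_equal(r3@trainSize, nRecords(tinyDb) + nRecords(clTr))

  # training data reappearing in a test set is rejected
  expect_error(runScenario("sc1", "raw10", simulated = tinyDb,
                           tests = list(bad = tinyDb), seed = 1L),
               "overlaps")
})

test_that("the top-feature representation reuses the extra-trees ranking", {
  clTe <- generateClinicalLike(30L, 0.4, generatorConfig(
    nAnatomies = 3L, nElectrodeConfigs = 2L, seed = 17L, noiseSd = 0.05))
  small <- methods::new("ECGDataset", records = records(tinyDb),
                        provenance = "simulated_style", metadata = list())
  r <- runScenario("sc1", "top10", simulated = small,
                   tests = list(clin = clTe), seed = 1L, nTop = 10L)
  expect_length(r@spec$topFeatures, 10L)
  expect_true(all(r@spec$topFeatures %in%
                  colnames(extractFeatureMatrix(
                    methods::new("ECGDataset",
                                 records = records(tinyDb)[1L],
                                 provenance = "user",
                                 metadata = list()))$x)))
})
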