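#' Balanced accuracy
#'
#' Unweighted mean of per-class recalls: robust to class imbalance, the
#' evaluation metric for imbalanced clinical-like test sets. Equals
#' plain accuracy when the true classes are exactly balanced.
#'
#' @param yTrue,yPred equal-length label vectors; every class present in
#'   `yTrue` needs at least one sample.
#' @return number in `[0, 1]`.
#' @export
#' @examples
#' balancedAccuracy(c("A", "A", "B"), c("A", "B", "B"))
balancedAccuracy <- function(yTrue, yPred) {
  if (length(yTrue) == 0L) stop("empty input")
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  classes <- unique(yTrue)
  recalls <- vapply(classes, function(cl) {
    sel <- yTrue == cl
    mean(yPred[sel] == cl)
  }, numeric(1L))
  mean(recalls)
}

# stratified fold assignment: shuffle each class, deal round-robin
.stratifiedFolds <- function(y, folds, seed) {
  y <- as.character(y)
  assign <- integer(length(y))
  .withSeed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified k-fold cross-validation of an SVM
#'
#' Splits samples into stratified folds (per-class proportions within
#' one sample of the global ones), trains on the complement of each
#' fold — carrying any per-sample weights into the fit — and returns
#' the mean plain accuracy over the folds. Plain accuracy is used
#' inside CV; balanced accuracy is reserved for imbalanced external
#' test sets.
#'
#' @param x feature matrix.
#' @param y labels; every class must have at least `folds` samples.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @param C,gamma,weights,kernel passed to [trainSvm()].
#' @return list with `cvAccuracy` (mean), `foldAccuracies`, and
#'   `foldAssignment`.
#' @export
crossValidate <- function(x, y, folds = 5L, seed = 1L, C = 1, gamma = NULL,
                          weights = NULL, kernel = "radial") {
  x <- as.matrix(x)
  y <- as.character(y)
  folds <- as.integer(folds)
  counts <- table(y)
  if (any(counts < folds))
    stop(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                 names(counts)[which.min(counts)], min(counts), folds))
  assign <- .stratifiedFolds(y, folds, seed)
  accs <- vapply(seq_len(folds), function(f) {
    tr <- assign != f
    model <- trainSvm(x[tr, , drop = FALSE], y[tr], C = C, gamma = gamma,
                      weights = if (is.null(weights)) NULL else weights[tr],
                      kernel = kernel)
    pred <- predict(model, x[!tr, , drop = FALSE])
    mean(pred == y[!tr])
  }, numeric(1L))
  list(cvAccuracy = mean(accs), foldAccuracies = accs,
       foldAssignment = assign)
}

.confusion2 <- function(yTrue, yPred, levels = chamberLevels()) {
  table(true = factor(yTrue, levels = levels),
        pred = factor(yPred, levels = levels))
}

#' Exhaustive lead-subset search
#'
#' Trains one SVM per non-empty subset of the given leads on the
#' concatenated bin-mean columns of those leads (2^12 - 1 = 4,095
#' models for the full 12-lead set) and evaluates balanced accuracy on
#' each test set. Per-lead accuracy distributions pool the accuracies
#' of every subset containing the lead (2^11 = 2,048 subsets per lead
#' for 12 leads).
#'
#' @param trainX raw bin-mean matrix (columns blocked per lead as
#'   produced by [extractRawMatrix()]).
#' @param trainY training labels.
#' @param tests named list of test sets, each `list(x = , y = )` with
#'   the same column layout.
#' @param leads lead names being searched (default all 12).
#' @param nBins bins per lead in the column layout.
#' @param fast logical; use a linear kernel to cut per-model cost.
#' @param C,gamma passed to [trainSvm()].
#' @return A `"LeadSearchResult"`: list with `table` (one row per
#'   subset: `mask`, `leads`, one balanced-accuracy column per test
#'   set) and `perLead` (named list of accuracy vectors, first test
#'   set).
#' @export
exhaustiveLeadSearch <- function(trainX, trainY, tests,
                                 leads = leadNames(), nBins = 10L,
                                 fast = FALSE, C = 1, gamma = NULL) {
  nL <- length(leads)
  if (nL < 1L || nL > 20L) stop("unreasonable number of leads")
  if (is.null(names(tests)) || any(names(tests) == ""))
    names(tests) <- paste0("test", seq_along(tests))
  kernel <- if (fast) "linear" else "radial"
  leadCols <- lapply(seq_len(nL), function(j)
    ((j - 1L) * nBins + 1L):(j * nBins))
  nMask <- 2L^nL - 1L
  accs <- matrix(NA_real_, nrow = nMask, ncol = length(tests),
                 dimnames = list(NULL, names(tests)))
  leadStr <- character(nMask)
  for (mask in seq_len(nMask)) {
    inSet <- which(bitwAnd(mask, bitwShiftL(1L, 0:(nL - 1L))) != 0L)
    cols <- unlist(leadCols[inSet])
    model <- trainSvm(trainX[, cols, drop = FALSE], trainY, C = C,
                      gamma = gamma, kernel = kernel)
    for (t in seq_along(tests)) {
      pred <- predict(model, tests[[t]]$x[, cols, drop = FALSE])
      accs[mask, t] <- balancedAccuracy(tests[[t]]$y, pred)
    }
    leadStr[mask] <- paste(leads[inSet], collapse = "+")
  }
  tab <- data.frame(mask = seq_len(nMask), leads = leadStr,
                    stringsAsFactors = FALSE)
  for (t in seq_along(tests)) tab[[names(tests)[t]]] <- accs[, t]
  perLead <- stats::setNames(lapply(seq_len(nL), function(j) {
    sel <- bitwAnd(seq_len(nMask), bitwShiftL(1L, j - 1L)) != 0L
    accs[sel, 1L]
  }), leads)
  structure(list(table = tab, perLead = perLead, leads = leads,
                 nBins = nBins, kernel = kernel),
            class = "LeadSearchResult")
}

#' Extra-trees feature ranking
#'
#' Ranks features by mean impurity-decrease importance over an ensemble
#' of extremely randomized trees: each tree is fit on the whole
#' training set (no bootstrap) with random split thresholds, and the
#' per-tree importance accumulations give the mean and standard
#' deviation reported per feature. Importances are normalized to sum
#' to 1. Deterministic given the seed.
#'
#' @param x feature matrix with column names.
#' @param y labels (two or more classes).
#' @param nTrees ensemble size (default 200).
#' @param seed integer seed.
#' @return data.frame with `feature`, `importance` (sums to 1), `sd`
#'   (per-tree dispersion on the same scale), sorted by decreasing
#'   importance.
#' @export
rankFeaturesExtraTrees <- function(x, y, nTrees = 200L, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("need at least two classes")
  vars <- apply(x, 2L, stats::var)
  if (all(vars == 0)) {
    warning("constant feature matrix: all importances are zero")
    return(data.frame(feature = colnames(x), importance = 0, sd = 0,
                      stringsAsFactors = FALSE))
  }
  p <- ncol(x)
  mtry <- max(1L, floor(sqrt(p)))
  df <- data.frame(y = y, x, check.names = FALSE)
  imp <- matrix(0, nrow = nTrees, ncol = p, dimnames = list(NULL, colnames(x)))
  for (t in seq_len(nTrees)) {
    fit <- ranger::ranger(
      dependent.variable.name = "y", data = df, num.trees = 1L,
      mtry = mtry, splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1, importance = "impurity",
      seed = .childSeed(seed, paste0("tree", t)), num.threads = 1L,
      verbose = FALSE)
    imp[t, names(fit$variable.importance)] <- fit$variable.importance
  }
  m <- colMeans(imp)
  tot <- sum(m)
  if (tot == 0) {
    warning("no impurity decrease accumulated: all importances are zero")
    norm <- rep(0, p); sdv <- rep(0, p)
  } else {
    norm <- m / tot
    sdv <- apply(imp, 2L, stats::sd) / tot
  }
  out <- data.frame(feature = colnames(x), importance = norm, sd = sdv,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}

#' Cumulative explained-variance curve of a PCA
#'
#' Nondecreasing curve (ending at 1) of the variance explained by the
#' leading principal components; used to justify the 10-sample raw
#' representation and the top-10-feature subset.
#'
#' @param x numeric matrix with at least two rows.
#' @return numeric vector of cumulative explained-variance fractions.
#' @export
pcaCumulativeVariance <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least two rows")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) stop("zero total variance")
  cumsum(v) / sum(v)
}

#' Run one train/test scenario
#'
#' Composes the training set per scenario — `sc1`: simulated beats,
#' optionally concatenated with their mixup-augmented copies (lambda
#' weights on augmented rows); `sc2`: clinical-like training data only;
#' `sc3`: hybrid concatenation of clinical-like and simulated — builds
#' the requested representation (`raw10` bin means, the full `features`
#' battery, or the `top10` extra-trees-ranked feature subset), fits the
#' SVM, cross-validates within the training domain, and reports
#' balanced accuracy and confusion counts on each held-out test set.
#' Test sets sharing records with the training data are rejected.
#'
#' @param scenario `"sc1"`, `"sc2"` or `"sc3"`.
#' @param representation `"raw10"`, `"features"` or `"top10"`.
#' @param simulated simulated-style [ECGDataset-class] (sc1, sc3).
#' @param augmented optional augmented [ECGDataset-class] (sc1 only).
#' @param clinicalTrain clinical-like training [ECGDataset-class]
#'   (sc2, sc3).
#' @param tests named list of test [ECGDataset-class] objects.
#' @param seed integer seed (CV shuffling, feature ranking).
#' @param C,gamma SVM hyperparameters.
#' @param folds CV folds.
#' @param nTop number of top-ranked features for `"top10"`.
#' @param nBins bins for the raw representation.
#' @param useTrueFiducials use stored ground-truth fiducials.
#' @return A [ScenarioResult-class].
#' @export
runScenario <- function(scenario = c("sc1", "sc2", "sc3"),
                        representation = c("raw10", "features", "top10"),
                        simulated = NULL, augmented = NULL,
                        clinicalTrain = NULL, tests = list(),
                        seed = 1L, C = 1, gamma = NULL, folds = 5L,
                        nTop = 10L, nBins = 10L, useTrueFiducials = TRUE) {
  scenario <- match.arg(scenario)
  representation <- match.arg(representation)
  trainSets <- switch(scenario,
    sc1 = {
      if (is.null(simulated)) stop("sc1 requires 'simulated'")
      if (is.null(augmented)) list(simulated) else list(simulated, augmented)
    },
    sc2 = {
      if (is.null(clinicalTrain)) stop("sc2 requires 'clinicalTrain'")
      list(clinicalTrain)
    },
    sc3 = {
      if (is.null(clinicalTrain) || is.null(simulated))
        stop("sc3 requires 'clinicalTrain' and 'simulated'")
      list(clinicalTrain, simulated)
    })
  if (length(tests) == 0L) stop("at least one test set is required")
  if (is.null(names(tests)) || any(names(tests) == ""))
    names(tests) <- paste0("test", seq_along(tests))

  trainIds <- unlist(lapply(trainSets, recordIds))
  for (nm in names(tests)) {
    if (any(recordIds(tests[[nm]]) %in% trainIds))
      stop(sprintf("test set '%s' overlaps the training data", nm))
  }

  repFun <- if (representation == "raw10") {
    function(ds) extractRawMatrix(ds, nBins = nBins,
                                  useTrueFiducials = useTrueFiducials)
  } else {
    function(ds) extractFeatureMatrix(ds,
                                      useTrueFiducials = useTrueFiducials)
  }
  trainReps <- lapply(trainSets, repFun)
  xTrain <- do.call(rbind, lapply(trainReps, `[[`, "x"))
  yTrain <- unlist(lapply(trainReps, `[[`, "chamber"))
  wTrain <- unlist(lapply(trainReps, `[[`, "weights"))
  useWeights <- scenario == "sc1" && !is.null(augmented)
  w <- if (useWeights) wTrain else NULL

  topFeatures <- NULL
  if (representation == "top10") {
    rk <- rankFeaturesExtraTrees(xTrain, yTrain, seed = .childSeed(seed, "rank"))
    topFeatures <- utils::head(rk$feature, nTop)
    xTrain <- xTrain[, topFeatures, drop = FALSE]
  }

  cv <- crossValidate(xTrain, yTrain, folds = folds,
                      seed = .childSeed(seed, "cv"), C = C, gamma = gamma,
                      weights = w)
  model <- trainSvm(xTrain, yTrain, C = C, gamma = gamma, weights = w)

  testResults <- lapply(tests, function(ds) {
    rep <- repFun(ds)
    xt <- rep$x
    if (!is.null(topFeatures)) xt <- xt[, topFeatures, drop = FALSE]
    pred <- predict(model, xt)
    list(balancedAccuracy = balancedAccuracy(rep$chamber, pred),
         confusion = .confusion2(rep$chamber, pred),
         n = nrow(xt))
  })

  methods::new("ScenarioResult",
    scenario = scenario, representation = representation,
    cvAccuracy = cv$cvAccuracy, foldAccuracies = cv$foldAccuracies,
    testResults = testResults, trainSize = nrow(xTrain),
    seed = as.integer(seed),
    spec = list(C = C, gamma = gamma, folds = folds, nTop = nTop,
                nBins = nBins, weighted = useWeights,
                topFeatures = topFeatures))
}
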