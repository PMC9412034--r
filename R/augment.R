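#' Mixup configuration
#'
#' Hyperparameters of the mixup augmentation stage. The defaults are the
#' adopted study values: `lambda ~ Beta(5, 1.5)` and three augmented
#' samples per original (7,488 from a 2,496-record database).
#'
#' @param alpha,beta positive Beta shape parameters.
#' @param ratio augmented samples per original record (>= 1).
#' @param labelMode `"chamber"` (unconstrained pairing) or
#'   `"sublocation"` (pairing restricted to anatomical neighbors).
#' @param seed integer seed.
#' @return validated list of class `"MixupConfig"`.
#' @export
mixupConfig <- function(alpha = 5, beta = 1.5, ratio = 3L,
                        labelMode = c("chamber", "sublocation"),
                        seed = 1L) {
  .assertScalarNumber(alpha, "alpha", lower = 1e-12)
  .assertScalarNumber(beta, "beta", lower = 1e-12)
  .assertScalarNumber(ratio, "ratio", lower = 1)
  labelMode <- match.arg(labelMode)
  structure(list(alpha = alpha, beta = beta, ratio = as.integer(ratio),
                 labelMode = labelMode, seed = as.integer(seed)),
            class = "MixupConfig")
}

#' Default sublocation adjacency graph
#'
#' Undirected edges over the nine sublocations following standard
#' outflow-tract anatomy; no cross-chamber edges. LVOT: the cusp chain
#' LCC - commissure - RCC with NCC adjacent to both LCC and RCC, AMC
#' adjacent to LCC and NCC, and the LV summit adjacent to LCC and RCC.
#' RVOT: anteroseptal, posteroseptal and free-wall sites mutually
#' adjacent.
#'
#' @return data.frame with columns `from`, `to` (one row per undirected
#'   edge).
#' @export
defaultAdjacencyGraph <- function() {
  data.frame(
    from = c("LCC", "LCC-RCC-commissure", "RCC", "LCC", "AMC", "AMC",
             "LV-summit", "LV-summit",
             "anteroseptal-RV", "anteroseptal-RV", "posteroseptal-RV"),
    to = c("LCC-RCC-commissure", "RCC", "NCC", "NCC", "LCC", "NCC",
           "LCC", "RCC",
           "posteroseptal-RV", "RFW", "RFW"),
    stringsAsFactors = FALSE)
}

.validateGraph <- function(graph) {
  if (!is.data.frame(graph) || !all(c("from", "to") %in% names(graph)))
    stop("'graph' must be a data.frame with columns from, to")
  labs <- sublocationLevels()
  if (!all(c(graph$from, graph$to) %in% labs))
    stop("graph references unknown sublocations")
  if (any(graph$from == graph$to)) stop("graph must have no self-loops")
  deg <- table(factor(c(graph$from, graph$to), levels = labs))
  if (any(deg == 0))
    stop(sprintf("sublocation '%s' has no neighbor",
                 names(deg)[deg == 0][1L]))
  invisible(graph)
}

# symmetric neighbor sets (including the sublocation itself)
.neighborSets <- function(graph) {
  labs <- sublocationLevels()
  sets <- stats::setNames(lapply(labs, function(s) {
    unique(c(s, graph$to[graph$from == s], graph$from[graph$to == s]))
  }), labs)
  sets
}

#' Mix one pair of beats
#'
#' Elementwise convex combination `xHat = lambda * xi + (1 - lambda) *
#' xj`; the label of the dominant parent is adopted (`yi` iff
#' `lambda > 0.5`) and `lambda` is kept as the sample weight for the
#' classifier.
#'
#' @param xi,xj numeric matrices of identical shape (12-lead QRS).
#' @param yi,yj parent labels.
#' @param lambda mixing weight in `[0, 1]`.
#' @return list with `xHat`, `label`, `lambda`.
#' @export
#' @examples
#' m <- mixupPair(matrix(1, 2, 2), matrix(0, 2, 2), "A", "B", 0.3)
#' m$label  # "B": the second parent dominates
mixupPair <- function(xi, xj, yi, yj, lambda) {
  if (!is.matrix(xi) || !is.matrix(xj) || !all(dim(xi) == dim(xj)))
    stop("'xi' and 'xj' must be matrices of identical shape")
  .assertScalarNumber(lambda, "lambda", lower = 0, upper = 1)
  list(xHat = lambda * xi + (1 - lambda) * xj,
       label = if (lambda > 0.5) yi else yj,
       lambda = lambda)
}

#' Mixup augmentation of a dataset
#'
#' Draws `ratio * nRecords(dataset)` augmented beats. For each, the
#' first parent is sampled uniformly; in `"chamber"` mode the second
#' parent is any other record, in `"sublocation"` mode it is restricted
#' to records whose sublocation is the first parent's own or one of its
#' neighbors in `graph`. `lambda ~ Beta(alpha, beta)` per sample; the
#' adopted parent supplies all labels and the mixed beat's R peak, the
#' QRS window is the union of the parents' windows, and `lambda` is
#' stored as the record weight.
#'
#' @param dataset an [ECGDataset-class] with at least two records.
#' @param config a [mixupConfig()].
#' @param graph adjacency data.frame (columns `from`, `to`); default
#'   [defaultAdjacencyGraph()].
#' @return An [ECGDataset-class] with provenance `"augmented"`; the
#'   metadata holds a `parents` data.frame (parent ids, lambda, adopted
#'   parent) for auditing.
#' @export
augmentDataset <- function(dataset, config = mixupConfig(),
                           graph = defaultAdjacencyGraph()) {
  stopifnot(is(dataset, "ECGDataset"), inherits(config, "MixupConfig"))
  .validateGraph(graph)
  recs <- dataset@records
  n <- length(recs)
  if (n < 2L) stop("mixup needs at least two records")
  subs <- sublocationLabels(dataset)
  if (config$labelMode == "sublocation") {
    nb <- .neighborSets(graph)
    pools <- lapply(seq_len(n), function(i) {
      p <- setdiff(which(subs %in% nb[[subs[i]]]), i)
      if (length(p) == 0L)
        stop(sprintf(
          "sublocation '%s' is isolated: no neighboring records to mix with",
          subs[i]))
      p
    })
  }
  nOut <- config$ratio * n
  out <- vector("list", nOut)
  parents <- data.frame(i = integer(nOut), j = integer(nOut),
                        lambda = numeric(nOut), adopted = integer(nOut))
  .withSeed(.childSeed(config$seed, "mixup"), {
    for (k in seq_len(nOut)) {
      i <- sample.int(n, 1L)
      j <- if (config$labelMode == "sublocation") {
        p <- pools[[i]]
        p[sample.int(length(p), 1L)]
      } else {
        jj <- sample.int(n - 1L, 1L)
        if (jj >= i) jj + 1L else jj
      }
      lam <- stats::rbeta(1L, config$alpha, config$beta)
      ri <- recs[[i]]; rj <- recs[[j]]
      adopted <- if (lam > 0.5) ri else rj
      mixed <- lam * ri@signal + (1 - lam) * rj@signal
      rec <- methods::new("ECGRecord",
        signal = mixed, fs = ri@fs, chamber = adopted@chamber,
        sublocation = adopted@sublocation, anatomyId = adopted@anatomyId,
        electrodeConfigId = adopted@electrodeConfigId,
        qrsOnset = min(ri@qrsOnset, rj@qrsOnset),
        qrsOffset = max(ri@qrsOffset, rj@qrsOffset),
        rPeak = adopted@rPeak,
        recordId = sprintf("aug_%06d", k), weight = lam)
      out[[k]] <- rec
      parents$i[k] <- i; parents$j[k] <- j
      parents$lambda[k] <- lam
      parents$adopted[k] <- if (lam > 0.5) i else j
    }
  })
  methods::new("ECGDataset", records = out, provenance = "augmented",
               metadata = list(config = unclass(config), parents = parents,
                               sourceProvenance = dataset@provenance))
}
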