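#' @import methods
NULL

#' ECGRecord: a single 12-lead beat
#'
#' Container for one 12-lead QRS complex. The signal is a 12 x T matrix in
#' millivolts with rows in the fixed order [leadNames()]. Ground-truth QRS
#' fiducials are stored as 1-based sample positions with a half-open QRS
#' window `[qrsOnset, qrsOffset)`; `qrsOffset` may therefore be `T + 1`
#' when the complex runs to the final sample.
#'
#' @slot signal numeric matrix, 12 leads x T samples (mV).
#' @slot fs sampling rate in Hz.
#' @slot chamber `"LVOT"` or `"RVOT"`.
#' @slot sublocation one of [sublocationLevels()], consistent with the
#'   chamber.
#' @slot anatomyId,electrodeConfigId integer design-cell identifiers.
#' @slot qrsOnset,qrsOffset,rPeak 1-based sample indices with
#'   `qrsOnset < rPeak < qrsOffset`.
#' @slot recordId unique record identifier.
#' @slot weight sample weight (1 for originals, mixup lambda for
#'   augmented beats).
#' @exportClass ECGRecord
setClass("ECGRecord",
  representation(
    signal = "matrix",
    fs = "numeric",
    chamber = "character",
    sublocation = "character",
    anatomyId = "integer",
    electrodeConfigId = "integer",
    qrsOnset = "integer",
    qrsOffset = "integer",
    rPeak = "integer",
    recordId = "character",
    weight = "numeric"
  ),
  prototype(weight = 1)
)

setValidity("ECGRecord", function(object) {
  msg <- character()
  sig <- object@signal
  if (!is.numeric(sig) || nrow(sig) != 12L)
    msg <- c(msg, "signal must be a numeric 12 x T matrix")
  if (!identical(rownames(sig), leadNames()))
    msg <- c(msg, "signal rows must be named and ordered as leadNames()")
  if (anyNA(sig)) msg <- c(msg, "signal contains missing samples")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (!(object@chamber %in% chamberLevels()))
    msg <- c(msg, "chamber must be 'LVOT' or 'RVOT'")
  if (!(object@sublocation %in% sublocationLevels())) {
    msg <- c(msg, sprintf("unknown sublocation '%s'", object@sublocation))
  } else if (unname(sublocationChamber()[object@sublocation]) != object@chamber) {
    msg <- c(msg, sprintf("sublocation '%s' is inconsistent with chamber '%s'",
                          object@sublocation, object@chamber))
  }
  n <- ncol(sig)
  on <- object@qrsOnset; off <- object@qrsOffset; r <- object@rPeak
  if (length(on) != 1L || length(off) != 1L || length(r) != 1L ||
      is.na(on) || is.na(off) || is.na(r) ||
      on < 1L || on >= r || r >= off || off > n + 1L)
    msg <- c(msg, "fiducials must satisfy 1 <= onset < rPeak < offset <= T + 1")
  if (length(object@weight) != 1L || is.na(object@weight) || object@weight < 0)
    msg <- c(msg, "weight must be a nonnegative scalar")
  if (length(msg)) msg else TRUE
})

#' ECGDataset: a collection of ECGRecord objects
#'
#' All records share the sampling rate and the fixed lead order.
#' `metadata` echoes the generator or augmentation configuration that
#' produced the dataset, plus per-record provenance tables for augmented
#' datasets.
#'
#' @slot records list of [ECGRecord-class] objects.
#' @slot provenance `"simulated_style"`, `"clinical_like"`, `"augmented"`
#'   or `"user"`.
#' @slot metadata named list.
#' @exportClass ECGDataset
setClass("ECGDataset",
  representation(records = "list", provenance = "character",
                 metadata = "list"),
  prototype(records = list(), provenance = "user", metadata = list())
)

setValidity("ECGDataset", function(object) {
  msg <- character()
  if (!(object@provenance %in%
        c("simulated_style", "clinical_like", "augmented", "user")))
    msg <- c(msg, "unknown provenance")
  if (length(object@records)) {
    if (!all(vapply(object@records, is, logical(1L), "ECGRecord")))
      msg <- c(msg, "records must all be ECGRecord objects")
    else {
      fss <- vapply(object@records, function(r) r@fs, numeric(1L))
      if (length(unique(fss)) != 1L)
        msg <- c(msg, "all records must share the sampling rate")
    }
  }
  if (length(msg)) msg else TRUE
})

#' QRSSegment: a normalized, R-peak-aligned QRS window
#'
#' @slot signal numeric 12 x L matrix, global max-abs equal to 1.
#' @slot fs sampling rate in Hz.
#' @slot rIndex 1-based position of the R peak inside the window.
#' @slot sourceRecordId id of the originating record.
#' @exportClass QRSSegment
setClass("QRSSegment",
  representation(signal = "matrix", fs = "numeric", rIndex = "integer",
                 sourceRecordId = "character"))

setValidity("QRSSegment", function(object) {
  msg <- character()
  sig <- object@signal
  if (nrow(sig) != 12L || !identical(rownames(sig), leadNames()))
    msg <- c(msg, "signal must be 12 x L with leadNames() rows")
  m <- max(abs(sig))
  if (!is.finite(m) || abs(m - 1) > 1e-9)
    msg <- c(msg, "global max-abs of a QRSSegment must equal 1")
  if (object@rIndex < 1L || object@rIndex > ncol(sig))
    msg <- c(msg, "rIndex out of range")
  if (length(msg)) msg else TRUE
})

#' DownsampledBeat: bin-mean representation of a QRS segment
#'
#' Each lead is reduced to `nBins` contiguous bin means (the "raw10"
#' pseudo-features when `nBins = 10`).
#'
#' @slot values numeric 12 x nBins matrix of bin means.
#' @slot binEdges integer vector of 1-based bin start positions, plus the
#'   exclusive end position as last element (length nBins + 1).
#' @exportClass DownsampledBeat
setClass("DownsampledBeat",
  representation(values = "matrix", binEdges = "integer"))

setValidity("DownsampledBeat", function(object) {
  msg <- character()
  if (nrow(object@values) != 12L ||
      !identical(rownames(object@values), leadNames()))
    msg <- c(msg, "values must be 12 x nBins with leadNames() rows")
  if (length(object@binEdges) != ncol(object@values) + 1L)
    msg <- c(msg, "binEdges must have nBins + 1 entries")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' ScenarioResult: one trained-and-evaluated classification scenario
#'
#' @slot scenario `"sc1"`, `"sc2"` or `"sc3"`.
#' @slot representation `"raw10"`, `"features"` or `"top10"`.
#' @slot cvAccuracy mean plain accuracy over the stratified CV folds.
#' @slot foldAccuracies per-fold accuracies.
#' @slot testResults list per test set: balanced accuracy and a 2 x 2
#'   confusion table of counts.
#' @slot trainSize number of training samples.
#' @slot seed the seed used.
#' @slot spec echo of the model / scenario configuration.
#' @exportClass ScenarioResult
setClass("ScenarioResult",
  representation(scenario = "character", representation = "character",
                 cvAccuracy = "numeric", foldAccuracies = "numeric",
                 testResults = "list", trainSize = "integer",
                 seed = "integer", spec = "list"))

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf(
    "ECGRecord '%s': 12 x %d @ %g Hz | %s / %s | anatomy %d, electrodes %d\n",
    object@recordId, ncol(object@signal), object@fs, object@chamber,
    object@sublocation, object@anatomyId, object@electrodeConfigId))
  cat(sprintf("  QRS [%d, %d), R peak at %d, weight %.3f\n",
              object@qrsOnset, object@qrsOffset, object@rPeak, object@weight))
})

setMethod("show", "ECGDataset", function(object) {
  ch <- vapply(object@records, function(r) r@chamber, character(1L))
  cat(sprintf("ECGDataset: %d records (%s) | %d LVOT, %d RVOT\n",
              length(object@records), object@provenance,
              sum(ch == "LVOT"), sum(ch == "RVOT")))
})

setMethod("show", "QRSSegment", function(object) {
  cat(sprintf("QRSSegment from '%s': 12 x %d @ %g Hz, R at %d\n",
              object@sourceRecordId, ncol(object@signal), object@fs,
              object@rIndex))
})

setMethod("show", "ScenarioResult", function(object) {
  cat(sprintf("ScenarioResult %s [%s]: CV accuracy %.3f (n = %d)\n",
              toupper(object@scenario), object@representation,
              object@cvAccuracy, object@trainSize))
  for (nm in names(object@testResults)) {
    cat(sprintf("  test '%s': balanced accuracy %.3f\n", nm,
                object@testResults[[nm]]$balancedAccuracy))
  }
})

#' Accessors for the central classes
#'
#' @param x an [ECGDataset-class], [ECGRecord-class], [QRSSegment-class]
#'   or [DownsampledBeat-class] object.
#' @param i record index.
#' @return `nRecords()` the number of records; `getRecord()` one
#'   [ECGRecord-class]; `records()` the record list; `provenance()` the
#'   provenance string; `signalMatrix()` the numeric signal/values matrix;
#'   `chamberLabels()`/`sublocationLabels()`/`sampleWeights()` per-record
#'   label and weight vectors.
#' @export
nRecords <- function(x) length(x@records)

#' @rdname nRecords
#' @export
getRecord <- function(x, i) x@records[[i]]

#' @rdname nRecords
#' @export
records <- function(x) x@records

#' @rdname nRecords
#' @export
provenance <- function(x) x@provenance

#' @rdname nRecords
#' @export
signalMatrix <- function(x) {
  if (is(x, "DownsampledBeat")) x@values else x@signal
}

#' @rdname nRecords
#' @export
chamberLabels <- function(x) {
  vapply(x@records, function(r) r@chamber, character(1L))
}

#' @rdname nRecords
#' @export
sublocationLabels <- function(x) {
  vapply(x@records, function(r) r@sublocation, character(1L))
}

#' @rdname nRecords
#' @export
sampleWeights <- function(x) {
  vapply(x@records, function(r) r@weight, numeric(1L))
}

#' @rdname nRecords
#' @export
recordIds <- function(x) {
  vapply(x@records, function(r) r@recordId, character(1L))
}
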