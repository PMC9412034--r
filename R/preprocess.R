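#' Wavelet-threshold QRS delineation
#'
#' Detects the QRS onset/offset of a record from scale-2 coefficients of
#' the quadratic-spline wavelet transform. Per-lead scale-2 coefficients
#' are combined into a root-mean-square modulus across leads; the QRS
#' region is where the combined modulus exceeds `peakFrac` of its
#' maximum. The onset is the last sub-threshold sample (below
#' `boundFrac` of the maximum modulus) before the first supra-`peakFrac`
#' sample, the offset the first sub-threshold sample after the last, so
#' the returned window is half-open `[onset, offset)`.
#'
#' @param record an [ECGRecord-class].
#' @param peakFrac relative threshold defining the QRS core region.
#' @param boundFrac relative threshold defining the onset/offset
#'   boundary.
#' @return named integer vector `c(onset, offset)` (1-based; half-open).
#' @export
delineateQrs <- function(record, peakFrac = 0.25, boundFrac = 0.05) {
  stopifnot(is(record, "ECGRecord"))
  sig <- record@signal
  if (max(abs(sig)) == 0) stop("no QRS found: flat (all-zero) signal")
  nT <- ncol(sig)
  w2 <- vapply(seq_len(12L), function(l)
    waveletTransform(sig[l, ], scales = 2L)$coefficients$s2,
    numeric(nT))
  combined <- sqrt(rowMeans(w2^2))
  m <- max(combined)
  if (m == 0) stop("no QRS found: flat (all-zero) signal")
  core <- which(combined >= peakFrac * m)
  sub <- combined < boundFrac * m
  before <- which(sub & seq_len(nT) < min(core))
  onset <- if (length(before)) max(before) else 1L
  after <- which(sub & seq_len(nT) > max(core))
  offset <- if (length(after)) min(after) else nT + 1L
  c(onset = as.integer(onset), offset = as.integer(offset))
}

#' Normalize, baseline-correct and R-align a QRS window
#'
#' Pipeline contract for every downstream representation: per-lead
#' baseline (mean of the 10 ms preceding the onset; zero when no such
#' samples exist) is subtracted, the QRS window is centered on the R
#' peak in a fixed window of `windowMs`, zero-padded where the window
#' extends past `[onset, offset)`, and the result is divided by its
#' global (across-lead) max-abs so inter-lead amplitude ratios are
#' preserved. Set `perLead = TRUE` for independent per-lead max-abs
#' scaling instead.
#'
#' The operation is idempotent and invariant to a global gain.
#'
#' @param record an [ECGRecord-class].
#' @param onset,offset half-open QRS window (1-based); default to the
#'   record's stored fiducials.
#' @param windowMs output window length, ms.
#' @param perLead logical; per-lead instead of global normalization.
#' @return A [QRSSegment-class] of length `round(windowMs * fs / 1000)`.
#' @export
normalizeAndAlign <- function(record, onset = record@qrsOnset,
                              offset = record@qrsOffset, windowMs = 160,
                              perLead = FALSE) {
  stopifnot(is(record, "ECGRecord"))
  sig <- record@signal
  nT <- ncol(sig)
  onset <- as.integer(onset); offset <- as.integer(offset)
  if (onset < 1L || offset <= onset || offset > nT + 1L)
    stop("invalid QRS window")
  fs <- record@fs
  nBase <- max(1L, round(10 * fs / 1000))
  b0 <- max(1L, onset - nBase)
  baseline <- if (onset > 1L)
    rowMeans(sig[, b0:(onset - 1L), drop = FALSE])
  else rep(0, 12L)
  x <- sig - baseline

  # R peak inside the window
  rp <- record@rPeak
  if (rp < onset || rp >= offset) {
    env <- apply(abs(x[, onset:(offset - 1L), drop = FALSE]), 2L, max)
    rp <- onset + which.max(env) - 1L
  }

  L <- as.integer(round(windowMs * fs / 1000))
  half <- L %/% 2L
  out <- matrix(0, nrow = 12L, ncol = L, dimnames = list(leadNames(), NULL))
  # source samples restricted to the QRS window [onset, offset)
  src <- (rp - half):(rp - half + L - 1L)
  keep <- src >= onset & src < offset & src >= 1L & src <= nT
  out[, which(keep)] <- x[, src[keep], drop = FALSE]

  if (perLead) {
    ml <- apply(abs(out), 1L, max)
    if (all(ml == 0)) stop("degenerate signal: zero max-abs in QRS window")
    ml[ml == 0] <- 1
    out <- out / ml
  } else {
    m <- max(abs(out))
    if (m == 0) stop("degenerate signal: zero max-abs in QRS window")
    out <- out / m
  }
  methods::new("QRSSegment", signal = out, fs = fs,
               rIndex = half + 1L, sourceRecordId = record@recordId)
}

#' Bin-mean downsampling of a QRS segment
#'
#' Splits each lead's `L` samples into `nBins` contiguous near-equal
#' bins (any remainder goes to the leading bins, a deterministic
#' tie-break) and takes the arithmetic mean per bin, producing the
#' low-dimensional pseudo-feature representation in which each value is
#' the mean electrical potential over a time interval.
#'
#' @param segment a [QRSSegment-class], or a numeric matrix with 12
#'   [leadNames()] rows.
#' @param nBins number of bins (default 10); requires `L >= nBins`.
#' @return A [DownsampledBeat-class] (12 x nBins).
#' @export
#' @examples
#' seg <- matrix(rep(seq(0, 1, length.out = 100), each = 12), nrow = 12,
#'               dimnames = list(leadNames(), NULL))
#' signalMatrix(downsampleBins(seg / max(seg), nBins = 10))[1, ]
downsampleBins <- function(segment, nBins = 10L) {
  x <- if (is(segment, "QRSSegment")) segment@signal else segment
  if (!is.matrix(x) || nrow(x) != 12L)
    stop("'segment' must be a QRSSegment or a 12-row matrix")
  if (is.null(rownames(x))) rownames(x) <- leadNames()
  nBins <- as.integer(nBins)
  L <- ncol(x)
  if (nBins < 1L) stop("'nBins' must be >= 1")
  if (L < nBins) stop(sprintf("segment too short: L = %d < nBins = %d",
                              L, nBins))
  base <- L %/% nBins
  rem <- L %% nBins
  sizes <- rep(base, nBins) + c(rep(1L, rem), rep(0L, nBins - rem))
  edges <- cumsum(c(1L, sizes))
  vals <- matrix(0, nrow = 12L, ncol = nBins,
                 dimnames = list(rownames(x), NULL))
  for (b in seq_len(nBins)) {
    vals[, b] <- rowMeans(x[, edges[b]:(edges[b + 1L] - 1L), drop = FALSE])
  }
  methods::new("DownsampledBeat", values = vals,
               binEdges = as.integer(edges))
}

#' Raw bin-mean matrix for a dataset
#'
#' Runs every record through [normalizeAndAlign()] and
#' [downsampleBins()] and flattens the result lead-by-lead into a
#' samples x (12 * nBins) matrix with columns `raw.<lead>.b<k>`; the
#' "raw10" representation at the default `nBins = 10`.
#'
#' @param dataset an [ECGDataset-class].
#' @param nBins bins per lead.
#' @param useTrueFiducials use the records' stored onset/offset (the
#'   generator ground truth) instead of [delineateQrs()].
#' @param windowMs alignment window, ms.
#' @return list with `x` (numeric matrix), `chamber`, `sublocation`,
#'   `weights`, `recordIds`.
#' @export
extractRawMatrix <- function(dataset, nBins = 10L, useTrueFiducials = TRUE,
                             windowMs = 160) {
  stopifnot(is(dataset, "ECGDataset"))
  recs <- dataset@records
  if (!length(recs)) stop("empty dataset")
  nBins <- as.integer(nBins)
  cols <- as.vector(t(outer(leadNames(), seq_len(nBins),
                            function(l, b) sprintf("raw.%s.b%d", l, b))))
  x <- matrix(NA_real_, nrow = length(recs), ncol = 12L * nBins,
              dimnames = list(NULL, cols))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    fid <- if (useTrueFiducials) c(rec@qrsOnset, rec@qrsOffset)
           else delineateQrs(rec)
    seg <- normalizeAndAlign(rec, fid[1L], fid[2L], windowMs = windowMs)
    ds <- downsampleBins(seg, nBins = nBins)
    x[i, ] <- as.vector(t(ds@values))
  }
  list(x = x, chamber = chamberLabels(dataset),
       sublocation = sublocationLabels(dataset),
       weights = sampleWeights(dataset), recordIds = recordIds(dataset))
}
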