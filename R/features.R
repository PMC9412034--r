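#' Within-group lead comparison pairs
#'
#' Comparative features are only computed inside three lead groups —
#' limb (I, II, III), augmented (aVR, aVL, aVF) and precordial (V1-V6) —
#' giving 3 + 3 + 15 = 21 ordered pairs per comparative feature.
#'
#' @param groups subset of `c("limb", "augmented", "precordial")`.
#' @return data.frame with columns `a`, `b` (leads, `a` before `b` in
#'   [leadNames()] order).
#' @export
#' @examples
#' nrow(comparisonPairs())
comparisonPairs <- function(groups = c("limb", "augmented", "precordial")) {
  groups <- match.arg(groups, several.ok = TRUE)
  sets <- list(limb = .limbLeads(), augmented = .augmentedLeads(),
               precordial = .precordialLeads())
  out <- do.call(rbind, lapply(groups, function(g) {
    cc <- utils::combn(sets[[g]], 2L)
    data.frame(a = cc[1L, ], b = cc[2L, ], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# transition code from the six precordial signed maxima:
# k = 0-based index of the first lead (V2 onward) whose signed-maximum
# polarity differs from V1's, coded k/5 in [0, 1]; 1.0 when no change
# (sentinel). A zero signed maximum counts as positive polarity.
.transitionCode <- function(sm6) {
  pol <- ifelse(sm6 >= 0, 1, -1)
  chg <- which(pol[-1L] != pol[1L])
  if (length(chg) == 0L) return(1.0)
  unname(chg[1L]) / 5
}

#' Precordial transition code
#'
#' Retrieves the signed maximum of each precordial lead and codes the
#' first lead at which the QRS polarity differs from V1's as a decimal
#' between 0 (V1) and 1 (V6); 1.0 also serves as the no-transition
#' sentinel. An earlier transition is the classical marker of an LVOT
#' origin.
#'
#' @param segment a [QRSSegment-class] or 12-row signal matrix.
#' @return number in `[0, 1]`.
#' @export
precordialTransition <- function(segment) {
  x <- if (is(segment, "QRSSegment")) segment@signal else segment
  if (!is.matrix(x) || nrow(x) != 12L)
    stop("'segment' must be a QRSSegment or a 12-row matrix")
  if (is.null(rownames(x))) rownames(x) <- leadNames()
  sm <- vapply(.precordialLeads(), function(l) .signedMax(x[l, ]),
               numeric(1L))
  .transitionCode(sm)
}

#' Signal-based feature family
#'
#' Two all-lead features (QRS total activation time in ms and the
#' precordial transition), eight per-lead features (polarity of the
#' signed maximum, max and min voltage, signed and unsigned absolute
#' maximum, amplitude, raw and absolute trapezoidal area) and three
#' comparative features per pair (signed maximum of the lead
#' difference, area of the difference, zero-lag normalized
#' cross-correlation): 2 + 8 x 12 + 3 x 21 = 161 values.
#'
#' @param segment a [QRSSegment-class].
#' @param onset,offset the record-level QRS window used for the duration
#'   (1-based, half-open).
#' @return named numeric vector (161 entries).
#' @export
extractSignalFeatures <- function(segment, onset, offset) {
  stopifnot(is(segment, "QRSSegment"))
  x <- segment@signal
  fs <- segment@fs
  out <- c(signal.qrsDuration = (offset - onset) / fs * 1000,
           signal.precordialTransition = precordialTransition(segment))
  perLead <- function(feat, fun) {
    v <- vapply(leadNames(), function(l) fun(x[l, ]), numeric(1L))
    names(v) <- sprintf("signal.%s.%s", feat, leadNames())
    v
  }
  out <- c(out,
    perLead("polarity", function(v) if (.signedMax(v) >= 0) 1 else -1),
    perLead("vmax", max),
    perLead("vmin", min),
    perLead("maxAbsSigned", .signedMax),
    perLead("maxAbs", function(v) max(abs(v))),
    perLead("amplitude", function(v) max(v) - min(v)),
    perLead("area", .trapz),
    perLead("absArea", function(v) .trapz(abs(v))))
  pairs <- comparisonPairs()
  comp <- function(feat, fun) {
    v <- mapply(function(a, b) fun(x[a, ], x[b, ]), pairs$a, pairs$b)
    names(v) <- sprintf("signal.%s.%s_%s", feat, pairs$a, pairs$b)
    v
  }
  c(out,
    comp("diffMax", function(a, b) .signedMax(a - b)),
    comp("diffArea", function(a, b) .trapz(a - b)),
    comp("xcorr", .xcorr0))
}

#' Wavelet-based feature family
#'
#' Computed on scale-1 coefficients only (coarser scales serve fiducial
#' propagation): one all-lead feature (wavelet precordial transition
#' from scale-1 signed maxima), six per-lead features (max, min and
#' mean coefficient amplitude, area under the curve, fragmentation =
#' raw area / absolute area, and the R/S amplitude ratio from the
#' detected fiducials) and three comparative features per pair (area of
#' difference, maximum difference, cross-correlation):
#' 1 + 6 x 12 + 3 x 21 = 136 values.
#'
#' An absent S fiducial is imputed with an S amplitude floored at 1e-3
#' (the amplitude resolution of the normalized segment) so the vector
#' stays finite and NaN-free.
#'
#' @param segment a [QRSSegment-class].
#' @param decomps list of 12 per-lead [waveletTransform()] results.
#' @param fiducials list of 12 per-lead [detectFiducials()] results (or
#'   `NULL` entries when detection failed).
#' @return named numeric vector (136 entries).
#' @export
extractWaveletFeatures <- function(segment, decomps, fiducials) {
  stopifnot(is(segment, "QRSSegment"), length(decomps) == 12L,
            length(fiducials) == 12L)
  w1 <- vapply(decomps, function(d) d$coefficients$s1,
               numeric(ncol(segment@signal)))
  colnames(w1) <- leadNames()
  smPrec <- vapply(.precordialLeads(), function(l) .signedMax(w1[, l]),
                   numeric(1L))
  out <- c(wavelet.precordialTransition = .transitionCode(smPrec))

  floorAmp <- 1e-3
  rs <- vapply(seq_len(12L), function(l) {
    f <- fiducials[[l]]
    if (is.null(f) || is.na(f$rPeak)) return(0)
    rA <- abs(segment@signal[l, f$rPeak])
    sA <- if (is.na(f$sPeak)) floorAmp
          else max(abs(segment@signal[l, f$sPeak]), floorAmp)
    rA / sA
  }, numeric(1L))

  perLead <- function(feat, vals) {
    names(vals) <- sprintf("wavelet.%s.%s", feat, leadNames())
    vals
  }
  area <- apply(w1, 2L, .trapz)
  absArea <- apply(w1, 2L, function(v) .trapz(abs(v)))
  frag <- ifelse(absArea == 0, 0, area / absArea)
  out <- c(out,
    perLead("wmax", apply(w1, 2L, max)),
    perLead("wmin", apply(w1, 2L, min)),
    perLead("wmean", colMeans(w1)),
    perLead("area", area),
    perLead("fragmentation", frag),
    perLead("rsRatio", rs))
  pairs <- comparisonPairs()
  comp <- function(feat, fun) {
    v <- mapply(function(a, b) fun(w1[, a], w1[, b]), pairs$a, pairs$b)
    names(v) <- sprintf("wavelet.%s.%s_%s", feat, pairs$a, pairs$b)
    v
  }
  c(out,
    comp("diffArea", function(a, b) .trapz(a - b)),
    comp("diffMax", function(a, b) max(a - b)),
    comp("xcorr", .xcorr0))
}

.spectralBands <- function() {
  cbind(lo = c(0, 3, 6, 9, 12, 25), hi = c(3, 6, 9, 12, 25, 50))
}

#' Spectral feature family
#'
#' Seven per-lead features from the Welch power spectral density of the
#' QRS window: the fundamental frequency (argmax of power) and six band
#' powers averaged over \[0,3), \[3,6), \[6,9), \[9,12), \[12,25) and
#' \[25,50) Hz: 7 x 12 = 84 values.
#'
#' @param segment a [QRSSegment-class] (used for lead naming only).
#' @param spectra list of 12 per-lead [welchPsd()] results.
#' @return named numeric vector (84 entries).
#' @export
extractSpectralFeatures <- function(segment, spectra) {
  stopifnot(length(spectra) == 12L)
  bands <- .spectralBands()
  out <- numeric(0)
  for (l in seq_len(12L)) {
    ps <- spectra[[l]]
    if (max(ps$frequencies) < 50)
      stop("spectral bands unresolvable: fs / 2 < 50 Hz")
    fund <- ps$frequencies[which.max(ps$power)]
    bp <- vapply(seq_len(nrow(bands)), function(b) {
      sel <- ps$frequencies >= bands[b, "lo"] & ps$frequencies < bands[b, "hi"]
      if (!any(sel)) 0 else mean(ps$power[sel])
    }, numeric(1L))
    v <- c(fund, bp)
    names(v) <- sprintf("spectral.%s.%s",
                        c("fundamental", sprintf("band%g_%g", bands[, "lo"],
                                                 bands[, "hi"])),
                        leadNames()[l])
    out <- c(out, v)
  }
  out
}

# full 381-entry vector for one record
.featureVectorForRecord <- function(rec, useTrueFiducials = TRUE,
                                    windowMs = 160) {
  fid <- if (useTrueFiducials) c(rec@qrsOnset, rec@qrsOffset)
         else delineateQrs(rec)
  seg <- normalizeAndAlign(rec, fid[1L], fid[2L], windowMs = windowMs)
  decomps <- lapply(seq_len(12L), function(l)
    waveletTransform(seg@signal[l, ], scales = 1:4))
  fids <- lapply(decomps, function(d)
    tryCatch(detectFiducials(d, rHint = seg@rIndex), error = function(e) NULL))
  spectra <- lapply(seq_len(12L), function(l)
    welchPsd(seg@signal[l, ], fs = seg@fs))
  c(extractSignalFeatures(seg, fid[1L], fid[2L]),
    extractWaveletFeatures(seg, decomps, fids),
    extractSpectralFeatures(seg, spectra))
}

#' Feature matrix for a dataset
#'
#' Runs the full signal / wavelet / spectral battery on every record and
#' assembles a fixed-column-order table (381 canonical features named
#' `<family>.<feature>[.<lead>|.<leadA>_<leadB>]`) with label and weight
#' columns attached. The column order is deterministic across runs and
#' platforms, and every beat yields the complete vector (absent
#' fiducials are imputed, never `NA`).
#'
#' @param dataset an [ECGDataset-class] with a common sampling rate.
#' @param useTrueFiducials use stored ground-truth fiducials instead of
#'   [delineateQrs()].
#' @param windowMs alignment window, ms.
#' @return list with `x` (numeric matrix, rows = beats), `chamber`,
#'   `sublocation`, `weights`, `recordIds`, and `featureNames`.
#' @export
extractFeatureMatrix <- function(dataset, useTrueFiducials = TRUE,
                                 windowMs = 160) {
  stopifnot(is(dataset, "ECGDataset"))
  recs <- dataset@records
  if (!length(recs)) stop("empty dataset")
  fss <- vapply(recs, function(r) r@fs, numeric(1L))
  if (length(unique(fss)) != 1L)
    stop("inconsistent sampling rates across records")
  if (any(vapply(recs, function(r) nrow(r@signal), integer(1L)) != 12L))
    stop("inconsistent lead count across records")
  first <- .featureVectorForRecord(recs[[1L]], useTrueFiducials, windowMs)
  x <- matrix(NA_real_, nrow = length(recs), ncol = length(first),
              dimnames = list(NULL, names(first)))
  x[1L, ] <- first
  if (length(recs) > 1L) {
    for (i in 2L:length(recs)) {
      v <- .featureVectorForRecord(recs[[i]], useTrueFiducials, windowMs)
      if (!identical(names(v), colnames(x)))
        stop("inconsistent feature naming across records")
      x[i, ] <- v
    }
  }
  if (anyNA(x)) stop("internal error: NA in feature matrix")
  list(x = x, chamber = chamberLabels(dataset),
       sublocation = sublocationLabels(dataset),
       weights = sampleWeights(dataset), recordIds = recordIds(dataset),
       featureNames = colnames(x))
}
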