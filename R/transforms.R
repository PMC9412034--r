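#' Undecimated quadratic-spline wavelet transform
#'
#' Stationary (a-trous) wavelet decomposition with the
#' derivative-of-smoothing quadratic-spline mother wavelet classically
#' used for QRS analysis. The transform acts as a robust surrogate of the
#' signal's derivative: a positive lobe maps to a positive/negative
#' modulus-maxima pair whose zero crossing marks the lobe peak.
#'
#' The filter bank is applied exactly in the frequency domain
#' (lowpass `H(w) = exp(iw/2) cos^3(w/2)`, highpass
#' `G(w) = 4i exp(iw/2) sin(w/2)`, dyadically dilated per scale) on a
#' mirror-extended copy of the signal, and the accumulated half-sample
#' group delay `(2^j - 1)/2` of each scale is compensated with a phase
#' ramp so every scale stays aligned with the input grid. Output at each
#' scale has the length of the input; the transform is linear and (away
#' from the boundaries) shift-equivariant.
#'
#' @param x numeric signal vector of length `L >= 2^max(scales)`.
#' @param scales integer subset of 1:5.
#' @return A `"WaveletDecomposition"`: list with `coefficients` (named
#'   list `s1`, `s2`, ... of length-L vectors), `scales`, and `L`.
#' @export
#' @examples
#' w <- waveletTransform(sin(seq(0, 2 * pi, length.out = 64)), scales = 1:3)
#' lengths(w$coefficients)
waveletTransform <- function(x, scales = 1:5) {
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be a numeric vector")
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) == 0L || any(scales < 1L) || any(scales > 5L))
    stop("'scales' must be a nonempty subset of 1:5")
  L <- length(x)
  if (L < 2^max(scales))
    stop(sprintf("signal too short: need L >= %d for scale %d",
                 2^max(scales), max(scales)))
  # mirror extension (whole-sample reflection) -> smooth boundaries
  xe <- c(x, rev(x))
  N <- length(xe)
  X <- stats::fft(xe)
  w <- 2 * pi * (0:(N - 1L)) / N
  # wrap to (-pi, pi] so conjugate symmetry is preserved numerically
  w <- ifelse(w > pi, w - 2 * pi, w)
  H <- function(om) exp(1i * om / 2) * cos(om / 2)^3
  G <- function(om) 4i * exp(1i * om / 2) * sin(om / 2)

  out <- vector("list", length(scales))
  names(out) <- paste0("s", scales)
  low <- rep(1 + 0i, N)     # product of H terms up to current level
  lev <- 0L
  for (j in seq_len(max(scales))) {
    filt <- G(2^(j - 1L) * w) * low
    delay <- (2^j - 1) / 2
    filt <- filt * exp(-1i * w * delay)
    if (j %in% scales) {
      wj <- Re(stats::fft(X * filt, inverse = TRUE)) / N
      out[[paste0("s", j)]] <- wj[seq_len(L)]
    }
    low <- low * H(2^(j - 1L) * w)
    lev <- j
  }
  structure(list(coefficients = out, scales = scales, L = L),
            class = "WaveletDecomposition")
}

# local modulus maxima of a coefficient vector above a magnitude floor
.modulusMaxima <- function(v, floorFrac = 0.05) {
  L <- length(v)
  a <- abs(v)
  thr <- floorFrac * max(a)
  idx <- which(a[2:(L - 1L)] >= a[1:(L - 2L)] & a[2:(L - 1L)] >= a[3:L] &
               a[2:(L - 1L)] > thr) + 1L
  # collapse plateaus
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > 1L)]
  idx
}

# zero crossing of v between samples i1 < i2, nearest-sample index
.zeroCross <- function(v, i1, i2) {
  seg <- v[i1:i2]
  s <- sign(seg)
  k <- which(s[-length(s)] * s[-1L] <= 0)
  if (length(k) == 0L) return(as.integer(round((i1 + i2) / 2)))
  k <- k[which.min(abs(k + 0.5 - (length(seg) + 1) / 2))]
  a <- seg[k]; b <- seg[k + 1L]
  frac <- if (a == b) 0.5 else a / (a - b)
  as.integer(round(i1 + k - 1L + frac))
}

#' Locate Q, R and S peaks from multiscale zero crossings
#'
#' Finds the dominant opposite-sign modulus-maxima pair at scale 4 near
#' `rHint`, propagates both maxima down through scales 3, 2, 1, and reads
#' the R peak as the scale-1 zero crossing between the pair. Q and S
#' peaks are read from flanking opposite-sign maxima at scale 1 whose
#' modulus exceeds `qsFrac` of the scale-1 maximum modulus; when no such
#' lobe exists (e.g. a monophasic beat) they are reported as `NA`.
#' Inverted (negative-dominant) beats are handled through the pair's
#' sign pattern and flagged with `polarity = -1`.
#'
#' @param decomp a [waveletTransform()] result containing scales 1:4.
#' @param rHint approximate R-peak sample index.
#' @param qsFrac relative modulus threshold for accepting Q/S lobes.
#' @return list with `qPeak`, `rPeak`, `sPeak` (1-based indices, `NA`
#'   when absent) and `polarity` (+1 upright, -1 inverted).
#' @export
detectFiducials <- function(decomp, rHint, qsFrac = 0.125) {
  stopifnot(inherits(decomp, "WaveletDecomposition"))
  need <- paste0("s", 1:4)
  if (!all(need %in% names(decomp$coefficients)))
    stop("scales 1-4 are required for fiducial detection")
  L <- decomp$L
  w4 <- decomp$coefficients$s4
  mm4 <- .modulusMaxima(w4)
  if (length(mm4) < 2L) stop("no QRS morphology found")
  # candidate opposite-sign consecutive pairs near the hint
  win <- max(20, round(0.25 * L))
  best <- NULL; bestScore <- -Inf
  for (k in seq_len(length(mm4) - 1L)) {
    n1 <- mm4[k]; n2 <- mm4[k + 1L]
    if (sign(w4[n1]) * sign(w4[n2]) >= 0) next
    zc <- (n1 + n2) / 2
    if (abs(zc - rHint) > win) next
    score <- abs(w4[n1]) + abs(w4[n2])
    if (score > bestScore) { bestScore <- score; best <- c(n1, n2) }
  }
  if (is.null(best)) stop("no QRS morphology found")

  # propagate the pair down to scale 1
  refine <- function(n, coarse, fine, radius) {
    mmf <- .modulusMaxima(fine, floorFrac = 0.01)
    cand <- mmf[abs(mmf - n) <= radius & sign(fine[mmf]) == sign(coarse[n])]
    if (length(cand) == 0L) return(n)
    cand[which.max(abs(fine[cand]))]
  }
  n1 <- best[1L]; n2 <- best[2L]
  for (j in c(3L, 2L, 1L)) {
    co <- decomp$coefficients[[paste0("s", j + 1L)]]
    fi <- decomp$coefficients[[paste0("s", j)]]
    n1 <- refine(n1, co, fi, radius = 2^j + 2L)
    n2 <- refine(n2, co, fi, radius = 2^j + 2L)
  }
  if (n1 > n2) { tmp <- n1; n1 <- n2; n2 <- tmp }
  w1 <- decomp$coefficients$s1
  r <- .zeroCross(w1, n1, n2)
  polarity <- if (w1[n1] > 0) 1 else -1

  thr <- qsFrac * max(abs(w1))
  mm1 <- .modulusMaxima(w1, floorFrac = 0.01)
  # Q: nearest opposite-sign maximum before n1 above threshold
  qPeak <- NA_integer_
  cand <- mm1[mm1 < n1 & sign(w1[mm1]) == -sign(w1[n1]) & abs(w1[mm1]) >= thr &
              n1 - mm1 <= max(30, round(0.2 * L))]
  if (length(cand)) qPeak <- .zeroCross(w1, max(cand), n1)
  # S: nearest opposite-sign maximum after n2 above threshold
  sPeak <- NA_integer_
  cand <- mm1[mm1 > n2 & sign(w1[mm1]) == -sign(w1[n2]) & abs(w1[mm1]) >= thr &
              mm1 - n2 <= max(30, round(0.2 * L))]
  if (length(cand)) sPeak <- .zeroCross(w1, n2, min(cand))

  list(qPeak = qPeak, rPeak = as.integer(r), sPeak = sPeak,
       polarity = polarity)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: segments of length `min(256, L)` with
#' 50% overlap, periodic Hann taper, per-segment mean removal, one-sided
#' density scaling (integrating the density over frequency recovers the
#' signal variance, up to taper leakage). Segments shorter than 256
#' samples are zero-padded to that canonical length, so the frequency
#' grid spacing is `fs / 256` regardless of the window length and the
#' low-frequency analysis bands always contain grid points.
#'
#' @param x numeric signal vector, `length(x) >= 16`.
#' @param fs sampling rate, Hz.
#' @return A `"PowerSpectrum"`: list with ascending `frequencies` (Hz,
#'   up to `fs / 2`), nonnegative `power` densities, and `fs`.
#' @export
#' @examples
#' ps <- welchPsd(sin(2 * pi * 10 * (0:999) / 1000), fs = 1000)
#' ps$frequencies[which.max(ps$power)]
welchPsd <- function(x, fs) {
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be a numeric vector")
  L <- length(x)
  if (L < 16L) stop("signal too short for Welch estimation (need L >= 16)")
  .assertScalarNumber(fs, "fs", lower = 1e-9)
  nper <- min(256L, L)
  nfft <- 256L
  step <- max(1L, nper %/% 2L)
  starts <- seq(1L, L - nper + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * (0:(nper - 1L)) / nper))  # periodic Hann
  u <- sum(win^2)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1L)]
    seg <- c((seg - mean(seg)) * win, numeric(nfft - nper))
    sp <- abs(stats::fft(seg))^2 / (fs * u)
    half <- sp[seq_len(nfft %/% 2L + 1L)]
    # one-sided: double everything except DC and Nyquist
    mult <- rep(2, length(half))
    mult[1L] <- 1
    mult[length(half)] <- 1
    acc <- acc + half * mult
  }
  structure(list(frequencies = (0:(nfft %/% 2L)) * fs / nfft,
                 power = acc / length(starts), fs = fs),
            class = "PowerSpectrum")
}
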