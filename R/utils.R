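#' Standard 12-lead order
#'
#' Fixed lead ordering used throughout the package: limb leads, augmented
#' leads, then the six precordial leads. All signal matrices carry these
#' names as rownames and every feature name refers to them.
#'
#' @return Character vector of the 12 lead names.
#' @export
#' @examples
#' leadNames()
leadNames <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", "V1", "V2", "V3", "V4", "V5", "V6")
}

.limbLeads <- function() c("I", "II", "III")
.augmentedLeads <- function() c("aVR", "aVL", "aVF")
.precordialLeads <- function() c("V1", "V2", "V3", "V4", "V5", "V6")

#' Valid chamber and sublocation labels
#'
#' @return `chamberLevels()` gives the two chamber labels;
#'   `sublocationLevels()` the nine site-of-origin sublocations;
#'   `sublocationChamber()` the chamber each sublocation belongs to,
#'   as a named character vector.
#' @export
chamberLevels <- function() c("LVOT", "RVOT")

#' @rdname chamberLevels
#' @export
sublocationLevels <- function() {
  c("LCC", "RCC", "LCC-RCC-commissure", "NCC", "AMC", "LV-summit",
    "anteroseptal-RV", "posteroseptal-RV", "RFW")
}

#' @rdname chamberLevels
#' @export
sublocationChamber <- function() {
  c("LCC" = "LVOT", "RCC" = "LVOT", "LCC-RCC-commissure" = "LVOT",
    "NCC" = "LVOT", "AMC" = "LVOT", "LV-summit" = "LVOT",
    "anteroseptal-RV" = "RVOT", "posteroseptal-RV" = "RVOT", "RFW" = "RVOT")
}

# Deterministic expansion of a global seed into per-stage child seeds.
# Rule: ((seed mod m) * 48271 + polynomial 31-hash of the stage name) mod m,
# m = 2^31 - 1, computed in doubles (exact below 2^53). Guarantees stage
# streams never collide for distinct stage strings (up to hash collisions)
# and stays inside 32-bit integer range.
.childSeed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((((seed %% m) * 48271) %% m + h) %% m)
}

# Evaluate code under a temporary RNG state (restores .Random.seed).
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647L), code)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Trapezoidal area with unit sample spacing.
.trapz <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum(y) - (y[1L] + y[n]) / 2
}

# Zero-lag normalized cross-correlation (Pearson after mean removal).
# Deterministic tie-breaks for degenerate inputs: two identical vectors
# (including constants) give 1, a single constant vector gives 0.
.xcorr0 <- function(a, b) {
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  na <- sqrt(sum(a0^2))
  nb <- sqrt(sum(b0^2))
  if (na == 0 && nb == 0) return(if (isTRUE(all.equal(a, b))) 1 else 0)
  if (na == 0 || nb == 0) return(0)
  sum(a0 * b0) / (na * nb)
}

# Signed maximum: the sample value with the largest magnitude (first on
# ties). All-zero input returns +0 so downstream polarity is +1.
.signedMax <- function(x) x[which.max(abs(x))]
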