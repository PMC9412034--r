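# SVM training with optional per-sample weights.
#
# Unweighted fits go through e1071::svm (libsvm). Per-sample weights
# (the mixup lambdas) are not supported by any installed SVM front-end,
# so the weighted C-SVM is solved directly as the standard dual QP
#   min_a  1/2 a' (yy' o K) a - 1'a   s.t.  y'a = 0,  0 <= a_i <= C w_i
# with kernlab::ipop. Duplicating a sample while halving its weight
# leaves the decision function unchanged, which is the defining property
# of per-sample cost scaling (verified in the test suite).

.gammaScale <- function(x, gamma = NULL) {
  if (!is.null(gamma)) {
    .assertScalarNumber(gamma, "gamma", lower = 1e-300)
    return(gamma)
  }
  v <- mean(apply(x, 2L, stats::var))
  if (!is.finite(v) || v <= 0) return(1 / ncol(x))
  1 / (ncol(x) * v)
}

.rbfKernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Train a support vector machine
#'
#' Radial-basis (default) or linear C-SVM for two-class chamber
#' prediction. The default `gamma` follows the variance-scaled rule
#' `1 / (p * mean feature variance)`. When `weights` are supplied
#' (mixup lambdas), the weighted dual problem is solved exactly; with
#' `weights = NULL` training is delegated to libsvm. Training is
#' deterministic given the inputs.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y factor or character labels (two or more classes; two for
#'   the weighted path).
#' @param C regularization constant (> 0).
#' @param gamma RBF kernel width; `NULL` for the variance-scaled rule.
#' @param weights optional nonnegative per-sample weights.
#' @param kernel `"radial"` or `"linear"`.
#' @return An object of class `"ecgsooSvm"` with a [predict][stats::predict]
#'   method (`type = "class"` or `"decision"`).
#' @export
trainSvm <- function(x, y, C = 1, gamma = NULL, weights = NULL,
                     kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class")
  y <- droplevels(y)
  .assertScalarNumber(C, "C", lower = 1e-300)
  gamma <- if (kernel == "radial") .gammaScale(x, gamma) else 0

  if (is.null(weights)) {
    fit <- e1071::svm(x = x, y = y, scale = FALSE, kernel = kernel,
                      cost = C, gamma = if (kernel == "radial") gamma else 1)
    return(structure(list(type = "libsvm", fit = fit, levels = levels(y),
                          kernel = kernel, gamma = gamma, C = C),
                     class = "ecgsooSvm"))
  }
  if (nlevels(y) != 2L)
    stop("weighted training supports exactly two classes")
  if (length(weights) != nrow(x) || any(weights < 0) || anyNA(weights))
    stop("'weights' must be nonnegative, one per sample")
  yNum <- ifelse(y == levels(y)[1L], 1, -1)
  K <- if (kernel == "radial") .rbfKernel(x, x, gamma) else tcrossprod(x)
  n <- nrow(x)
  H <- (yNum %o% yNum) * K + diag(1e-8, n)
  u <- C * weights
  sol <- kernlab::ipop(c = rep(-1, n), H = H,
                       A = matrix(yNum, nrow = 1L), b = 0,
                       l = rep(0, n), u = u, r = 0,
                       sigf = 7, maxiter = 80)
  alpha <- kernlab::primal(sol)
  tolA <- 1e-7 * max(u)
  sv <- alpha > tolA
  coef <- alpha * yNum
  fx <- as.vector(K %*% coef)
  free <- sv & alpha < u - tolA
  b <- if (any(free)) mean(yNum[free] - fx[free])
       else if (any(sv)) mean(yNum[sv] - fx[sv]) else 0
  structure(list(type = "qp", xSv = x[sv, , drop = FALSE],
                 coefSv = coef[sv], b = b, levels = levels(y),
                 kernel = kernel, gamma = gamma, C = C),
            class = "ecgsooSvm")
}

#' @rdname trainSvm
#' @param object an `"ecgsooSvm"` model.
#' @param newdata numeric matrix of samples to classify.
#' @param type `"class"` for labels, `"decision"` for the decision
#'   function value.
#' @param ... unused.
#' @export
predict.ecgsooSvm <- function(object, newdata, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (object$type == "libsvm") {
    if (type == "class")
      return(as.character(stats::predict(object$fit, newdata)))
    dv <- attr(stats::predict(object$fit, newdata, decision.values = TRUE),
               "decision.values")
    return(as.vector(dv))
  }
  Kx <- if (object$kernel == "radial")
    .rbfKernel(newdata, object$xSv, object$gamma)
  else tcrossprod(newdata, object$xSv)
  f <- as.vector(Kx %*% object$coefSv) + object$b
  if (type == "decision") return(f)
  ifelse(f >= 0, object$levels[1L], object$levels[2L])
}
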