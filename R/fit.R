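# Tensor estimation: log-linear WLS, scalar maps, modified-Z-score outlier
# down-weighting, and the iterated robust fit.

# One voxel's weighted least-squares solve in the log domain.
# y: log-signals; X: design; w: external weights (0 excludes a volume).
# WLS weights are w * (predicted signal)^2, the standard variance
# stabilisation for log-transformed Rician/Gaussian magnitude data; the
# first pass uses the observed signals as the prediction.
.wlsCore <- function(y, X, w, nPass = 2L) {
  sPred2 <- exp(2 * y)
  sPred2[w == 0] <- 0
  beta <- NULL
  for (pass in seq_len(nPass)) {
    W <- w * sPred2
    A <- crossprod(X, X * W)
    bvec <- crossprod(X, W * y)
    beta <- tryCatch(solve(A, bvec),
                     error = function(e) stop("insufficient usable volumes",
                                              call. = FALSE))
    fitted <- as.numeric(X %*% beta)
    sPred2 <- exp(2 * fitted)
    sPred2[w == 0] <- 0
  }
  W <- w * sPred2
  A <- crossprod(X, X * W)
  Ainv <- tryCatch(solve(A),
                   error = function(e) stop("insufficient usable volumes",
                                            call. = FALSE))
  hat <- W * rowSums((X %*% Ainv) * X)
  list(beta = as.numeric(beta), fitted = fitted, resid = y - fitted,
       W = W, hat = pmin(pmax(hat, 0), 1 - 1e-8))
}

# Continuous down-weighting from a modified Z-score of residual magnitude:
# weight 1 below `lower`, 0 above `upper`, linear in between.  Scores are
# computed only over volumes with positive external weight; MAD = 0 means
# no dispersion, hence no outliers (all weights 1).
.detectWeights <- function(absres, active, lower = 3.5, upper = 10) {
  w <- rep(1, length(absres))
  s <- absres[active]
  med <- median(s)
  madv <- median(abs(s - med))
  # a log-domain residual spread below 1e-8 is numerical jitter, not
  # measurement dispersion: no outliers can be resolved against it
  if (madv <= 1e-8) return(w)
  z <- 0.6745 * (absres - med) / madv
  w <- ifelse(z <= lower, 1, ifelse(z >= upper, 0,
                                    (upper - z) / (upper - lower)))
  w[!active] <- 1
  w
}

# Iterated robust fit for one voxel; extw carries exclusions (0 entries).
# The scoring fit uses a single WLS pass (variance weights from the
# observed signals), which keeps dropped-out volumes naturally
# down-weighted before they are formally detected; refits after detection
# use the full predicted-signal weighting.
.robustCore <- function(y, X, extw, lower = 3.5, upper = 10,
                        maxIter = 10L, tol = 1e-6) {
  active <- extw > 0
  fit <- .wlsCore(y, X, extw, nPass = 1L)
  detw <- .detectWeights(abs(fit$resid), active, lower, upper)
  w <- extw * detw
  fit <- .wlsCore(y, X, w)
  for (it in seq_len(maxIter)) {
    detw <- .detectWeights(abs(fit$resid), active, lower, upper)
    wNew <- extw * detw
    if (max(abs(wNew - w)) < tol) break
    w <- wNew
    fit <- .wlsCore(y, X, w)
  }
  fit$outw <- extw * detw
  fit
}

# FA from a row-matrix of (clamped, non-negative) eigenvalues.
.faRows <- function(ev) {
  mu <- rowMeans(ev)
  num <- rowSums((ev - mu)^2)
  den <- rowSums(ev^2)
  out <- sqrt(1.5 * num / den)
  out[den == 0] <- 0
  pmin(out, 1)
}

#' Fractional anisotropy of a set of eigenvalues
#'
#' \code{FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||}, defined
#' as 0 when all eigenvalues are zero.
#'
#' @param eigenvalues three non-negative diffusivities.
#' @return FA in [0, 1].
#' @examples
#' computeFA(c(1.7e-3, 0.3e-3, 0.3e-3))  # ~0.799
#' @export
computeFA <- function(eigenvalues) {
  if (length(eigenvalues) != 3L || any(eigenvalues < 0))
    stop("need 3 non-negative eigenvalues")
  .faRows(matrix(eigenvalues, 1L))[1L]
}

#' Mean diffusivity of a set of eigenvalues
#'
#' @inheritParams computeFA
#' @return MD in mm^2/s (arithmetic mean of the eigenvalues).
#' @export
computeMD <- function(eigenvalues) {
  if (length(eigenvalues) != 3L || any(eigenvalues < 0))
    stop("need 3 non-negative eigenvalues")
  mean(eigenvalues)
}

# Prepare log-signals and exclusion-aware external weights for a signal
# matrix (voxels x volumes).
.prepLog <- function(sig, extw) {
  bad <- !is.finite(sig) | sig <= 0
  y <- sig
  y[bad] <- 1  # placeholder; weight 0 removes these volumes from the fit
  extw[bad] <- 0
  list(y = log(y), extw = extw)
}

# Assemble a TensorFit from per-voxel core fits.
.buildTensorFit <- function(scheme, y, fits, outw) {
  nv <- nrow(y)
  n <- ncol(y)
  coefs <- matrix(0, nv, 7L,
                  dimnames = list(NULL, c("logS0", "Dxx", "Dyy", "Dzz",
                                          "Dxy", "Dxz", "Dyz")))
  ev <- matrix(0, nv, 3L)
  resid <- wls <- hat <- matrix(0, nv, n)
  clamped <- logical(nv)
  for (v in seq_len(nv)) {
    f <- fits[[v]]
    coefs[v, ] <- f$beta
    lam <- tensorEigen(f$beta[2:7])
    clamped[v] <- any(lam < 0)
    ev[v, ] <- pmax(lam, 0)
    resid[v, ] <- f$resid
    wls[v, ] <- f$W
    hat[v, ] <- f$hat
  }
  new("TensorFit", scheme = scheme, coefficients = coefs,
      eigenvalues = ev, fa = .faRows(ev), md = rowMeans(ev),
      logSignals = y, residuals = resid, outlierWeights = outw,
      wlsWeights = wls, hatDiag = hat, clamped = clamped)
}

.checkDesign <- function(scheme, nSignals) {
  if (nSignals != nVolumes(scheme))
    stop("signal length must match the scheme's volume count")
  if (nVolumes(scheme) < 7L)
    stop("at least 7 volumes are required for the tensor fit")
}

.asWeightMatrix <- function(weights, nv, n) {
  if (is.null(weights)) return(matrix(1, nv, n))
  if (is.vector(weights)) weights <- matrix(weights, nv, n, byrow = TRUE)
  stopifnot(all(dim(weights) == c(nv, n)), all(weights >= 0),
            all(weights <= 1))
  weights
}

#' @rdname fitTensor
#' @export
setMethod("fitTensor", "numeric",
  function(object, scheme, weights = NULL, ...) {
    fitTensor(matrix(object, nrow = 1L), scheme, weights = weights, ...)
  })

#' @rdname fitTensor
#' @export
setMethod("fitTensor", "matrix",
  function(object, scheme, weights = NULL, ...) {
    .checkDesign(scheme, ncol(object))
    X <- designMatrix(scheme)
    extw <- .asWeightMatrix(weights, nrow(object), ncol(object))
    prep <- .prepLog(object, extw)
    fits <- lapply(seq_len(nrow(object)), function(v) {
      .wlsCore(prep$y[v, ], X, prep$extw[v, ])
    })
    .buildTensorFit(scheme, prep$y, fits, prep$extw)
  })

#' @rdname fitTensor
#' @export
setMethod("fitTensor", "DWIDataset",
  function(object, scheme, weights = NULL, ...) {
    fitTensor(dwiSignals(object), dwiScheme(object), weights = weights, ...)
  })

#' Outlier down-weighting from a fitted tensor
#'
#' Scores every volume of every voxel by the modified Z-score
#' (median/MAD-based across that voxel's volumes) of its absolute
#' log-domain residual and converts the score to a weight: 1 below
#' \code{lowerThreshold}, 0 above \code{upperThreshold}, linear in
#' between.  In a volumetric acquisition the natural scoring unit is the
#' slice; for the single-voxel and labelled-phantom data handled here the
#' unit degenerates to the voxel, so scoring is per voxel x volume.
#' A zero MAD (no residual dispersion) yields all-ones weights.
#'
#' @param fit a \linkS4class{TensorFit} from an initial (unweighted) fit.
#' @param lowerThreshold,upperThreshold modified-Z-score bounds
#'   (defaults 3.5 and 10).
#' @return matrix (voxels x volumes) of weights in [0, 1].
#' @export
detectOutliers <- function(fit, lowerThreshold = 3.5, upperThreshold = 10) {
  stopifnot(is(fit, "TensorFit"))
  out <- fit@outlierWeights
  for (v in seq_len(nrow(out))) {
    active <- fit@outlierWeights[v, ] > 0
    out[v, ] <- .detectWeights(abs(fit@residuals[v, ]), active,
                               lowerThreshold, upperThreshold)
    out[v, !active] <- 0
  }
  out
}

#' @rdname fitTensorRobust
#' @export
setMethod("fitTensorRobust", "numeric",
  function(object, scheme, weights = NULL, lowerThreshold = 3.5,
           upperThreshold = 10, ...) {
    fitTensorRobust(matrix(object, nrow = 1L), scheme, weights = weights,
                    lowerThreshold = lowerThreshold,
                    upperThreshold = upperThreshold, ...)
  })

#' @rdname fitTensorRobust
#' @export
setMethod("fitTensorRobust", "matrix",
  function(object, scheme, weights = NULL, lowerThreshold = 3.5,
           upperThreshold = 10, ...) {
    .checkDesign(scheme, ncol(object))
    X <- designMatrix(scheme)
    extw <- .asWeightMatrix(weights, nrow(object), ncol(object))
    prep <- .prepLog(object, extw)
    outw <- prep$extw
    fits <- vector("list", nrow(object))
    for (v in seq_len(nrow(object))) {
      f <- .robustCore(prep$y[v, ], X, prep$extw[v, ],
                       lower = lowerThreshold, upper = upperThreshold)
      outw[v, ] <- f$outw
      fits[[v]] <- f
    }
    .buildTensorFit(scheme, prep$y, fits, outw)
  })

#' @rdname fitTensorRobust
#' @export
setMethod("fitTensorRobust", "DWIDataset",
  function(object, scheme, weights = NULL, lowerThreshold = 3.5,
           upperThreshold = 10, ...) {
    fitTensorRobust(dwiSignals(object), dwiScheme(object),
                    weights = weights, lowerThreshold = lowerThreshold,
                    upperThreshold = upperThreshold, ...)
  })

# ---- TensorFit accessors --------------------------------------------------

#' @rdname TensorFit-class
#' @export
setMethod("fa", "TensorFit", function(object) object@fa)

#' @rdname TensorFit-class
#' @export
setMethod("md", "TensorFit", function(object) object@md)

#' @rdname TensorFit-class
#' @export
setMethod("tensorEigenvalues", "TensorFit",
          function(object) object@eigenvalues)

#' @rdname TensorFit-class
#' @export
setMethod("outlierWeights", "TensorFit",
          function(object) object@outlierWeights)

#' @rdname TensorFit-class
#' @export
setMethod("residuals", "TensorFit", function(object) object@residuals)

#' @rdname TensorFit-class
#' @export
setMethod("show", "TensorFit", function(object) {
  cat("TensorFit: ", nrow(object@coefficients), " voxel(s), ",
      nVolumes(object@scheme), " volumes; FA range [",
      sprintf("%.3f", min(object@fa)), ", ",
      sprintf("%.3f", max(object@fa)), "]; ",
      sum(object@clamped), " voxel(s) with clamped eigenvalues\n",
      sep = "")
})
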