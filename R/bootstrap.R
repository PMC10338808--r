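# Wild residual bootstrap of the tensor fit.

# One voxel's bootstrap: resample log-signals around the fitted model with
# Rademacher sign flips of leverage-corrected residuals, refit with the
# frozen WLS weights (one shared projection), return FA/MD samples.
.wildBootVoxel <- function(y, X, fitted, resid, W, hat, nSamples) {
  rtilde <- resid / sqrt(pmax(1 - hat, 1e-8))
  rtilde[W == 0] <- 0  # excluded volumes carry no resampling information
  A <- crossprod(X, X * W)
  M <- solve(A, t(X * W))  # 7 x volumes projection, frozen weights
  signs <- matrix(sample(c(-1, 1), length(y) * nSamples, replace = TRUE),
                  length(y), nSamples)
  yStar <- fitted + rtilde * signs
  betaStar <- M %*% yStar  # 7 x nSamples
  faS <- numeric(nSamples)
  mdS <- numeric(nSamples)
  for (s in seq_len(nSamples)) {
    lam <- pmax(tensorEigen(betaStar[2:7, s]), 0)
    faS[s] <- .faRows(matrix(lam, 1L))[1L]
    mdS[s] <- mean(lam)
  }
  list(fa = faS, md = mdS)
}

#' @rdname wildBootstrap
#' @export
setMethod("wildBootstrap", "TensorFit",
  function(object, nSamples = 2000L, seed = NULL, level = 0.95, ...) {
    nSamples <- as.integer(nSamples)
    if (nSamples < 2L) stop("nSamples must be >= 2")
    if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
    X <- designMatrix(object@scheme)
    nv <- nrow(object@coefficients)
    faS <- mdS <- matrix(0, nv, nSamples)
    withSeed(seed, {
      for (v in seq_len(nv)) {
        fitted <- object@logSignals[v, ] - object@residuals[v, ]
        bs <- .wildBootVoxel(object@logSignals[v, ], X, fitted,
                             object@residuals[v, ], object@wlsWeights[v, ],
                             object@hatDiag[v, ], nSamples)
        faS[v, ] <- bs$fa
        mdS[v, ] <- bs$md
      }
    })
    alpha <- (1 - level) / 2
    ciOf <- function(m) {
      t(apply(m, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE))
    }
    new("BootstrapResult", faSamples = faS, mdSamples = mdS,
        faCI = ciOf(faS), mdCI = ciOf(mdS), level = level,
        nSamples = nSamples)
  })

#' @rdname medianFAMap
#' @export
setMethod("medianFAMap", "BootstrapResult",
          function(object) apply(object@faSamples, 1L, median))

#' @rdname checkConvergence
#' @export
setMethod("checkConvergence", "BootstrapResult",
  function(object, metric = c("fa", "md"), ciWidthThreshold = NULL) {
    metric <- match.arg(metric)
    if (is.null(ciWidthThreshold))
      ciWidthThreshold <- if (metric == "fa") 0.2 else 0.4e-3
    ci <- if (metric == "fa") object@faCI else object@mdCI
    (ci[, 2L] - ci[, 1L]) <= ciWidthThreshold
  })

#' Percentile confidence intervals of a bootstrap result
#'
#' @param object a \linkS4class{BootstrapResult}.
#' @param metric \code{"fa"} or \code{"md"}.
#' @return matrix (voxels x 2) of lower/upper bounds.
#' @export
bootstrapCI <- function(object, metric = c("fa", "md")) {
  stopifnot(is(object, "BootstrapResult"))
  metric <- match.arg(metric)
  ci <- if (metric == "fa") object@faCI else object@mdCI
  colnames(ci) <- c("lower", "upper")
  ci
}

#' @rdname BootstrapResult-class
#' @param object a \linkS4class{BootstrapResult}.
#' @export
setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult: ", nrow(object@faSamples), " voxel(s) x ",
      object@nSamples, " samples; ", round(object@level * 100),
      "% percentile CIs\n", sep = "")
})
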