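#' @import methods
#' @importFrom stats median mad quantile rnorm runif sd var
NULL

#' Diffusion gradient scheme
#'
#' Per-volume description of a diffusion-weighted acquisition: b-values,
#' unit gradient directions (zero rows for b=0 volumes), repetition labels
#' and the derived b-matrices.  A scheme is the concatenation of
#' \code{nRepetitions} identical blocks, each holding one b=0 volume
#' followed by the diffusion-weighted directions, mirroring clinical
#' protocols that repeat a short scan for redundancy.
#'
#' @slot name scheme label, e.g. \code{"overplus15"} or \code{"uniform15"}.
#' @slot bValues numeric, per-volume diffusion weighting in s/mm^2.
#' @slot directions matrix (volumes x 3), per-volume unit gradient
#'   direction; zero rows for b=0 volumes.
#' @slot repetition integer, per-volume repetition index (1-based).
#' @slot bMatrices array (3 x 3 x volumes), per-volume symmetric b-matrix
#'   in s/mm^2, \code{b * g %*% t(g)}; the zero matrix for b=0 volumes.
#'
#' @seealso [buildOverplusScheme()], [buildUniformScheme()],
#'   [designMatrix()], [conditionNumber()]
#' @export
setClass("GradientScheme",
  representation(
    name = "character",
    bValues = "numeric",
    directions = "matrix",
    repetition = "integer",
    bMatrices = "array"
  )
)

setValidity("GradientScheme", function(object) {
  n <- length(object@bValues)
  msg <- character()
  if (nrow(object@directions) != n || ncol(object@directions) != 3L)
    msg <- c(msg, "directions must be a (volumes x 3) matrix")
  if (length(object@repetition) != n)
    msg <- c(msg, "repetition must have one entry per volume")
  if (!all(dim(object@bMatrices) == c(3L, 3L, n)))
    msg <- c(msg, "bMatrices must be 3 x 3 x volumes")
  if (any(object@bValues < 0)) msg <- c(msg, "b-values must be >= 0")
  if (length(msg) > 0L) return(msg)
  wtd <- object@bValues > 0
  nrm <- sqrt(rowSums(object@directions^2))
  if (any(abs(nrm[wtd] - 1) > 1e-9))
    msg <- c(msg, "weighted directions must be unit vectors (|norm - 1| <= 1e-9)")
  if (any(nrm[!wtd] > 1e-12))
    msg <- c(msg, "b=0 volumes must have zero direction rows")
  for (k in seq_len(n)) {
    tr <- sum(diag(object@bMatrices[, , k]))
    if (abs(tr - object@bValues[k]) > 1e-6) {
      msg <- c(msg, sprintf("trace of b-matrix %d differs from its b-value", k))
      break
    }
  }
  nrep <- length(unique(object@repetition))
  if (n %% nrep != 0L)
    msg <- c(msg, "volumes must split evenly across repetitions")
  if (length(msg) > 0L) msg else TRUE
})

#' Diffusion-weighted dataset
#'
#' Voxels-by-volumes signal container built on
#' \linkS4class{SummarizedExperiment}.  The \code{"signals"} assay holds
#' non-negative signal intensities; an optional \code{"outliers"} logical
#' assay marks synthetically corrupted entries.  Row (voxel) metadata
#' carries a white-matter bundle label per voxel plus, for phantoms, the
#' ground-truth FA/MD/S0 of the generating tensor; column (volume) metadata
#' mirrors the scheme's b-values, directions and repetition index.  The
#' full \linkS4class{GradientScheme} is kept in \code{metadata(x)$scheme}.
#'
#' @seealso [DWIDataset()], [simulateCohort()], [fitTensor()]
#' @export
setClass("DWIDataset", contains = "SummarizedExperiment")

setValidity("DWIDataset", function(object) {
  msg <- character()
  if (!"signals" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'signals' assay is required")
  sch <- S4Vectors::metadata(object)$scheme
  if (is.null(sch) || !is(sch, "GradientScheme")) {
    msg <- c(msg, "metadata(x)$scheme must hold a GradientScheme")
  } else if (ncol(object) != nVolumes(sch)) {
    msg <- c(msg, "column count must match the scheme's volume count")
  }
  if ("signals" %in% SummarizedExperiment::assayNames(object) &&
      any(SummarizedExperiment::assay(object, "signals") < 0))
    msg <- c(msg, "signals must be non-negative")
  if (!"region" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData(x)$region is required")
  if (length(msg) > 0L) msg else TRUE
})

#' Tensor fit result
#'
#' Per-voxel diffusion tensor estimate from log-linear (weighted) least
#' squares: model coefficients (log S0 and the six unique tensor elements,
#' mm^2/s), eigenvalues (clamped at zero where needed, with a flag), FA and
#' MD scalars, the log-domain residuals, the outlier weights in [0, 1] used
#' for each volume, the full WLS weights and hat-matrix diagonal needed by
#' the wild residual bootstrap, and the fitted log-signals.
#'
#' @slot scheme the \linkS4class{GradientScheme} the data were fit against.
#' @slot coefficients matrix (voxels x 7): logS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#' @slot eigenvalues matrix (voxels x 3), descending, clamped at 0.
#' @slot fa,md numeric per-voxel scalars.
#' @slot logSignals,residuals matrix (voxels x volumes), log domain.
#' @slot outlierWeights matrix (voxels x volumes) in [0, 1].
#' @slot wlsWeights matrix (voxels x volumes): outlier weight times squared
#'   predicted signal (the weights actually applied in the final solve).
#' @slot hatDiag matrix (voxels x volumes): leverage of each volume.
#' @slot clamped logical per voxel: TRUE if an eigenvalue was clamped at 0.
#'
#' @seealso [fitTensor()], [fitTensorRobust()], [wildBootstrap()]
#' @export
setClass("TensorFit",
  representation(
    scheme = "GradientScheme",
    coefficients = "matrix",
    eigenvalues = "matrix",
    fa = "numeric",
    md = "numeric",
    logSignals = "matrix",
    residuals = "matrix",
    outlierWeights = "matrix",
    wlsWeights = "matrix",
    hatDiag = "matrix",
    clamped = "logical"
  )
)

setValidity("TensorFit", function(object) {
  v <- nrow(object@coefficients)
  n <- nVolumes(object@scheme)
  msg <- character()
  if (ncol(object@coefficients) != 7L)
    msg <- c(msg, "coefficients must have 7 columns")
  for (nm in c("logSignals", "residuals", "outlierWeights", "wlsWeights",
               "hatDiag")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(v, n)))
      msg <- c(msg, sprintf("%s must be voxels x volumes", nm))
  }
  if (any(object@fa < -1e-12 | object@fa > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "fa must lie in [0, 1]")
  if (any(object@outlierWeights < -1e-12 | object@outlierWeights > 1 + 1e-12))
    msg <- c(msg, "outlier weights must lie in [0, 1]")
  if (length(msg) > 0L) msg else TRUE
})

#' Wild-bootstrap result
#'
#' Per-voxel bootstrap distributions of FA and MD: the raw samples, the
#' percentile confidence interval at the configured level, and the number
#' of samples drawn.
#'
#' @slot faSamples,mdSamples matrix (voxels x samples).
#' @slot faCI,mdCI matrix (voxels x 2), percentile interval bounds.
#' @slot level numeric, confidence level of the intervals.
#' @slot nSamples integer.
#'
#' @seealso [wildBootstrap()], [medianFAMap()], [checkConvergence()]
#' @export
setClass("BootstrapResult",
  representation(
    faSamples = "matrix",
    mdSamples = "matrix",
    faCI = "matrix",
    mdCI = "matrix",
    level = "numeric",
    nSamples = "integer"
  )
)

setValidity("BootstrapResult", function(object) {
  msg <- character()
  if (ncol(object@faSamples) != object@nSamples)
    msg <- c(msg, "faSamples column count must equal nSamples")
  if (!all(dim(object@mdSamples) == dim(object@faSamples)))
    msg <- c(msg, "mdSamples must match faSamples in shape")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must lie in (0, 1)")
  if (length(msg) > 0L) msg else TRUE
})
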