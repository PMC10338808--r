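#' @rdname GradientScheme-class
#' @param object,x a \linkS4class{GradientScheme} (or, where documented, a
#'   \linkS4class{DWIDataset} or \linkS4class{TensorFit}).
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))

#' @rdname GradientScheme-class
#' @export
setGeneric("nRepetitions", function(object) standardGeneric("nRepetitions"))

#' @rdname GradientScheme-class
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))

#' @rdname GradientScheme-class
#' @export
setGeneric("gradientDirections",
           function(object) standardGeneric("gradientDirections"))

#' @rdname GradientScheme-class
#' @export
setGeneric("bMatrices", function(object) standardGeneric("bMatrices"))

#' @rdname GradientScheme-class
#' @export
setGeneric("repetitionIndex",
           function(object) standardGeneric("repetitionIndex"))

#' Design matrix of the log-linear tensor model
#'
#' One row per volume: \code{(1, -Bxx, -Byy, -Bzz, -2 Bxy, -2 Bxz, -2 Byz)},
#' so that \code{log S = X \%*\% c(log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)}.
#'
#' @param object a \linkS4class{GradientScheme}.
#' @return numeric matrix, volumes x 7.
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' Condition number of a scheme's tensor design
#'
#' Ratio of the largest to the smallest singular value of the 7-column
#' log-linear design matrix.  Large values mean the angular coverage of the
#' scheme supports the tensor fit poorly; a rank-deficient design (e.g. one
#' direction duplicated throughout) is rejected.
#'
#' @param object a \linkS4class{GradientScheme} with at least 6
#'   diffusion-weighted volumes.
#' @return a single positive number (dimensionless).
#' @examples
#' ovp <- buildOverplusScheme(700, 3)
#' conditionNumber(ovp)
#' @export
setGeneric("conditionNumber",
           function(object) standardGeneric("conditionNumber"))

#' @rdname DWIDataset
#' @export
setGeneric("dwiSignals", function(object) standardGeneric("dwiSignals"))

#' @rdname DWIDataset
#' @export
setGeneric("dwiScheme", function(object) standardGeneric("dwiScheme"))

#' @rdname DWIDataset
#' @export
setGeneric("voxelRegions", function(object) standardGeneric("voxelRegions"))

#' @rdname DWIDataset
#' @export
setGeneric("outlierMask", function(object) standardGeneric("outlierMask"))

#' @rdname TensorFit-class
#' @export
setGeneric("fa", function(object) standardGeneric("fa"))

#' @rdname TensorFit-class
#' @export
setGeneric("md", function(object) standardGeneric("md"))

#' @rdname TensorFit-class
#' @export
setGeneric("tensorEigenvalues",
           function(object) standardGeneric("tensorEigenvalues"))

#' @rdname TensorFit-class
#' @export
setGeneric("outlierWeights",
           function(object) standardGeneric("outlierWeights"))

#' Fit the diffusion tensor by log-linear weighted least squares
#'
#' @param object signals: a numeric vector (one voxel), a voxels-x-volumes
#'   matrix, or a \linkS4class{DWIDataset}.
#' @param scheme the \linkS4class{GradientScheme}; taken from the dataset's
#'   metadata when \code{object} is a \linkS4class{DWIDataset}.
#' @param weights optional per-volume (or voxels x volumes) external
#'   weights in [0, 1]; volumes with non-positive signal are excluded with
#'   weight 0 automatically.
#' @param ... passed between methods.
#' @return a \linkS4class{TensorFit}.
#' @seealso [fitTensorRobust()] for the outlier-down-weighting variant.
#' @export
setGeneric("fitTensor",
           function(object, scheme, weights = NULL, ...)
             standardGeneric("fitTensor"))

#' Robust tensor fit with iterative outlier down-weighting
#'
#' Alternates weighted least-squares fitting with modified-Z-score outlier
#' scoring of the log-domain residuals until the weights stabilise
#' (change < 1e-6) or 10 iterations are reached.  Deterministic: no
#' internal randomness.
#'
#' @inheritParams fitTensor
#' @param lowerThreshold,upperThreshold modified-Z-score bounds: weight 1
#'   below the lower bound, 0 above the upper, linear in between.
#' @return a \linkS4class{TensorFit} whose \code{outlierWeights} reflect
#'   the final down-weighting.
#' @export
setGeneric("fitTensorRobust",
           function(object, scheme, weights = NULL, lowerThreshold = 3.5,
                    upperThreshold = 10, ...)
             standardGeneric("fitTensorRobust"))

#' Add Rician noise to diffusion-weighted signals
#'
#' Each value S is replaced by \code{sqrt((S + n1)^2 + n2^2)} with n1, n2
#' independent zero-mean Gaussians of standard deviation \code{s0 / snr} --
#' the magnitude-image noise model of MRI.
#'
#' @param object numeric vector/matrix of signals, or a
#'   \linkS4class{DWIDataset}.
#' @param snr signal-to-noise ratio S0 / sigma (dimensionless, > 0).
#' @param s0 reference non-diffusion-weighted signal defining sigma; for a
#'   \linkS4class{DWIDataset} it defaults to each voxel's ground-truth S0
#'   when present, else the voxel's mean b=0 signal.
#' @param seed optional integer for reproducibility.
#' @param ... passed between methods.
#' @export
setGeneric("addRicianNoise",
           function(object, snr, s0 = 1, seed = NULL, ...)
             standardGeneric("addRicianNoise"))

#' Inject signal-dropout outliers
#'
#' Corrupts a random subset of the diffusion-weighted volumes of each voxel
#' (the single-voxel analogue of motion-induced slicewise dropout):
#' \code{round(fraction * n_weighted)} volumes have their signal multiplied
#' by \code{magnitude}.  b=0 volumes are never corrupted.  The corrupted
#' entries are recorded in the dataset's \code{"outliers"} assay.
#'
#' @param object a \linkS4class{DWIDataset}.
#' @param fraction proportion of weighted volumes to corrupt, in [0, 0.5].
#' @param magnitude multiplicative attenuation (default 0.25).
#' @param seed optional integer.
#' @param ... passed between methods.
#' @export
setGeneric("injectOutliers",
           function(object, fraction, magnitude = 0.25, seed = NULL, ...)
             standardGeneric("injectOutliers"))

#' Scale whole repetitions of a dataset
#'
#' Emulates between-scan intensity offsets from re-shimming or subject
#' repositioning: every volume of repetition r is multiplied by
#' \code{scales[r]}.  Ground-truth metadata is unchanged.
#'
#' @param object a \linkS4class{DWIDataset}.
#' @param scales one positive factor per repetition.
#' @param ... passed between methods.
#' @export
setGeneric("applyRepetitionScaling",
           function(object, scales, ...)
             standardGeneric("applyRepetitionScaling"))

#' Between-repetition intensity normalisation
#'
#' Rescales each repetition so that its mean foreground b=0 intensity
#' matches the reference repetition's, and applies the same factor to the
#' diffusion-weighted volumes of that repetition.  Idempotent.
#'
#' @param object a \linkS4class{DWIDataset} whose every repetition holds at
#'   least one b=0 volume.
#' @param referenceRepetition 1-based index of the reference repetition.
#' @param ... passed between methods.
#' @return a list with elements \code{dataset} (normalised copy) and
#'   \code{factors} (one factor per repetition; reference factor 1).
#' @export
setGeneric("normalizeRepetitions",
           function(object, referenceRepetition = 1L, ...)
             standardGeneric("normalizeRepetitions"))

#' Wild residual bootstrap of a tensor fit
#'
#' Resamples the fitted log-domain model: each bootstrap replicate flips
#' the sign of every volume's leverage-corrected residual independently
#' (Rademacher draws) and refits with the frozen outlier weights, yielding
#' per-voxel FA and MD sampling distributions without exchangeability
#' assumptions.
#'
#' @param object a \linkS4class{TensorFit} (point fit with residuals and
#'   weights).
#' @param nSamples number of bootstrap replicates (default 2000).
#' @param seed optional integer.
#' @param level confidence level for the percentile intervals.
#' @param ... passed between methods.
#' @return a \linkS4class{BootstrapResult}.
#' @export
setGeneric("wildBootstrap",
           function(object, nSamples = 2000L, seed = NULL, level = 0.95, ...)
             standardGeneric("wildBootstrap"))

#' Elementwise median FA over bootstrap samples
#'
#' @param object a \linkS4class{BootstrapResult}.
#' @return numeric, one median FA per voxel.
#' @export
setGeneric("medianFAMap", function(object) standardGeneric("medianFAMap"))

#' Convergence check for bootstrap scalar estimates
#'
#' A voxel's estimate of the chosen metric is declared converged when its
#' bootstrap percentile-interval width does not exceed the threshold.
#' Defaults: 0.2 for FA (dimensionless), 0.4e-3 mm^2/s for MD.
#'
#' @param object a \linkS4class{BootstrapResult}.
#' @param metric \code{"fa"} or \code{"md"}.
#' @param ciWidthThreshold width threshold in the metric's units; `NULL`
#'   picks the metric's default.
#' @return logical, one flag per voxel.
#' @export
setGeneric("checkConvergence",
           function(object, metric = c("fa", "md"), ciWidthThreshold = NULL)
             standardGeneric("checkConvergence"))
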