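# Single-voxel signal simulation: tensor specs, forward model, Rician
# noise, dropout outliers, repetition scaling, DWIDataset construction.

#' White-matter bundle labels
#'
#' The monolateral bundles (left/right) and bilateral forceps used as
#' region labels by the synthetic phantoms: anterior thalamic radiation
#' (ATR), corticospinal tract (CST), cingulum cingulate gyrus (CGY),
#' cingulum hippocampus (CHI), inferior fronto-occipital fasciculus
#' (IFOF), inferior longitudinal fasciculus (ILF), superior longitudinal
#' fasciculus (SLF), uncinate fasciculus (UF), temporal SLF (SLF_temp),
#' plus bilateral forceps major (FMA) and minor (FMI).
#'
#' @return character vector of region labels (sides suffixed "_l"/"_r").
#' @export
wmBundles <- function() {
  mono <- c("ATR", "CST", "CGY", "CHI", "IFOF", "ILF", "SLF", "UF",
            "SLF_temp")
  c(paste0(rep(mono, each = 2L), c("_l", "_r")), "FMA", "FMI")
}

#' Tensor specification
#'
#' Ground-truth diffusion tensor for simulation: three non-negative
#' eigenvalues in mm^2/s (sorted descending), an orientation (3x3 rotation
#' matrix whose columns are the eigenvectors) and the non-diffusion-weighted
#' signal S0.
#'
#' @param eigenvalues three non-negative diffusivities, mm^2/s.
#' @param orientation 3x3 rotation matrix (default identity).
#' @param s0 positive b=0 signal (arbitrary units, default 1).
#' @return a list of class \code{"TensorSpec"}.
#' @export
tensorSpec <- function(eigenvalues, orientation = diag(3), s0 = 1) {
  ev <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  if (length(ev) != 3L || any(ev < 0)) stop("need 3 non-negative eigenvalues")
  if (s0 <= 0) stop("s0 must be positive")
  stopifnot(is.matrix(orientation), all(dim(orientation) == c(3L, 3L)))
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-8)
    stop("orientation must be a rotation matrix")
  structure(list(eigenvalues = ev, orientation = orientation, s0 = s0),
            class = "TensorSpec")
}

#' Prolate tensor with a prescribed FA at fixed mean diffusivity
#'
#' One-parameter invertible mapping from FA to a tensor: the two minor
#' eigenvalues are set equal (lambda2 = lambda3) and solved so that the
#' tensor has the requested FA while the mean diffusivity stays at
#' \code{md}.  Used throughout the simulations, with a default MD of
#' 1.1e-3 mm^2/s on the neonatal white-matter scale.
#'
#' @param fa target fractional anisotropy in [0, 1).
#' @param md mean diffusivity, mm^2/s.
#' @param orientation 3x3 rotation; principal eigenvector is its first
#'   column.
#' @param s0 b=0 signal.
#' @return a \code{"TensorSpec"}.
#' @export
prolateTensor <- function(fa, md = 1.1e-3, orientation = diag(3), s0 = 1) {
  if (fa < 0 || fa >= 1) stop("fa must lie in [0, 1)")
  if (md <= 0) stop("md must be positive")
  # lambda1 = md (1 + 2 delta), lambda2 = lambda3 = md (1 - delta) gives
  # FA = 3 delta / sqrt(3 + 6 delta^2)  =>  delta below.
  delta <- fa * sqrt(3) / sqrt(9 - 6 * fa^2)
  tensorSpec(c(md * (1 + 2 * delta), md * (1 - delta), md * (1 - delta)),
             orientation = orientation, s0 = s0)
}

# 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) of a TensorSpec.
.tensorD6 <- function(tensor) {
  d <- tensor$orientation %*% diag(tensor$eigenvalues) %*%
    t(tensor$orientation)
  c(d[1L, 1L], d[2L, 2L], d[3L, 3L], d[1L, 2L], d[1L, 3L], d[2L, 3L])
}

#' Noiseless diffusion-weighted signal of a tensor
#'
#' Forward model of diffusion tensor imaging:
#' \code{S_k = S0 * exp(-sum_ij B_k,ij D_ij)} per volume k.
#'
#' @param tensor a \code{"TensorSpec"} (see [tensorSpec()]).
#' @param scheme a \linkS4class{GradientScheme}.
#' @return numeric vector, one signal per volume.
#' @examples
#' sch <- buildOverplusScheme(700, 1)
#' simulateSignal(tensorSpec(rep(1.1e-3, 3)), sch)
#' @export
simulateSignal <- function(tensor, scheme) {
  stopifnot(inherits(tensor, "TensorSpec"), is(scheme, "GradientScheme"))
  theta <- c(log(tensor$s0), .tensorD6(tensor))
  as.numeric(exp(designMatrix(scheme) %*% theta))
}

# ---- Rician noise ---------------------------------------------------------

.ricianize <- function(x, sigma) {
  n1 <- stats::rnorm(length(x), 0, sigma)
  n2 <- stats::rnorm(length(x), 0, sigma)
  sqrt((x + n1)^2 + n2^2)
}

#' @rdname addRicianNoise
#' @export
setMethod("addRicianNoise", "numeric",
  function(object, snr, s0 = 1, seed = NULL, ...) {
    if (snr <= 0) stop("snr must be positive")
    withSeed(seed, .ricianize(object, s0 / snr))
  })

#' @rdname addRicianNoise
#' @export
setMethod("addRicianNoise", "matrix",
  function(object, snr, s0 = 1, seed = NULL, ...) {
    if (snr <= 0) stop("snr must be positive")
    withSeed(seed, {
      out <- .ricianize(as.numeric(object), s0 / snr)
      matrix(out, nrow(object), ncol(object), dimnames = dimnames(object))
    })
  })

#' @rdname addRicianNoise
#' @export
setMethod("addRicianNoise", "DWIDataset",
  function(object, snr, s0 = NULL, seed = NULL, ...) {
    if (snr <= 0) stop("snr must be positive")
    sig <- dwiSignals(object)
    rd <- SummarizedExperiment::rowData(object)
    if (is.null(s0)) {
      s0 <- if ("truth_s0" %in% colnames(rd)) {
        rd$truth_s0
      } else {
        rowMeans(sig[, bValues(dwiScheme(object)) == 0, drop = FALSE])
      }
    }
    sigma <- rep_len(s0, nrow(sig)) / snr
    withSeed(seed, {
      noisy <- sig
      for (v in seq_len(nrow(sig))) {
        noisy[v, ] <- .ricianize(sig[v, ], sigma[v])
      }
      SummarizedExperiment::assay(object, "signals") <- noisy
      object
    })
  })

# ---- outlier injection ----------------------------------------------------

# Indices (within `weightedIdx`) to corrupt for one voxel/slice unit.
.dropoutIndices <- function(weightedIdx, fraction) {
  nOut <- round(fraction * length(weightedIdx))
  if (nOut == 0L) return(integer())
  sample(weightedIdx, nOut)
}

#' @rdname injectOutliers
#' @export
setMethod("injectOutliers", "DWIDataset",
  function(object, fraction, magnitude = 0.25, seed = NULL, ...) {
    if (fraction < 0 || fraction > 0.5)
      stop("fraction must lie in [0, 0.5]")
    sig <- dwiSignals(object)
    wtd <- which(bValues(dwiScheme(object)) > 0)
    mask <- matrix(FALSE, nrow(sig), ncol(sig))
    withSeed(seed, {
      for (v in seq_len(nrow(sig))) {
        idx <- .dropoutIndices(wtd, fraction)
        sig[v, idx] <- sig[v, idx] * magnitude
        mask[v, idx] <- TRUE
      }
    })
    SummarizedExperiment::assay(object, "signals") <- sig
    SummarizedExperiment::assays(object)[["outliers"]] <- mask
    object
  })

# ---- repetition scaling ---------------------------------------------------

#' @rdname applyRepetitionScaling
#' @export
setMethod("applyRepetitionScaling", "DWIDataset",
  function(object, scales, ...) {
    sch <- dwiScheme(object)
    if (length(scales) != nRepetitions(sch))
      stop("need one scale factor per repetition")
    if (any(scales <= 0)) stop("scale factors must be positive")
    sig <- dwiSignals(object)
    sig <- sig * rep(scales[repetitionIndex(sch)], each = nrow(sig))
    SummarizedExperiment::assay(object, "signals") <- sig
    object
  })

# ---- dataset construction -------------------------------------------------

#' Construct a DWIDataset
#'
#' @param signals voxels x volumes non-negative signal matrix.
#' @param scheme the \linkS4class{GradientScheme} of the acquisition.
#' @param region per-voxel bundle label (see [wmBundles()]); defaults to
#'   \code{"background"}.
#' @param truth optional per-voxel ground truth: a data.frame with columns
#'   \code{fa}, \code{md}, \code{s0} (stored as \code{truth_*} row
#'   metadata).
#' @param outlierMask optional logical voxels x volumes matrix of
#'   corrupted entries.
#' @return a \linkS4class{DWIDataset}.
#' @rdname DWIDataset
#' @aliases DWIDataset-class
#' @export
DWIDataset <- function(signals, scheme, region = "background", truth = NULL,
                       outlierMask = NULL) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  rd <- S4Vectors::DataFrame(region = rep_len(region, nrow(signals)))
  if (!is.null(truth)) {
    stopifnot(nrow(truth) == nrow(signals))
    for (cn in colnames(truth)) rd[[paste0("truth_", cn)]] <- truth[[cn]]
  }
  cd <- S4Vectors::DataFrame(
    bValue = bValues(scheme),
    gx = gradientDirections(scheme)[, 1L],
    gy = gradientDirections(scheme)[, 2L],
    gz = gradientDirections(scheme)[, 3L],
    repetition = repetitionIndex(scheme)
  )
  assays <- list(signals = signals)
  if (!is.null(outlierMask)) assays$outliers <- outlierMask
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = cd,
    metadata = list(scheme = scheme)
  )
  new("DWIDataset", se)
}

#' @rdname DWIDataset
#' @export
setMethod("dwiSignals", "DWIDataset",
          function(object) SummarizedExperiment::assay(object, "signals"))

#' @rdname DWIDataset
#' @export
setMethod("dwiScheme", "DWIDataset",
          function(object) S4Vectors::metadata(object)$scheme)

#' @rdname DWIDataset
#' @export
setMethod("voxelRegions", "DWIDataset",
          function(object) SummarizedExperiment::rowData(object)$region)

#' @rdname DWIDataset
#' @export
setMethod("outlierMask", "DWIDataset", function(object) {
  a <- SummarizedExperiment::assays(object)
  if ("outliers" %in% names(a)) a[["outliers"]] else NULL
})

#' @rdname DWIDataset
#' @export
setMethod("show", "DWIDataset", function(object) {
  cat("DWIDataset: ", nrow(object), " voxel(s) x ", ncol(object),
      " volume(s); scheme \"", dwiScheme(object)@name, "\"; regions: ",
      paste(utils::head(unique(voxelRegions(object)), 5L), collapse = ", "),
      if (length(unique(voxelRegions(object))) > 5L) ", ..." else "",
      "\n", sep = "")
})

#' Simulate a labelled multi-region phantom
#'
#' Builds a \linkS4class{DWIDataset} from per-voxel ground-truth FA values:
#' each voxel gets a prolate tensor at the given FA (fixed MD), a random
#' orientation, and its noiseless forward signal under \code{scheme}.
#'
#' @param faByVoxel numeric vector of ground-truth FA values, one per
#'   voxel.
#' @param scheme a \linkS4class{GradientScheme}.
#' @param region per-voxel region labels (recycled).
#' @param md mean diffusivity, mm^2/s.
#' @param s0 b=0 signal.
#' @param seed optional integer (orientations).
#' @return a \linkS4class{DWIDataset} with \code{truth_*} row metadata.
#' @export
simulatePhantom <- function(faByVoxel, scheme, region = "background",
                            md = 1.1e-3, s0 = 1, seed = NULL) {
  withSeed(seed, {
    nv <- length(faByVoxel)
    sig <- matrix(0, nv, nVolumes(scheme))
    for (v in seq_len(nv)) {
      tn <- prolateTensor(faByVoxel[v], md = md,
                          orientation = randomRotation(), s0 = s0)
      sig[v, ] <- simulateSignal(tn, scheme)
    }
    DWIDataset(sig, scheme, region = region,
               truth = data.frame(fa = faByVoxel, md = md, s0 = s0))
  })
}
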