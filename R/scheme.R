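# Gradient schemes: construction, accessors, quality metrics, bval/bvec IO.

.bmatrix <- function(b, g) b * tcrossprod(g)

# Assemble the concatenated per-volume layout from one repetition block of
# weighted directions: each repetition is (1 b=0 volume, then the block).
.schemeFromBlock <- function(name, dirs, b, nRepetitions) {
  stopifnot(is.matrix(dirs), ncol(dirs) == 3L)
  if (b <= 0) stop("b-value must be positive")
  if (nRepetitions < 1L) stop("nRepetitions must be >= 1")
  nd <- nrow(dirs)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  nPer <- nd + 1L
  n <- nPer * nRepetitions
  bv <- rep(c(0, rep(b, nd)), nRepetitions)
  dd <- matrix(0, n, 3L)
  rep_idx <- integer(n)
  bm <- array(0, c(3L, 3L, n))
  for (r in seq_len(nRepetitions)) {
    off <- (r - 1L) * nPer
    rep_idx[off + seq_len(nPer)] <- r
    for (j in seq_len(nd)) {
      k <- off + 1L + j
      dd[k, ] <- dirs[j, ]
      bm[, , k] <- .bmatrix(b, dirs[j, ])
    }
  }
  new("GradientScheme", name = name, bValues = bv, directions = dd,
      repetition = rep_idx, bMatrices = bm)
}

#' Construct a gradient scheme from per-volume b-values and directions
#'
#' @param name text label for the scheme.
#' @param bValues per-volume b-values in s/mm^2 (0 marks reference volumes).
#' @param directions volumes x 3 matrix of gradient directions; rows for
#'   weighted volumes are normalised to unit length, rows for b=0 volumes
#'   are zeroed.
#' @param repetition optional per-volume repetition index (1-based);
#'   defaults to a single repetition.
#' @return a \linkS4class{GradientScheme}.
#' @export
GradientScheme <- function(name, bValues, directions,
                           repetition = rep(1L, length(bValues))) {
  n <- length(bValues)
  stopifnot(is.matrix(directions), nrow(directions) == n,
            ncol(directions) == 3L, length(repetition) == n)
  dimnames(directions) <- NULL
  directions[bValues == 0, ] <- 0
  wtd <- which(bValues > 0)
  nrm <- sqrt(rowSums(directions[wtd, , drop = FALSE]^2))
  if (any(nrm == 0)) stop("weighted volumes need nonzero directions")
  directions[wtd, ] <- directions[wtd, , drop = FALSE] / nrm
  bm <- array(0, c(3L, 3L, n))
  for (k in wtd) bm[, , k] <- .bmatrix(bValues[k], directions[k, ])
  new("GradientScheme", name = name, bValues = as.numeric(bValues),
      directions = directions, repetition = as.integer(repetition),
      bMatrices = bm)
}

# ---- accessors ------------------------------------------------------------

#' @rdname GradientScheme-class
#' @export
setMethod("nVolumes", "GradientScheme",
          function(object) length(object@bValues))

#' @rdname GradientScheme-class
#' @export
setMethod("nRepetitions", "GradientScheme",
          function(object) length(unique(object@repetition)))

#' @rdname GradientScheme-class
#' @export
setMethod("bValues", "GradientScheme", function(object) object@bValues)

#' @rdname GradientScheme-class
#' @export
setMethod("gradientDirections", "GradientScheme",
          function(object) object@directions)

#' @rdname GradientScheme-class
#' @export
setMethod("bMatrices", "GradientScheme", function(object) object@bMatrices)

#' @rdname GradientScheme-class
#' @export
setMethod("repetitionIndex", "GradientScheme",
          function(object) object@repetition)

#' @rdname GradientScheme-class
#' @export
setMethod("show", "GradientScheme", function(object) {
  nw <- sum(object@bValues > 0)
  cat("GradientScheme \"", object@name, "\": ", nVolumes(object),
      " volumes (", nVolumes(object) - nw, " b=0 + ", nw, " weighted), ",
      nRepetitions(object), " repetition(s), b = ",
      paste(unique(object@bValues[object@bValues > 0]), collapse = "/"),
      " s/mm^2\n", sep = "")
})

#' @rdname designMatrix
#' @export
setMethod("designMatrix", "GradientScheme", function(object) {
  bm <- object@bMatrices
  X <- cbind(1,
             -bm[1L, 1L, ], -bm[2L, 2L, ], -bm[3L, 3L, ],
             -2 * bm[1L, 2L, ], -2 * bm[1L, 3L, ], -2 * bm[2L, 3L, ])
  colnames(X) <- c("logS0", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  X
})

#' @rdname conditionNumber
#' @export
setMethod("conditionNumber", "GradientScheme", function(object) {
  if (sum(object@bValues > 0) < 6L)
    stop("scheme needs at least 6 weighted volumes")
  d <- svd(designMatrix(object), nu = 0, nv = 0)$d
  if (d[7L] <= d[1L] * 1e-10)
    stop("scheme cannot support tensor fit (rank-deficient design)")
  d[1L] / d[7L]
})

# ---- builders -------------------------------------------------------------

#' Over-plus 15-direction scheme
#'
#' Builds the anisotropic vendor-style "over-plus" acquisition used by the
#' simulated protocol: per repetition one b=0 volume plus 15 weighted
#' directions drawn from combined gradient axes (face diagonals, body
#' diagonals and double-axis combinations).  The packaged direction table
#' is a synthetic approximation of a vendor over-plus table -- it
#' reproduces the scheme's defining property, anisotropic angular coverage
#' with a clustered minimum inter-direction angle, not any specific
#' scanner's table.  Pass \code{directions} (or use [readScheme()]) to
#' substitute a measured table.
#'
#' @param b diffusion weighting in s/mm^2 (> 0); the simulated protocol
#'   uses 700.
#' @param nRepetitions number of concatenated repetitions (>= 1); the
#'   simulated protocol uses 3, giving 3 b=0 + 45 weighted volumes.
#' @param directions optional 15 x 3 replacement direction table.
#' @return a \linkS4class{GradientScheme} named \code{"overplus15"}.
#' @examples
#' sch <- buildOverplusScheme(700, 3)
#' nVolumes(sch)   # 48
#' @export
buildOverplusScheme <- function(b = 700, nRepetitions = 3L,
                                directions = NULL) {
  if (b <= 0) stop("b-value must be positive")
  if (is.null(directions)) {
    path <- system.file("extdata", "overplus15_directions.tsv",
                        package = "dtiboot", mustWork = TRUE)
    directions <- as.matrix(utils::read.table(path, header = TRUE,
                                              sep = "\t"))
  }
  .schemeFromBlock("overplus15", directions, b, as.integer(nRepetitions))
}

# Electrostatic-repulsion energy over antipodally symmetric pairs, with
# directions parameterised as (theta, phi) spherical angles.
.repulsionEnergy <- function(par, n) {
  th <- par[seq_len(n)]
  ph <- par[n + seq_len(n)]
  p <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d1 <- sqrt(sum((p[i, ] - p[j, ])^2))
      d2 <- sqrt(sum((p[i, ] + p[j, ])^2))
      e <- e + 1 / max(d1, 1e-9) + 1 / max(d2, 1e-9)
    }
  }
  e
}

#' Uniform (electrostatic-repulsion) gradient scheme
#'
#' Direction table minimising the electrostatic-repulsion energy over
#' antipodally symmetric point pairs -- the conventional "uniform" design
#' against which anisotropic vendor schemes are compared.  Deterministic
#' for a fixed \code{seed}: the optimiser is started from a seeded random
#' configuration and refined with BFGS.
#'
#' @param nDirs number of directions (>= 6; fewer under-determines the
#'   tensor).
#' @param b diffusion weighting in s/mm^2 (> 0).
#' @param nRepetitions number of concatenated repetitions.
#' @param seed integer controlling the optimiser start (default 1).
#' @return a \linkS4class{GradientScheme} named \code{"uniform<nDirs>"}.
#' @export
buildUniformScheme <- function(nDirs, b = 700, nRepetitions = 3L, seed = 1L) {
  if (nDirs < 6L) stop("nDirs must be >= 6 (tensor under-determined)")
  dirs <- withSeed(seed, {
    best <- NULL
    bestE <- Inf
    for (start in 1:3) {
      th0 <- acos(stats::runif(nDirs, -1, 1))
      ph0 <- stats::runif(nDirs, 0, 2 * pi)
      opt <- stats::optim(c(th0, ph0), .repulsionEnergy, n = nDirs,
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      if (opt$value < bestE) {
        bestE <- opt$value
        best <- opt$par
      }
    }
    th <- best[seq_len(nDirs)]
    ph <- best[nDirs + seq_len(nDirs)]
    cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  })
  .schemeFromBlock(paste0("uniform", nDirs), dirs, b,
                   as.integer(nRepetitions))
}

#' Minimum antipodal angle between scheme directions
#'
#' Smallest pairwise angle (degrees) between the distinct weighted
#' directions of a scheme, folding antipodal pairs together.  A small value
#' indicates clustered, anisotropic angular coverage.
#'
#' @param scheme a \linkS4class{GradientScheme}.
#' @return angle in degrees.
#' @export
minimumAntipodalAngle <- function(scheme) {
  g <- unique(round(scheme@directions[scheme@bValues > 0, , drop = FALSE],
                    12L))
  n <- nrow(g)
  ang <- Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ca <- min(abs(sum(g[i, ] * g[j, ])), 1)
      ang <- min(ang, acos(ca))
    }
  }
  ang * 180 / pi
}

# ---- bval/bvec IO ---------------------------------------------------------

#' Read / write FSL-style bval and bvec files
#'
#' \code{readScheme} builds a \linkS4class{GradientScheme} from a
#' \code{.bval} / \code{.bvec} pair (bvec: three rows of x, y, z
#' components, one column per volume, image-coordinate frame);
#' \code{writeScheme} writes one.  Repetition structure is inferred from
#' the positions of b=0 volumes: each b=0 volume starts a new repetition
#' when \code{inferRepetitions} is TRUE.
#'
#' @param bvalPath,bvecPath file paths.
#' @param name scheme label.
#' @param inferRepetitions logical; treat each b=0 volume as the start of a
#'   repetition block.
#' @param scheme a \linkS4class{GradientScheme} to write.
#' @param prefix output path prefix; writes \code{<prefix>.bval} and
#'   \code{<prefix>.bvec}.
#' @return \code{readScheme}: a \linkS4class{GradientScheme};
#'   \code{writeScheme}: the prefix, invisibly.
#' @export
readScheme <- function(bvalPath, bvecPath, name = "custom",
                       inferRepetitions = TRUE) {
  bv <- scan(bvalPath, quiet = TRUE)
  gv <- as.matrix(utils::read.table(bvecPath))
  if (nrow(gv) != 3L || ncol(gv) != length(bv))
    stop("bvec must have 3 rows and one column per b-value")
  rep_idx <- rep(1L, length(bv))
  if (inferRepetitions && sum(bv == 0) > 1L) {
    rep_idx <- cumsum(bv == 0)
    rep_idx[rep_idx == 0L] <- 1L
  }
  GradientScheme(name, bv, t(gv), as.integer(rep_idx))
}

#' @rdname readScheme
#' @export
writeScheme <- function(scheme, prefix) {
  cat(paste(format(scheme@bValues, trim = TRUE), collapse = " "), "\n",
      sep = "", file = paste0(prefix, ".bval"))
  gv <- t(scheme@directions)
  con <- file(paste0(prefix, ".bvec"), "w")
  on.exit(close(con))
  for (r in 1:3) {
    cat(paste(format(gv[r, ], trim = TRUE, digits = 15), collapse = " "),
        "\n", sep = "", file = con)
  }
  invisible(prefix)
}
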