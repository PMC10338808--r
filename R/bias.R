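# Single-voxel Monte-Carlo evaluation of FA estimation error across
# ground-truth FA, gradient schemes and outlier fractions.

#' Monte-Carlo FA bias experiment
#'
#' For every combination of scheme, outlier fraction and ground-truth FA
#' grid value, repeats \code{nTrials} single-voxel simulations: a prolate
#' tensor at fixed MD with a uniformly random orientation is acquired under
#' the scheme, Rician noise is added at the given SNR, dropout outliers are
#' injected at the given fraction (signal multiplied by
#' \code{dropoutMagnitude}; b=0 volumes untouched), the tensor is
#' re-estimated (robust fit by default), and the FA deviation
#' \code{estimated - truth} is recorded.  Within a trial the same noise
#' realisation underlies every outlier fraction, so fraction contrasts are
#' paired.  Fully reproducible under \code{seed}.
#'
#' @param schemes a \linkS4class{GradientScheme} or list of them.
#' @param faGrid ascending ground-truth FA values in [0, 1).
#' @param outlierFractions proportions in [0, 0.5] (default 0 and 0.15).
#' @param nTrials simulations per (scheme, fraction, FA) cell.
#' @param snr signal-to-noise ratio S0/sigma; \code{Inf} for noiseless.
#' @param md mean diffusivity of the simulated tensors, mm^2/s.
#' @param dropoutMagnitude multiplicative attenuation of corrupted volumes.
#' @param robust use the outlier-down-weighting fit (TRUE) or plain WLS.
#' @param seed integer; every random draw derives from it.
#' @return a long-format data.frame (one row per scheme x fraction x grid
#'   point): \code{scheme}, \code{outlier_fraction}, \code{fa_true},
#'   \code{mean_delta_fa}, \code{sd_delta_fa}, \code{n_trials},
#'   \code{snr}, \code{seed}.
#' @seealso [outlierPenalty()]
#' @export
runBiasExperiment <- function(schemes, faGrid = seq(0.05, 0.90, by = 0.05),
                              outlierFractions = c(0, 0.15),
                              nTrials = 2000L, snr = 20, md = 1.1e-3,
                              dropoutMagnitude = 0.25, robust = TRUE,
                              seed = NULL) {
  if (is(schemes, "GradientScheme")) schemes <- list(schemes)
  if (nTrials < 1L) stop("nTrials must be >= 1")
  if (any(faGrid < 0 | faGrid >= 1)) stop("faGrid values must lie in [0, 1)")
  if (is.unsorted(faGrid, strictly = TRUE))
    stop("faGrid must be strictly ascending")
  if (any(outlierFractions < 0 | outlierFractions > 0.5))
    stop("outlier fractions must lie in [0, 0.5]")
  sigma <- if (is.finite(snr)) 1 / snr else 0
  rows <- list()
  withSeed(seed, {
    for (sch in schemes) {
      X <- designMatrix(sch)
      wtd <- which(bValues(sch) > 0)
      n <- nVolumes(sch)
      ones <- rep(1, n)
      for (faT in faGrid) {
        lam <- prolateTensor(faT, md = md)$eigenvalues
        dsum <- matrix(0, length(outlierFractions), 1L)
        dsq <- matrix(0, length(outlierFractions), 1L)
        for (trial in seq_len(nTrials)) {
          R <- randomRotation()
          D <- R %*% (lam * t(R))
          theta <- c(0, D[1L, 1L], D[2L, 2L], D[3L, 3L],
                     D[1L, 2L], D[1L, 3L], D[2L, 3L])
          sClean <- exp(as.numeric(X %*% theta))
          sNoisy <- if (sigma > 0) .ricianize(sClean, sigma) else sClean
          for (fi in seq_along(outlierFractions)) {
            frac <- outlierFractions[fi]
            s <- sNoisy
            if (frac > 0) {
              idx <- .dropoutIndices(wtd, frac)
              s[idx] <- s[idx] * dropoutMagnitude
            }
            y <- log(s)
            f <- if (robust) .robustCore(y, X, ones) else .wlsCore(y, X, ones)
            ev <- pmax(tensorEigen(f$beta[2:7]), 0)
            dFA <- .faRows(matrix(ev, 1L))[1L] - faT
            dsum[fi] <- dsum[fi] + dFA
            dsq[fi] <- dsq[fi] + dFA^2
          }
        }
        for (fi in seq_along(outlierFractions)) {
          m <- dsum[fi] / nTrials
          v <- if (nTrials > 1L) (dsq[fi] - nTrials * m^2) / (nTrials - 1L)
               else 0
          rows[[length(rows) + 1L]] <- data.frame(
            scheme = sch@name, outlier_fraction = outlierFractions[fi],
            fa_true = faT, mean_delta_fa = m,
            sd_delta_fa = sqrt(max(v, 0)), n_trials = nTrials, snr = snr,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
          )
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Largest mean-error difference attributable to outliers
#'
#' Compares two bias curves from [runBiasExperiment()] for the same scheme
#' and FA grid (typically outlier fractions 0 and 0.15): returns the
#' maximum over the grid of the absolute difference in mean FA deviation
#' and the grid FA at which it is attained.
#'
#' @param curve0,curve15 data.frames as returned by [runBiasExperiment()],
#'   each restricted to a single scheme and outlier fraction.
#' @return a list: \code{penalty} (max |difference of mean delta-FA|) and
#'   \code{faAtMax} (grid value where it occurs).
#' @export
outlierPenalty <- function(curve0, curve15) {
  need <- c("scheme", "fa_true", "mean_delta_fa")
  stopifnot(all(need %in% names(curve0)), all(need %in% names(curve15)))
  curve0 <- curve0[order(curve0$fa_true), ]
  curve15 <- curve15[order(curve15$fa_true), ]
  if (length(unique(curve0$scheme)) != 1L ||
      !identical(unique(curve0$scheme), unique(curve15$scheme)))
    stop("curves must come from the same scheme")
  if (!isTRUE(all.equal(curve0$fa_true, curve15$fa_true)))
    stop("FA grids differ between the two curves")
  d <- abs(curve15$mean_delta_fa - curve0$mean_delta_fa)
  i <- which.max(d)
  list(penalty = d[i], faAtMax = curve0$fa_true[i])
}
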