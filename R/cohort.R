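# Two-group cohort simulation: region-wise FA structure, outcome scores
# coupled to mean FA, and optional per-subject phantom signal data.

#' Default per-region FA configuration
#'
#' One row per white-matter bundle label (see [wmBundles()]): the
#' optimal-group mean FA, the within-group SD, and the standardised group
#' difference (Cohen's D; nonoptimal mean = optimal mean - d * sd).
#' Defaults encode region-wise FA group differences between optimal and
#' nonoptimal visual-alertness groups on the scale seen in neonatal
#' cohorts (CST 0.29-0.33 up to FMA 0.70), a neonatal-scale baseline FA
#' per bundle, and a 0.03 within-group SD.
#'
#' @return data.frame: \code{region}, \code{mean_optimal}, \code{sd},
#'   \code{cohen_d}.
#' @export
defaultRegionConfig <- function() {
  base <- c(ATR = 0.22, CST = 0.35, CGY = 0.20, CHI = 0.20, IFOF = 0.25,
            ILF = 0.25, SLF = 0.22, UF = 0.22, SLF_temp = 0.22,
            FMA = 0.35, FMI = 0.30)
  d <- c(ATR_l = 0.30, ATR_r = 0.30, CST_l = 0.29, CST_r = 0.33,
         CGY_l = 0.44, CGY_r = 0.63, CHI_l = 0.57, CHI_r = 0.50,
         IFOF_l = 0.56, IFOF_r = 0.63, ILF_l = 0.54, ILF_r = 0.60,
         SLF_l = 0.45, SLF_r = 0.64, UF_l = 0.61, UF_r = 0.61,
         SLF_temp_l = 0.58, SLF_temp_r = 0.59, FMA = 0.70, FMI = 0.36)
  regions <- wmBundles()
  bundle <- sub("_[lr]$", "", regions)
  data.frame(region = regions,
             mean_optimal = unname(base[bundle]),
             sd = 0.03,
             cohen_d = unname(d[regions]))
}

#' Default outcome-score configuration
#'
#' IQ composites (mean 100, SD 15 scale) and developmental
#' neuropsychological subtest standard scores (mean 10, SD 3 scale) with
#' the per-group means and SDs of the emulated cohort, plus the slope
#' linking each score to a subject's mean white-matter FA.
#'
#' @return data.frame: \code{score}, \code{scale}, \code{mean_optimal},
#'   \code{sd_optimal}, \code{mean_nonoptimal}, \code{sd_nonoptimal},
#'   \code{fa_slope}.
#' @export
defaultOutcomeConfig <- function() {
  data.frame(
    score = c("FSIQ", "VIQ", "PIQ", "Visual_attention", "Arrows",
              "Design_copying", "Imitating_hand_positions",
              "Affect_recognition"),
    scale = c("iq", "iq", "iq", rep("standard", 5L)),
    mean_optimal = c(98, 106, 91, 10.0, 10.8, 8.2, 8.6, 10.0),
    sd_optimal = c(11.6, 12.5, 15.1, 1.6, 2.1, 2.7, 3.3, 1.7),
    mean_nonoptimal = c(98, 108, 87, 9.3, 8.2, 6.8, 5.3, 7.4),
    sd_nonoptimal = c(5.1, 8.5, 9.1, 2.0, 2.3, 0.9, 2.7, 2.4),
    fa_slope = 50
  )
}

#' Cohort simulation configuration
#'
#' @param nPerGroup subjects per group (>= 2).
#' @param regions per-region FA configuration (see
#'   [defaultRegionConfig()]).
#' @param outcomes outcome-score configuration (see
#'   [defaultOutcomeConfig()]).
#' @param sexPMale probability that a subject is male.
#' @return a list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nPerGroup = 10L, regions = defaultRegionConfig(),
                         outcomes = defaultOutcomeConfig(),
                         sexPMale = 0.7) {
  if (nPerGroup < 2L) stop("nPerGroup must be >= 2")
  stopifnot(all(c("region", "mean_optimal", "sd", "cohen_d")
                %in% names(regions)))
  meanNon <- regions$mean_optimal - regions$cohen_d * regions$sd
  if (any(regions$mean_optimal <= 0 | regions$mean_optimal >= 1) ||
      any(meanNon <= 0 | meanNon >= 1))
    stop("infeasible FA targets: group means must lie inside (0, 1)")
  structure(list(nPerGroup = as.integer(nPerGroup), regions = regions,
                 outcomes = outcomes, sexPMale = sexPMale),
            class = "CohortConfig")
}

#' Read a cohort configuration from a YAML file
#'
#' Expected top-level keys: \code{n_per_group}, \code{sex_p_male},
#' \code{regions} (list of records with the columns of
#' [defaultRegionConfig()]) and \code{outcomes} (records with the columns
#' of [defaultOutcomeConfig()]).  Missing keys fall back to the defaults.
#'
#' @param path path to a YAML file.
#' @return a \code{"CohortConfig"}.
#' @export
readCohortConfig <- function(path) {
  y <- yaml::read_yaml(path)
  toDF <- function(records) {
    do.call(rbind, lapply(records, function(r) as.data.frame(r)))
  }
  cohortConfig(
    nPerGroup = y$n_per_group %||% 10L,
    regions = if (is.null(y$regions)) defaultRegionConfig()
              else toDF(y$regions),
    outcomes = if (is.null(y$outcomes)) defaultOutcomeConfig()
               else toDF(y$outcomes),
    sexPMale = y$sex_p_male %||% 0.7
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a two-group cohort
#'
#' Draws a cohort with the configured group sizes: per subject, region FA
#' values from truncated normals (group mean, region SD, support [0, 1)),
#' outcome scores as linear functions of the subject's mean FA plus
#' Gaussian noise -- centred so the configured group mean differences hold
#' in expectation, with residual SD chosen so each score's total SD
#' matches its configured value -- and sex drawn with the configured male
#' proportion.  Optionally also builds per-subject labelled phantom
#' \linkS4class{DWIDataset}s with Rician noise.  Seed-deterministic
#' end-to-end.
#'
#' @param config a \code{"CohortConfig"} (default [cohortConfig()]).
#' @param seed optional integer.
#' @param signals also simulate per-subject DWI phantoms (slower).
#' @param snr phantom SNR when \code{signals} is TRUE.
#' @param voxelsPerRegion phantom voxels per region when \code{signals}
#'   is TRUE.
#' @return a list: \code{cohort} (data.frame: subject_id, group, sex, one
#'   column per outcome score, one \code{fa_<region>} column per region),
#'   \code{faMatrix} (regions x subjects), and \code{datasets} (list of
#'   \linkS4class{DWIDataset} or NULL).
#' @examples
#' sim <- simulateCohort(cohortConfig(nPerGroup = 5), seed = 1)
#' head(sim$cohort[, 1:6])
#' @export
simulateCohort <- function(config = cohortConfig(), seed = NULL,
                           signals = FALSE, snr = 20,
                           voxelsPerRegion = 5L) {
  stopifnot(inherits(config, "CohortConfig"))
  rg <- config$regions
  oc <- config$outcomes
  nR <- nrow(rg)
  n <- 2L * config$nPerGroup
  meanByGroup <- cbind(optimal = rg$mean_optimal,
                       nonoptimal = rg$mean_optimal - rg$cohen_d * rg$sd)
  withSeed(seed, {
    group <- rep(c("optimal", "nonoptimal"), each = config$nPerGroup)
    sex <- ifelse(runif(n) < config$sexPMale, "M", "F")
    faMat <- matrix(0, nR, n, dimnames = list(rg$region, NULL))
    for (i in seq_len(n)) {
      mu <- meanByGroup[, group[i]]
      faMat[, i] <- vapply(seq_len(nR), function(r) {
        rtruncnorm(1L, mu[r], rg$sd[r], lo = 0, hi = 1)
      }, numeric(1L))
    }
    meanFA <- colMeans(faMat)
    expMeanFA <- colMeans(meanByGroup)  # per group
    varMeanFA <- sum(rg$sd^2) / nR^2
    cohort <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                         group = group, sex = sex)
    for (k in seq_len(nrow(oc))) {
      slope <- oc$fa_slope[k]
      mu_k <- ifelse(group == "optimal", oc$mean_optimal[k],
                     oc$mean_nonoptimal[k])
      sd_k <- ifelse(group == "optimal", oc$sd_optimal[k],
                     oc$sd_nonoptimal[k])
      sdResid <- sqrt(pmax(sd_k^2 - slope^2 * varMeanFA, 1e-6))
      centred <- meanFA - expMeanFA[group]
      cohort[[oc$score[k]]] <- mu_k + slope * centred +
        rnorm(n, 0, sdResid)
    }
    for (r in seq_len(nR)) {
      cohort[[paste0("fa_", rg$region[r])]] <- faMat[r, ]
    }
    datasets <- NULL
    if (signals) {
      sch <- buildOverplusScheme(700, 3)
      datasets <- lapply(seq_len(n), function(i) {
        faVox <- rep(faMat[, i], each = voxelsPerRegion)
        regVox <- rep(rg$region, each = voxelsPerRegion)
        ph <- simulatePhantom(faVox, sch, region = regVox)
        addRicianNoise(ph, snr = snr)
      })
      names(datasets) <- cohort$subject_id
    }
    list(cohort = cohort, faMatrix = faMat, datasets = datasets,
         config = config)
  })
}

#' Write / read a cohort table as TSV
#'
#' @param cohort the cohort data.frame from [simulateCohort()].
#' @param path output (or input) file path.
#' @return \code{readCohortTable}: the data.frame;
#'   \code{writeCohortTable}: the path, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
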