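# Between-repetition intensity normalisation.

#' @rdname normalizeRepetitions
#' @export
setMethod("normalizeRepetitions", "DWIDataset",
  function(object, referenceRepetition = 1L, ...) {
    sch <- dwiScheme(object)
    reps <- sort(unique(repetitionIndex(sch)))
    if (!(referenceRepetition %in% reps))
      stop("referenceRepetition not present in the scheme")
    sig <- dwiSignals(object)
    fg <- voxelRegions(object) != "background"
    if (!any(fg)) fg <- rep(TRUE, nrow(sig))  # phantom with no background
    isB0 <- bValues(sch) == 0
    b0Mean <- function(r) {
      cols <- isB0 & repetitionIndex(sch) == r
      if (!any(cols)) stop("repetition ", r, " has no b=0 volume")
      mean(sig[fg, cols, drop = FALSE])
    }
    refMean <- b0Mean(referenceRepetition)
    if (!is.finite(refMean) || refMean <= 0)
      stop("degenerate reference intensity")
    factors <- vapply(reps, function(r) {
      m <- b0Mean(r)
      if (!is.finite(m) || m <= 0) stop("degenerate reference intensity")
      refMean / m
    }, numeric(1L))
    names(factors) <- paste0("rep", reps)
    out <- sig * rep(factors[match(repetitionIndex(sch), reps)],
                     each = nrow(sig))
    SummarizedExperiment::assay(object, "signals") <- out
    list(dataset = object, factors = factors)
  })
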