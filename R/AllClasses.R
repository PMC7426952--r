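#' @import methods
NULL

#' SessionData: one two-region recording session
#'
#' Container for a single recording session: spike timestamps for every unit in
#' two simultaneously recorded regions (by convention \code{"M2"} and
#' \code{"M1"}), plus the trial event table.
#'
#' @slot regions character(2), region labels; the first is treated as the
#'   putative upstream region (M2) throughout.
#' @slot spikes named list (one element per region) of per-unit numeric vectors
#'   of spike times in seconds, each sorted increasing.
#' @slot trials data.frame with one row per trial and columns
#'   \code{trial_id}, \code{door_open}, \code{reach_start}, \code{grasp_onset},
#'   \code{reach_end} (may be NA), \code{success} (logical),
#'   \code{reaction_time}, \code{reach_duration} (all times in seconds).
#' @slot animal character(1) animal identifier.
#' @slot stage character(1), one of \code{"early"}, \code{"late"},
#'   \code{"baseline"}, \code{"perturbed"}.
#'
#' @seealso [makeSessionData()], [generateSession()], [readSessionTSV()]
#' @exportClass SessionData
setClass("SessionData",
  representation(
    regions = "character",
    spikes = "list",
    trials = "data.frame",
    animal = "character",
    stage = "character"
  )
)

setValidity("SessionData", function(object) {
  msgs <- character(0)
  if (length(object@regions) != 2L || anyDuplicated(object@regions))
    msgs <- c(msgs, "exactly two distinct region labels required")
  if (!identical(sort(names(object@spikes)), sort(object@regions)))
    msgs <- c(msgs, "spikes must be a named list keyed by the two regions")
  for (r in names(object@spikes)) {
    un <- object@spikes[[r]]
    if (length(un) < 1L)
      msgs <- c(msgs, sprintf("region %s has no units", r))
    for (u in seq_along(un)) {
      st <- un[[u]]
      if (length(st) && (is.unsorted(st) || any(st < 0)))
        msgs <- c(msgs, sprintf("unsorted or negative spike times: %s unit %d", r, u))
    }
  }
  tr <- object@trials
  need <- c("trial_id", "door_open", "reach_start", "grasp_onset")
  if (!all(need %in% names(tr))) {
    msgs <- c(msgs, "trial table missing required columns")
  } else if (nrow(tr)) {
    ok <- stats::complete.cases(tr[, c("door_open", "reach_start", "grasp_onset")])
    bad <- ok & !(tr$door_open <= tr$reach_start & tr$reach_start <= tr$grasp_onset)
    if (any(bad))
      msgs <- c(msgs, "trial events must satisfy door_open <= reach_start <= grasp_onset")
    rs <- tr$reach_start[ok]
    if (length(rs) > 1L && is.unsorted(rs))
      msgs <- c(msgs, "trials must be ordered and non-overlapping in time")
  }
  if (!object@stage %in% c("early", "late", "baseline", "perturbed"))
    msgs <- c(msgs, "stage must be early/late/baseline/perturbed")
  if (length(msgs)) msgs else TRUE
})

#' BinnedPopulation: time-binned population counts
#'
#' A bins x units spike-count (or rate) matrix with its time axis and
#' provenance: bin width, the alignment event, and the trial index of every
#' row (NA trial index denotes a continuous, un-aligned segment).
#' Bins are half-open \code{[t, t + width)}.
#'
#' @slot counts numeric matrix, rows = time bins, columns = units.
#' @slot binWidth numeric(1), bin width in milliseconds.
#' @slot time numeric, bin-center times (s) relative to the alignment event.
#' @slot event character(1), name of the alignment event ("none" if continuous).
#' @slot trial integer, trial index per row (NA if continuous).
#' @exportClass BinnedPopulation
setClass("BinnedPopulation",
  representation(
    counts = "matrix",
    binWidth = "numeric",
    time = "numeric",
    event = "character",
    trial = "integer"
  )
)

setValidity("BinnedPopulation", function(object) {
  msgs <- character(0)
  if (nrow(object@counts) != length(object@time))
    msgs <- c(msgs, "row count must equal length of time axis")
  if (length(object@trial) != nrow(object@counts))
    msgs <- c(msgs, "trial index must have one entry per row")
  if (any(object@counts < 0))
    msgs <- c(msgs, "counts must be nonnegative")
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msgs <- c(msgs, "binWidth must be a single positive number (ms)")
  if (length(msgs)) msgs else TRUE
})

#' CCAModel: paired canonical-correlation model of two populations
#'
#' Weight matrices for both regions, canonical correlations, the column means
#' removed before fitting, and the bin width / inter-region lag at which the
#' model was fit. Canonical-variable (CV) signs are oriented at fit time (see
#' [fitCCA()]); weights of units dropped for zero variance are zero and the
#' kept-unit mask is recorded.
#'
#' @slot regions character(2) region labels (A = first, B = second).
#' @slot weights named list of two n_units x k weight matrices.
#' @slot cors numeric(k), canonical correlations, nonincreasing in [0, 1].
#' @slot means named list of two column-mean vectors (length n_units).
#' @slot kept named list of two logical vectors marking units kept in the fit.
#' @slot binWidth numeric(1) bin width (ms) of the training data.
#' @slot lag numeric(1) inter-region lag (ms; region B window shifted by +lag).
#' @exportClass CCAModel
setClass("CCAModel",
  representation(
    regions = "character",
    weights = "list",
    cors = "numeric",
    means = "list",
    kept = "list",
    binWidth = "numeric",
    lag = "numeric"
  )
)

setValidity("CCAModel", function(object) {
  msgs <- character(0)
  k <- length(object@cors)
  if (k && (any(diff(object@cors) > 1e-8) ||
            any(object@cors < -1e-8) || any(object@cors > 1 + 1e-8)))
    msgs <- c(msgs, "canonical correlations must be nonincreasing in [0, 1]")
  if (length(object@weights) != 2L || length(object@means) != 2L)
    msgs <- c(msgs, "weights and means must have one entry per region")
  for (r in seq_len(2L)) {
    if (ncol(object@weights[[r]]) != k)
      msgs <- c(msgs, "weight matrices must have one column per CV")
    if (nrow(object@weights[[r]]) != length(object@means[[r]]))
      msgs <- c(msgs, "weights and means disagree on unit count")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SessionData-class construct a SessionData, validating invariants
#' @param regions character(2) region labels.
#' @param spikes named list of per-unit spike-time vectors per region.
#' @param trials trial event data.frame (see slots); \code{reaction_time} and
#'   \code{reach_duration} are filled in if missing.
#' @param animal animal identifier.
#' @param stage stage label.
#' @export
makeSessionData <- function(spikes, trials, regions = names(spikes),
                            animal = "animal1", stage = "late") {
  trials <- as.data.frame(trials)
  if (!"trial_id" %in% names(trials)) trials$trial_id <- seq_len(nrow(trials))
  if (!"reach_end" %in% names(trials)) trials$reach_end <- NA_real_
  if (!"success" %in% names(trials)) trials$success <- NA
  if (!"reaction_time" %in% names(trials))
    trials$reaction_time <- trials$reach_start - trials$door_open
  if (!"reach_duration" %in% names(trials))
    trials$reach_duration <- trials$grasp_onset - trials$reach_start
  new("SessionData", regions = regions, spikes = spikes[regions],
      trials = trials, animal = animal, stage = stage)
}

#' @rdname SessionData-class
#' @param object,x a \code{SessionData}
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))

#' @rdname SessionData-class
#' @export
setMethod("trialTable", "SessionData", function(x) x@trials)

#' @rdname SessionData-class
#' @param region region label
#' @export
setGeneric("spikeTimes", function(x, region) standardGeneric("spikeTimes"))

#' @rdname SessionData-class
#' @export
setMethod("spikeTimes", "SessionData", function(x, region) {
  if (!region %in% x@regions) stop("unknown region: ", region)
  x@spikes[[region]]
})

#' @rdname SessionData-class
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname SessionData-class
#' @export
setMethod("regions", "SessionData", function(x) x@regions)

#' @rdname SessionData-class
#' @export
setMethod("regions", "CCAModel", function(x) x@regions)

#' @rdname BinnedPopulation-class
#' @param x a \code{BinnedPopulation}
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname BinnedPopulation-class
#' @export
setMethod("counts", "BinnedPopulation", function(x) x@counts)

#' @rdname BinnedPopulation-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname BinnedPopulation-class
#' @export
setMethod("binWidth", "BinnedPopulation", function(x) x@binWidth)

#' @rdname BinnedPopulation-class
#' @export
setMethod("binWidth", "CCAModel", function(x) x@binWidth)

#' @rdname BinnedPopulation-class
#' @export
setGeneric("binTimes", function(x) standardGeneric("binTimes"))

#' @rdname BinnedPopulation-class
#' @export
setMethod("binTimes", "BinnedPopulation", function(x) x@time)

#' @rdname CCAModel-class
#' @param x a \code{CCAModel}
#' @export
setGeneric("canonicalCors", function(x) standardGeneric("canonicalCors"))

#' @rdname CCAModel-class
#' @export
setMethod("canonicalCors", "CCAModel", function(x) x@cors)

#' @rdname CCAModel-class
#' @param region region label
#' @export
setGeneric("ccaWeights", function(x, region) standardGeneric("ccaWeights"))

#' @rdname CCAModel-class
#' @export
setMethod("ccaWeights", "CCAModel", function(x, region) {
  if (!region %in% x@regions) stop("unknown region: ", region)
  x@weights[[region]]
})

setMethod("show", "SessionData", function(object) {
  nu <- vapply(object@spikes, length, 0L)
  ns <- vapply(object@spikes, function(r) sum(lengths(r)), 0L)
  cat(sprintf("SessionData: animal %s, stage %s\n", object@animal, object@stage))
  for (r in object@regions)
    cat(sprintf("  %s: %d units, %d spikes\n", r, nu[[r]], ns[[r]]))
  cat(sprintf("  %d trials\n", nrow(object@trials)))
})

setMethod("show", "BinnedPopulation", function(object) {
  cat(sprintf(
    "BinnedPopulation: %d bins x %d units, %g ms bins, aligned to %s\n",
    nrow(object@counts), ncol(object@counts), object@binWidth, object@event))
})

setMethod("show", "CCAModel", function(object) {
  cat(sprintf("CCAModel (%s ~ %s): %d CVs, %g ms bins, lag %g ms\n",
              object@regions[1], object@regions[2], length(object@cors),
              object@binWidth, object@lag))
  if (length(object@cors))
    cat("  canonical correlations:",
        paste(sprintf("%.3f", utils::head(object@cors, 5)), collapse = " "),
        if (length(object@cors) > 5) "...\n" else "\n")
})
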