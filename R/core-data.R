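## Binning, trial alignment, concatenation and normalization.
## Conventions: times in seconds at the API surface, bin widths in ms;
## bins are half-open [t, t + width) so a spike on the right window edge is
## excluded and one sitting exactly on an interior edge belongs to the later bin.

#' Bin spike trains into a counts matrix
#'
#' Counts spikes of each unit in half-open bins \code{[start + i*w, start +
#' (i+1)*w)}. If the bin width does not divide the window, the trailing
#' partial bin is dropped.
#'
#' @param spikes list of numeric vectors, sorted spike times (s), one per unit.
#' @param window numeric(2), window start and end (s).
#' @param binWidthMs bin width in milliseconds.
#' @param event alignment-event name stored in the result (metadata only).
#' @param trial trial index stored for every row (NA for continuous data).
#' @return a [BinnedPopulation-class]
#' @examples
#' bp <- binSpikes(list(c(0.05, 0.15, 0.151)), c(0, 0.4), 100)
#' counts(bp)
#' @export
binSpikes <- function(spikes, window, binWidthMs, event = "none",
                      trial = NA_integer_) {
  if (!is.list(spikes) || length(spikes) == 0L)
    stop("spikes must be a non-empty list of per-unit spike-time vectors")
  if (length(window) != 2L || window[2] <= window[1])
    stop("window end must exceed window start")
  w <- binWidthMs / 1000
  nbin <- floor((window[2] - window[1]) / w + 1e-9)
  if (nbin < 1L) stop("window shorter than one bin")
  edges <- window[1] + w * (0:nbin)
  cnt <- matrix(0L, nbin, length(spikes))
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]
    if (length(st) && is.unsorted(st)) stop("spike times must be sorted (unit ", u, ")")
    st <- st[st >= edges[1] & st < edges[nbin + 1L]]
    if (length(st)) {
      idx <- findInterval(st, edges, left.open = FALSE)
      cnt[, u] <- tabulate(idx, nbins = nbin)
    }
  }
  new("BinnedPopulation", counts = cnt, binWidth = binWidthMs,
      time = edges[-(nbin + 1L)] + w / 2, event = event,
      trial = rep(as.integer(trial), nbin))
}

#' Align trials of a session to a behavioral event
#'
#' Bins each region's population in a window around the given event of every
#' trial. Trials lacking the event or whose window (including any lag shift)
#' leaves the recorded span are dropped and counted.
#'
#' @param session a [SessionData-class]
#' @param event one of \code{"door_open"}, \code{"reach_start"},
#'   \code{"grasp_onset"}.
#' @param window numeric(2) window around the event (s), e.g. \code{c(-1, 1)}.
#' @param binWidthMs bin width (ms).
#' @param lagMs per-region named numeric of window shifts (ms); the shift is
#'   added to the event time before binning (used by [lagBinwidthSweep()]).
#' @return list with per-region lists of per-trial [BinnedPopulation-class]
#'   (\code{tensors}), the retained trial ids (\code{trials}), and
#'   \code{dropped} counts by reason.
#' @export
alignTrials <- function(session, event = "grasp_onset", window = c(-1, 1),
                        binWidthMs = 100, lagMs = NULL) {
  stopifnot(is(session, "SessionData"))
  tr <- trialTable(session)
  if (!event %in% names(tr)) stop("unknown event: ", event)
  ev <- tr[[event]]
  span <- range(unlist(session@spikes, use.names = FALSE), na.rm = TRUE)
  lag <- setNames(numeric(2), session@regions)
  if (!is.null(lagMs)) lag[names(lagMs)] <- lagMs / 1000
  missing_ev <- is.na(ev)
  keep <- !missing_ev
  for (r in session@regions)
    keep <- keep & !is.na(ev) &
      (ev + window[1] + lag[[r]] >= span[1]) &
      (ev + window[2] + lag[[r]] <= span[2])
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no retained trials for event ", event)
  out <- list(trials = tr$trial_id[keep],
              dropped = c(missing_event = sum(missing_ev),
                          out_of_span = sum(!keep) - sum(missing_ev)),
              event = event, window = window, binWidthMs = binWidthMs)
  for (r in session@regions) {
    out[[r]] <- lapply(which(keep), function(i) {
      bp <- binSpikes(session@spikes[[r]],
                      ev[i] + lag[[r]] + window, binWidthMs,
                      event = event, trial = tr$trial_id[i])
      bp@time <- bp@time - ev[i] - lag[[r]]
      bp
    })
  }
  out
}

#' Concatenate per-trial tensors and mean-center columns
#'
#' Stacks per-trial bins x units matrices in trial order and subtracts each
#' column's mean, recording a trial map that recovers the trial and bin of
#' every row.
#'
#' @param tensors list of [BinnedPopulation-class] (or plain matrices) with a
#'   common unit count.
#' @return list: \code{X} centered matrix, \code{means} removed column means,
#'   \code{map} data.frame(row, trial, bin, time).
#' @export
concatAndCenter <- function(tensors) {
  mats <- lapply(tensors, function(t) if (is(t, "BinnedPopulation")) counts(t) else t)
  nu <- unique(vapply(mats, ncol, 0L))
  if (length(nu) != 1L) stop("mismatched unit counts across trials")
  X <- do.call(rbind, mats)
  nb <- vapply(mats, nrow, 0L)
  trial <- rep(seq_along(mats), nb)
  if (is(tensors[[1]], "BinnedPopulation")) {
    tid <- vapply(tensors, function(t) t@trial[1], 0L)
    trial <- rep(tid, nb)
    tm <- unlist(lapply(tensors, binTimes), use.names = FALSE)
  } else tm <- unlist(lapply(nb, seq_len), use.names = FALSE)
  mu <- colMeans(X)
  list(X = sweep(X, 2, mu), means = mu,
       map = data.frame(row = seq_len(nrow(X)), trial = trial,
                        bin = unlist(lapply(nb, seq_len), use.names = FALSE),
                        time = tm))
}

#' z-score each column of a matrix
#'
#' Columns are centered and scaled by the sample (n - 1) standard deviation.
#' Zero-variance columns become all-zero rather than NaN.
#'
#' @param x numeric matrix (rows = observations, columns = units).
#' @return matrix of the same shape.
#' @export
zscorePerUnit <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- Inf   # degenerate columns -> zeros
  sweep(sweep(x, 2, mu), 2, sd, "/")
}
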