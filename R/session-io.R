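## Plain-text session interchange: a spikes TSV (region, unit_id, spike_time_s)
## and a trials TSV (trial_id, door_open_s, reach_start_s, grasp_onset_s,
## reach_end_s, success).

#' Read a session from spike and trial TSV tables
#'
#' @param spikeFile TSV with columns \code{region}, \code{unit_id},
#'   \code{spike_time_s}.
#' @param trialFile TSV with columns \code{trial_id}, \code{door_open_s},
#'   \code{reach_start_s}, \code{grasp_onset_s}, \code{reach_end_s},
#'   \code{success}.
#' @param regions region labels in (upstream, downstream) order; defaults to
#'   the order of first appearance in the spike table.
#' @param animal,stage session metadata.
#' @return a [SessionData-class]
#' @export
readSessionTSV <- function(spikeFile, trialFile, regions = NULL,
                           animal = "animal1", stage = "late") {
  sp <- utils::read.delim(spikeFile, stringsAsFactors = FALSE)
  tr <- utils::read.delim(trialFile, stringsAsFactors = FALSE)
  if (is.null(regions)) regions <- unique(sp$region)
  spikes <- lapply(regions, function(r) {
    d <- sp[sp$region == r, ]
    unname(lapply(split(d$spike_time_s, d$unit_id), sort))
  })
  names(spikes) <- regions
  trials <- data.frame(trial_id = tr$trial_id,
                       door_open = tr$door_open_s,
                       reach_start = tr$reach_start_s,
                       grasp_onset = tr$grasp_onset_s,
                       reach_end = if ("reach_end_s" %in% names(tr)) tr$reach_end_s else NA_real_,
                       success = if ("success" %in% names(tr)) as.logical(tr$success) else NA)
  makeSessionData(spikes, trials, regions = regions, animal = animal, stage = stage)
}

#' Write a session to spike and trial TSV tables
#'
#' @param session a [SessionData-class]
#' @param spikeFile,trialFile output paths.
#' @return invisibly, the session.
#' @export
writeSessionTSV <- function(session, spikeFile, trialFile) {
  stopifnot(is(session, "SessionData"))
  rows <- lapply(session@regions, function(r) {
    un <- session@spikes[[r]]
    data.frame(region = r,
               unit_id = rep(seq_along(un), lengths(un)),
               spike_time_s = sprintf("%.6f", unlist(un, use.names = FALSE)))
  })
  utils::write.table(do.call(rbind, rows), spikeFile, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- trialTable(session)
  fmt <- function(x) ifelse(is.na(x), NA, sprintf("%.6f", x))
  out <- data.frame(trial_id = tr$trial_id, door_open_s = fmt(tr$door_open),
                    reach_start_s = fmt(tr$reach_start),
                    grasp_onset_s = fmt(tr$grasp_onset),
                    reach_end_s = fmt(tr$reach_end), success = tr$success)
  utils::write.table(out, trialFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(session)
}

#' Read an analysis configuration from YAML
#'
#' Sections \code{data}, \code{windows}, \code{cca}, \code{nulls}, \code{seeds}
#' (all optional) are merged over package defaults.
#'
#' @param path YAML file path.
#' @return nested named list of settings.
#' @export
readConfigYAML <- function(path) {
  defaults <- list(
    windows = list(event = "grasp_onset", window = c(-1, 1), binwidth_ms = 100),
    cca = list(folds = 10, lag_ms = 0),
    nulls = list(n_shuffles = 10000, percentile = 95, null_type = "crossval"),
    seeds = list(analysis = 1)
  )
  cfg <- yaml::read_yaml(path)
  for (s in names(cfg))
    defaults[[s]] <- utils::modifyList(defaults[[s]] %||% list(), cfg[[s]])
  defaults
}

`%||%` <- function(a, b) if (is.null(a)) b else a
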