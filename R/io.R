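#' Save / load a trial set archive
#'
#' Lossless round trip of every [TrialSet-class] field through a versioned
#' on-disk container (an RDS file holding a plain named list, so archives
#' remain readable across package versions). \code{loadTrialSet} validates
#' the container and names any missing field in its error message.
#'
#' @param ts a [TrialSet-class].
#' @param path file path.
#' @return \code{saveTrialSet}: \code{path}, invisibly.
#'   \code{loadTrialSet}: the restored [TrialSet-class].
#' @examples
#' f <- tempfile(fileext = ".rds")
#' ts <- TrialSet(array(0, c(2, 1, 5)), fs = 5, window = c(0, 1),
#'                labels = c("left", "right"))
#' saveTrialSet(ts, f)
#' identical(trialLabels(loadTrialSet(f)), c("left", "right"))
#' @export
saveTrialSet <- function(ts, path) {
  stopifnot(is(ts, "TrialSet"))
  payload <- list(
    format = "errpBandit-trialset", version = 1L,
    data = ts@data, fs = ts@fs, window = ts@window,
    channelNames = ts@channelNames, labels = ts@labels,
    outcome = ts@outcome, subjectId = ts@subjectId,
    sessionId = ts@sessionId, runId = ts@runId, metadata = ts@metadata)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveTrialSet
#' @export
loadTrialSet <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("not a trial-set archive: ", conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "errpBandit-trialset"))
    stop("malformed trial-set archive: missing field 'format' or wrong type")
  need <- c("data", "fs", "window", "channelNames", "labels", "outcome",
            "subjectId", "sessionId", "runId")
  miss <- setdiff(need, names(payload))
  if (length(miss))
    stop("malformed trial-set archive: missing field '",
         paste(miss, collapse = "', '"), "'")
  new("TrialSet",
      data = payload$data, fs = payload$fs, window = payload$window,
      channelNames = payload$channelNames, labels = payload$labels,
      outcome = payload$outcome, subjectId = payload$subjectId,
      sessionId = payload$sessionId, runId = payload$runId,
      metadata = if (is.null(payload$metadata)) list() else payload$metadata)
}

#' Export a trial/event log as CSV
#'
#' Writes the per-trial log (trial index, label, executed action, outcome,
#' plus any extra columns such as run) produced by
#' [simulateSnakeProtocol()] or [streamRun()].
#'
#' @param log a data.frame.
#' @param path output CSV path.
#' @export
writeEventLog <- function(log, path) {
  stopifnot(is.data.frame(log))
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
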