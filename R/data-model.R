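#' Construct a continuous EEG recording
#'
#' @param signal numeric matrix \code{n_channels x n_samples} (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelNames ordered unique channel labels; defaults to
#'   \code{rownames(signal)} or \code{"ch1"..}.
#' @param events data.frame with columns \code{sample} (1-based) and
#'   \code{code}; optional extra columns are preserved.
#' @return an [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(3 * 1000), 3), fs = 500,
#'                     channelNames = c("C3", "Cz", "C4"))
#' @export
EEGRecording <- function(signal, fs, channelNames = NULL,
                         events = data.frame(sample = integer(),
                                             code = character())) {
  signal <- as.matrix(signal)
  if (is.null(channelNames)) {
    channelNames <- rownames(signal)
    if (is.null(channelNames))
      channelNames <- paste0("ch", seq_len(nrow(signal)))
  }
  rownames(signal) <- channelNames
  events$sample <- as.integer(events$sample)
  new("EEGRecording", signal = signal, fs = as.numeric(fs),
      channelNames = as.character(channelNames), events = events)
}

#' Construct an epoched trial set
#'
#' @param data numeric array \code{n_trials x n_channels x n_samples}.
#' @param fs sampling rate in Hz.
#' @param window epoch window \code{c(start, end)} in seconds relative to the
#'   alignment event; half-open, so \code{n_samples == round(diff(window)*fs)}.
#' @param channelNames ordered unique channel labels.
#' @param labels per-trial motor-imagery class (\code{"left"}/\code{"right"}).
#' @param outcome per-trial \code{"error"}/\code{"correct"} outcome.
#' @param subjectId,sessionId,runId identifiers; session and run are recycled
#'   to one value per trial.
#' @param metadata free-form list.
#' @return a [TrialSet-class] object.
#' @export
TrialSet <- function(data, fs, window, channelNames = NULL,
                     labels = NULL, outcome = NULL,
                     subjectId = "S01", sessionId = 1L, runId = 1L,
                     metadata = list()) {
  stopifnot(length(dim(data)) == 3L)
  n <- dim(data)[1]
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(dim(data)[2]))
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (is.null(outcome)) outcome <- rep("correct", n)
  new("TrialSet",
      data = data, fs = as.numeric(fs), window = as.numeric(window),
      channelNames = as.character(channelNames),
      labels = as.character(labels), outcome = as.character(outcome),
      subjectId = as.character(subjectId),
      sessionId = rep_len(as.integer(sessionId), n),
      runId = rep_len(as.integer(runId), n),
      metadata = metadata)
}

#' Accessors for EEG containers
#'
#' @param x an [EEGRecording-class] or [TrialSet-class].
#' @param ... for \code{trialData}, optional \code{trial} and \code{channel}
#'   (name or index) selectors.
#' @name TrialSet-accessors
NULL

#' @rdname TrialSet-accessors
#' @export
setMethod("nTrials", "TrialSet", function(x) dim(x@data)[1])

#' @rdname TrialSet-accessors
#' @export
setMethod("nChannels", "TrialSet", function(x) dim(x@data)[2])

#' @rdname TrialSet-accessors
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@signal))

#' @rdname TrialSet-accessors
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@fs)

#' @rdname TrialSet-accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname TrialSet-accessors
#' @export
setMethod("channelNames", "TrialSet", function(x) x@channelNames)

#' @rdname TrialSet-accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)

#' @rdname TrialSet-accessors
#' @export
setMethod("trialWindow", "TrialSet", function(x) x@window)

#' @rdname TrialSet-accessors
#' @export
setMethod("trialLabels", "TrialSet", function(x) x@labels)

#' @rdname TrialSet-accessors
#' @export
setMethod("trialOutcome", "TrialSet", function(x) x@outcome)

#' @rdname TrialSet-accessors
#' @export
setMethod("subjectId", "TrialSet", function(x) x@subjectId)

#' @rdname TrialSet-accessors
#' @export
setMethod("sessionId", "TrialSet", function(x) x@sessionId)

#' @rdname TrialSet-accessors
#' @export
setMethod("runId", "TrialSet", function(x) x@runId)

#' @rdname TrialSet-accessors
#' @export
setMethod("trialData", "TrialSet", function(x, trial = NULL, channel = NULL) {
  if (is.null(trial) && is.null(channel)) return(x@data)
  if (is.character(channel)) {
    channel <- match(channel, x@channelNames)
    if (anyNA(channel)) stop("unknown channel name")
  }
  if (is.null(channel)) channel <- seq_len(nChannels(x))
  if (is.null(trial)) trial <- seq_len(nTrials(x))
  x@data[trial, channel, , drop = !((length(trial) > 1) || (length(channel) > 1))]
})

#' @rdname TrialSet-accessors
#' @export
setMethod("timeAxis", "TrialSet", function(x) {
  n <- dim(x@data)[3]
  x@window[1] + (seq_len(n) - 1L) / x@fs
})

#' Subset a trial set by trial index
#'
#' @param x a [TrialSet-class].
#' @param i trial indices (integer or logical).
#' @param j,...,drop ignored.
#' @return the subset [TrialSet-class].
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) return(x)
  if (is.logical(i)) i <- which(i)
  i <- as.integer(i)
  initialize(x,
    data = x@data[i, , , drop = FALSE],
    labels = x@labels[i], outcome = x@outcome[i],
    sessionId = x@sessionId[i], runId = x@runId[i])
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@signal), ncol(object@signal), object@fs,
              ncol(object@signal) / object@fs))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  cat(sprintf("  events: %d", nrow(object@events)))
  if (nrow(object@events) > 0)
    cat(" (", paste(utils::head(sort(unique(object@events$code)), 6),
                    collapse = ", "), ")", sep = "")
  cat("\n")
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialSet '%s': %d trials x %d channels x %d samples @ %g Hz\n",
              object@subjectId, d[1], d[2], d[3], object@fs))
  cat(sprintf("  window: [%g, %g) s; channels: %s\n",
              object@window[1], object@window[2],
              paste(object@channelNames, collapse = ", ")))
  if (d[1] > 0) {
    cat("  labels: ", paste(sprintf("%s=%d", names(table(object@labels)),
                                    table(object@labels)), collapse = ", "),
        "; outcome: ",
        paste(sprintf("%s=%d", names(table(object@outcome)),
                      table(object@outcome)), collapse = ", "), "\n", sep = "")
  }
})
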