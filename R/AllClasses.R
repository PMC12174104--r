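#' @import methods
NULL

#' Continuous multichannel EEG recording
#'
#' Container for a continuous EEG recording: a channels-by-samples signal
#' matrix in microvolts, its sampling rate, ordered channel labels and an
#' event table. Events mark trial alignment points (directional commands,
#' feedback) with a sample index and a code; recognised codes are
#' \code{"left"}, \code{"right"}, \code{"error_feedback"},
#' \code{"correct_feedback"} and \code{"auto_forward"} (automatic snake
#' steps, which epoching always excludes).
#'
#' @slot signal numeric matrix, \code{n_channels x n_samples}, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames unique ordered channel labels (e.g. C3, Cz, C4).
#' @slot events \code{data.frame} with columns \code{sample} (1-based index
#'   into the recording) and \code{code}; optional extra columns (e.g.
#'   \code{outcome}) are carried into epoched trials.
#'
#' @seealso [EEGRecording()], [epochTrials()], [filterContinuous()]
#' @export
setClass("EEGRecording",
  slots = c(
    signal = "matrix",
    fs = "numeric",
    channelNames = "character",
    events = "data.frame"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (nrow(object@signal) != length(object@channelNames))
    msg <- c(msg, "nrow(signal) must equal length(channelNames)")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  ev <- object@events
  if (nrow(ev) > 0) {
    if (!all(c("sample", "code") %in% names(ev)))
      msg <- c(msg, "events must have columns 'sample' and 'code'")
    else if (any(ev$sample < 1L) || any(ev$sample > ncol(object@signal)))
      msg <- c(msg, "event sample indices must lie within the recording")
  }
  if (length(msg)) msg else TRUE
})

#' Epoched EEG trial set
#'
#' The universal exchange object of the package: epoched multichannel EEG
#' trials with motor-imagery class labels, error/correct outcome codes and
#' timing metadata. Trials are aligned so that time 0 is the alignment event
#' (the snake's movement onset); the epoch window is half-open
#' \code{[t_start, t_end)}, so a (-1, 2) s window at 500 Hz holds exactly
#' 1500 samples.
#'
#' @slot data numeric array \code{n_trials x n_channels x n_samples}
#'   (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot window length-2 numeric, epoch window (seconds) relative to the
#'   alignment event; must contain 0.
#' @slot channelNames unique ordered channel labels.
#' @slot labels per-trial motor-imagery class, \code{"left"}/\code{"right"}
#'   (or \code{NA} when unknown).
#' @slot outcome per-trial interaction outcome, \code{"error"}/\code{"correct"}.
#' @slot subjectId single subject identifier.
#' @slot sessionId integer session index per trial.
#' @slot runId integer run index per trial.
#' @slot metadata free-form list (artifact-rejection logs, simulator
#'   provenance, ...).
#'
#' @seealso [TrialSet()], [epochTrials()], [simulateSnakeProtocol()],
#'   [extractFeatures()]
#' @export
setClass("TrialSet",
  slots = c(
    data = "array",
    fs = "numeric",
    window = "numeric",
    channelNames = "character",
    labels = "character",
    outcome = "character",
    subjectId = "character",
    sessionId = "integer",
    runId = "integer",
    metadata = "list"
  )
)

setValidity("TrialSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    return("'data' must be a 3-d array (trials x channels x samples)")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "'window' must be c(start, end) with start < end")
  else {
    if (!(object@window[1] <= 0 && object@window[2] >= 0))
      msg <- c(msg, "'window' must contain the alignment event at time 0")
    nexp <- round(diff(object@window) * object@fs)
    if (d[3] != nexp)
      msg <- c(msg, sprintf(
        "n_samples (%d) must equal round((t_end - t_start) * fs) = %d under the half-open convention",
        d[3], nexp))
  }
  if (d[2] != length(object@channelNames))
    msg <- c(msg, "dim(data)[2] must equal length(channelNames)")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  for (sl in c("labels", "outcome", "sessionId", "runId")) {
    if (length(slot(object, sl)) != d[1])
      msg <- c(msg, sprintf("'%s' must have length n_trials (%d)", sl, d[1]))
  }
  if (!all(object@labels %in% c("left", "right") | is.na(object@labels)))
    msg <- c(msg, "labels must be 'left', 'right' or NA")
  if (!all(object@outcome %in% c("error", "correct") | is.na(object@outcome)))
    msg <- c(msg, "outcome must be 'error', 'correct' or NA")
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "'subjectId' must be a single identifier")
  if (length(msg)) msg else TRUE
})

#' Contextual-bandit agent base class
#'
#' Virtual parent of [LinUCBAgent-class] and [NeuralUCBAgent-class]. Agent
#' parameters live in an environment slot so that per-trial updates can be
#' done in place; use [agentState()] for a snapshot copy.
#'
#' @slot state environment holding the mutable agent parameters.
#' @slot d context dimension.
#' @slot k number of actions.
#' @export
setClass("BanditAgent",
  representation("VIRTUAL",
    state = "environment",
    d = "integer",
    k = "integer"
  )
)

#' LinUCB agent
#'
#' Disjoint-arm LinUCB: one ridge-regression estimator per action
#' (design matrix \eqn{A_a = I + \sum x x^T} over trials where the action was
#' chosen, response accumulator \eqn{b_a}), with upper-confidence-bound
#' scores \eqn{\theta_a^T x + \alpha \sqrt{x^T A_a^{-1} x}}. The inverse is
#' maintained by Sherman--Morrison rank-1 updates with a periodic full
#' re-solve for numerical hygiene; scores agree with a direct ridge solve to
#' high precision.
#'
#' @slot alpha exploration weight \eqn{\alpha \ge 0}.
#' @seealso [LinUCB()], [ucbScores()], [updateAgent()]
#' @export
setClass("LinUCBAgent",
  contains = "BanditAgent",
  slots = c(alpha = "numeric")
)

#' NeuralUCB agent
#'
#' Contextual bandit whose reward model is a one-hidden-layer ReLU network
#' shared across actions, the action encoded by placing the context in the
#' a-th block of the input (zeros elsewhere). Exploration uses the diagonal
#' approximation of the confidence matrix: the bonus for action a is
#' \eqn{\nu \sqrt{g_a^T \mathrm{diag}(Z)^{-1} g_a / m}} where \eqn{g_a} is the
#' network gradient at (x, a) and Z accumulates squared gradients starting
#' from \eqn{\lambda}.
#'
#' @slot m hidden-layer width.
#' @slot nu exploration scale.
#' @slot lambda ridge initialisation of the confidence accumulator.
#' @slot lr gradient-descent learning rate.
#' @slot stepBudget maximum gradient steps per trial over the replay buffer.
#' @seealso [NeuralUCB()], [ucbScores()], [updateAgent()]
#' @export
setClass("NeuralUCBAgent",
  contains = "BanditAgent",
  slots = c(
    m = "integer",
    nu = "numeric",
    lambda = "numeric",
    lr = "numeric",
    stepBudget = "integer"
  )
)

#' Result of a streamed bandit evaluation
#'
#' Per-trial rewards, the accumulated-error curve (count of zero-reward
#' trials, the cumulative regret under binary rewards) and the final
#' accuracy \eqn{1 - \mathrm{errors}/T}.
#'
#' @slot rewards per-trial rewards in \{0, 1\}.
#' @slot actions per-trial chosen action index.
#' @slot cumErrors non-decreasing accumulated error count.
#' @slot accuracy final accuracy (NA for an empty stream).
#' @slot seed seed used for the run (NA if none).
#' @slot split identity of the evaluated split ("train", "eval", ...).
#' @export
setClass("EvalResult",
  slots = c(
    rewards = "numeric",
    actions = "integer",
    cumErrors = "numeric",
    accuracy = "numeric",
    seed = "numeric",
    split = "character"
  )
)

setValidity("EvalResult", function(object) {
  msg <- character()
  n <- length(object@rewards)
  if (length(object@cumErrors) != n)
    msg <- c(msg, "cumErrors must have one entry per trial")
  if (n > 0) {
    inc <- diff(c(0, object@cumErrors))
    if (any(inc < 0 | inc > 1))
      msg <- c(msg, "cumErrors must be non-decreasing with increments in {0, 1}")
    if (!is.na(object@accuracy) &&
        (object@accuracy < 0 || object@accuracy > 1))
      msg <- c(msg, "accuracy must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
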