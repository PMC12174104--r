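#' @rdname TrialSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("trialWindow", function(x) standardGeneric("trialWindow"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("trialOutcome", function(x) standardGeneric("trialOutcome"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("trialData", function(x, ...) standardGeneric("trialData"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' Score all actions for a context
#'
#' Returns the per-action upper-confidence-bound scores of a bandit agent
#' for a single context vector: estimated reward plus exploration bonus.
#'
#' @param agent a [LinUCBAgent-class] or [NeuralUCBAgent-class].
#' @param x numeric context vector of length \code{agent@d} (finite).
#' @return numeric vector of length \code{agent@k}.
#' @seealso [selectAction()], [updateAgent()]
#' @export
setGeneric("ucbScores", function(agent, x) standardGeneric("ucbScores"))

#' Update a bandit agent after an observed reward
#'
#' Records the (context, action, reward) triple and updates the agent's
#' estimator: for LinUCB the chosen arm's design matrix and response
#' accumulator; for NeuralUCB the squared-gradient confidence accumulator
#' followed by gradient descent on the replay buffer. The agent's state is
#' modified in place; the agent is also returned invisibly.
#'
#' @param agent a bandit agent.
#' @param x context vector.
#' @param action chosen action index (1-based).
#' @param reward observed reward in \[0, 1\] (binary in this framework).
#' @return the updated agent, invisibly.
#' @export
setGeneric("updateAgent",
  function(agent, x, action, reward) standardGeneric("updateAgent"))

#' Snapshot of an agent's internal state
#'
#' Deep-copies the mutable parameters of an agent (so the snapshot is
#' insulated from subsequent in-place updates). For LinUCB this includes
#' the per-action \code{A}, \code{Ainv}, \code{b} and \code{theta}; for
#' NeuralUCB the network weights, confidence diagonal \code{Z} and replay
#' buffer sizes.
#'
#' @param agent a bandit agent.
#' @return a named list.
#' @export
setGeneric("agentState", function(agent) standardGeneric("agentState"))
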