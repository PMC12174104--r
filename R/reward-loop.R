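#' Simulated ErrP detector
#'
#' Confusion model of the ErrP classifier that mediates the reward: on a
#' true error trial an ErrP is detected with probability
#' \code{sensitivity}; on a correct trial a false detection occurs with
#' probability \code{1 - specificity}. The perfect detector (1, 1)
#' reproduces the assumption that the true labels are known, i.e. reward
#' equals \code{action == label} exactly.
#'
#' @param sensitivity P(detect | error), in \[0, 1\].
#' @param specificity P(no detect | correct), in \[0, 1\].
#' @return an object of class \code{"ErrPDetector"}.
#' @export
errpDetector <- function(sensitivity = 1, specificity = 1) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "ErrPDetector")
}

#' ErrP-derived reward
#'
#' Reward rule of the framework: an interaction error occurs when the
#' agent's action differs from the true label; the simulated detector then
#' flags an ErrP with its sensitivity (or falsely with 1 - specificity on
#' correct actions). Reward is 1 when no ErrP is detected and 0 otherwise.
#'
#' @param action chosen action (index or label).
#' @param trueLabel ground-truth action.
#' @param det an [errpDetector()].
#' @return reward in \{0, 1\}.
#' @export
errpReward <- function(action, trueLabel, det = errpDetector()) {
  isError <- action != trueLabel
  pDetect <- if (isError) det$sensitivity else 1 - det$specificity
  detected <- if (pDetect <= 0) FALSE
              else if (pDetect >= 1) TRUE
              else stats::runif(1) < pDetect
  as.numeric(!detected)
}

#' Train/evaluation split of a feature table
#'
#' Either a seeded random shuffle with the first 80\% of trials for
#' training, or the session-based split with sessions 1--3 for training
#' and 4--5 for evaluation.
#'
#' @param feats an \code{MIFeatures} object (see [extractFeatures()]) or
#'   anything with \code{n} rows given by \code{nTrials}.
#' @param mode \code{"shuffle"} (80/20) or \code{"session"}.
#' @param seed integer seed for the shuffle.
#' @param trainFraction training fraction for shuffle mode (default 0.8).
#' @return list with integer index vectors \code{train} and \code{eval}.
#' @export
splitDataset <- function(feats, mode = c("shuffle", "session"), seed = 1L,
                         trainFraction = 0.8) {
  mode <- match.arg(mode)
  n <- if (inherits(feats, "MIFeatures")) nrow(feats$x) else
    if (is.matrix(feats)) nrow(feats) else length(feats)
  if (mode == "shuffle") {
    set.seed(seed)
    perm <- sample.int(n)
    nTrain <- floor(trainFraction * n)
    list(train = perm[seq_len(nTrain)], eval = perm[-seq_len(nTrain)])
  } else {
    sess <- if (inherits(feats, "MIFeatures")) feats$sessionId else
      attr(feats, "sessionId")
    if (is.null(sess) || all(is.na(sess)))
      stop("session split requires session ids")
    list(train = which(sess %in% 1:3), eval = which(sess %in% 4:5))
  }
}

#' Stream trials to a bandit agent
#'
#' Simulates online use: trial by trial, the agent scores the context,
#' selects an action, receives the ErrP-derived reward and (when learning
#' is enabled) updates its estimator. Returns the per-trial reward
#' sequence, the accumulated-error curve and the final accuracy
#' \eqn{1 - \mathrm{errors}/T}. Fully reproducible under \code{seed}.
#'
#' @param agent a bandit agent ([LinUCB()] or [NeuralUCB()]).
#' @param x feature matrix \code{n x d}, or an \code{MIFeatures} object.
#' @param labels per-trial true labels (character or action indices);
#'   taken from \code{x} when it is an \code{MIFeatures} object.
#' @param det an [errpDetector()].
#' @param learn update the agent during the stream (default TRUE; set
#'   FALSE to evaluate a frozen policy).
#' @param seed optional integer seed.
#' @param actions action labels in index order (default
#'   \code{c("left", "right")}).
#' @param tieRule passed to [selectAction()].
#' @param split split identity recorded in the result.
#' @return an [EvalResult-class]. An empty stream yields an empty curve
#'   and \code{NA} accuracy.
#' @export
streamRun <- function(agent, x, labels = NULL, det = errpDetector(),
                      learn = TRUE, seed = NULL,
                      actions = c("left", "right"), tieRule = "first",
                      split = "train") {
  if (inherits(x, "MIFeatures")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$x
  }
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (!is.null(labels) && length(labels) != n)
    stop("features and labels are misaligned: ", n, " rows vs ",
         length(labels), " labels")
  if (is.character(labels)) {
    lab <- match(labels, actions)
    if (anyNA(lab)) stop("labels outside the action set")
  } else lab <- as.integer(labels)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) {
    warning("empty trial stream; accuracy undefined")
    return(new("EvalResult", rewards = numeric(0), actions = integer(0),
               cumErrors = numeric(0), accuracy = NA_real_,
               seed = if (is.null(seed)) NA_real_ else seed, split = split))
  }
  rewards <- numeric(n)
  acts <- integer(n)
  for (i in seq_len(n)) {
    sc <- ucbScores(agent, x[i, ])
    a <- selectAction(sc, tieRule)
    r <- errpReward(a, lab[i], det)
    if (learn) updateAgent(agent, x[i, ], a, r)
    rewards[i] <- r
    acts[i] <- a
  }
  cum <- cumsum(1 - rewards)
  new("EvalResult", rewards = rewards, actions = acts, cumErrors = cum,
      accuracy = accuracyFromErrors(cum[n], n),
      seed = if (is.null(seed)) NA_real_ else seed, split = split)
}

#' Accuracy from the final accumulated regret
#'
#' Accuracy of a streamed run: \code{1 - finalErrors / nTrials}, where the
#' accumulated error count (zero-reward trials) is the cumulative regret
#' under binary rewards.
#'
#' @param finalErrors accumulated error count, in \[0, nTrials\].
#' @param nTrials number of trials (> 0).
#' @return accuracy in \[0, 1\].
#' @export
accuracyFromErrors <- function(finalErrors, nTrials) {
  if (nTrials <= 0) stop("accuracy undefined for an empty stream")
  stopifnot(finalErrors >= 0, finalErrors <= nTrials)
  1 - finalErrors / nTrials
}

setMethod("show", "EvalResult", function(object) {
  n <- length(object@rewards)
  cat(sprintf("EvalResult (%s): %d trials, %d errors, accuracy %s\n",
              object@split, n, if (n) object@cumErrors[n] else 0,
              ifelse(is.na(object@accuracy), "NA",
                     sprintf("%.3f", object@accuracy))))
})

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every configuration of the grid by streaming the training
#' features through a fresh agent for \code{nSeeds} seeds and scoring the
#' mean training accuracy. Deterministic given \code{seeds}; ties keep the
#' first configuration in grid order.
#'
#' @param agentFamily \code{"linucb"} or \code{"neuralucb"}.
#' @param grids named list of parameter vectors; defaults to the printed
#'   grid of the family ([defaultLinUCBGrid()] / [defaultNeuralUCBGrid()]).
#' @param x feature matrix or \code{MIFeatures}.
#' @param labels per-trial labels (see [streamRun()]).
#' @param nSeeds seeds per configuration (default 5).
#' @param det an [errpDetector()].
#' @param seeds explicit seed vector (default \code{seq_len(nSeeds)}).
#' @param actions action labels in index order.
#' @return list with \code{best} (named parameter list), \code{bestScore}
#'   and \code{table} (one row per configuration with its mean accuracy).
#' @export
gridSearch <- function(agentFamily = c("linucb", "neuralucb"), grids = NULL,
                       x, labels = NULL, nSeeds = 5L, det = errpDetector(),
                       seeds = seq_len(nSeeds), actions = c("left", "right")) {
  agentFamily <- match.arg(agentFamily)
  if (is.null(grids))
    grids <- switch(agentFamily, linucb = defaultLinUCBGrid(),
                    neuralucb = defaultNeuralUCBGrid())
  stopifnot(length(grids) > 0, all(lengths(grids) > 0))
  if (inherits(x, "MIFeatures")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$x
  }
  d <- ncol(x)
  k <- length(actions)
  tab <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  score <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cfg <- as.list(tab[i, , drop = FALSE])
    accs <- vapply(seeds, function(s) {
      agent <- switch(agentFamily,
        linucb = LinUCB(d, k, alpha = cfg$alpha),
        neuralucb = NeuralUCB(d, k, m = cfg$m, nu = cfg$nu,
                              lambda = cfg$lambda, lr = cfg$lr, seed = s))
      streamRun(agent, x, labels, det, learn = TRUE, seed = s,
                actions = actions)@accuracy
    }, numeric(1))
    score[i] <- mean(accs)
  }
  tab$meanAccuracy <- score
  best <- which.max(score)            # first maximum in grid order
  list(best = as.list(tab[best, setdiff(names(tab), "meanAccuracy"),
                          drop = FALSE]),
       bestScore = score[best], table = tab)
}

#' Linearly realizable benchmark stream
#'
#' Synthetic two-action benchmark with class-conditional Gaussian contexts:
#' labels alternate at random (balanced in expectation) and the context is
#' \code{label_sign * margin/2 * e1} plus isotropic noise, so the classes
#' are separated by \code{margin} along the first coordinate and the
#' optimal reward mapping is linear. The default noise (SD 0.25, i.e. a
#' 2-sigma margin per class) leaves a visible learning phase while keeping
#' the Bayes accuracy near 0.98. Used for regret-sublinearity and
#' reward-corruption benchmarks.
#'
#' @param n number of trials.
#' @param d context dimension (default 10).
#' @param margin class-mean separation (default 1).
#' @param noiseSd isotropic noise SD (default 0.25).
#' @param seed integer seed.
#' @return list with \code{x} (n x d matrix) and \code{labels}
#'   (\code{"left"}/\code{"right"}).
#' @export
simulateLinearStream <- function(n, d = 10, margin = 1, noiseSd = 0.25,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- sample(c("left", "right"), n, replace = TRUE)
  x <- matrix(stats::rnorm(n * d, 0, noiseSd), n, d)
  x[, 1] <- x[, 1] + ifelse(lab == "right", margin / 2, -margin / 2)
  list(x = x, labels = lab)
}
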