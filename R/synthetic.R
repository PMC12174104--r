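#' Snake-game protocol configuration
#'
#' Parameters of the simulated fast-paced snake protocol: the snake takes
#' one step every \code{stepInterval} seconds, moving straight by default
#' and turning on the subject's directional command. Each run contains
#' \code{trialsPerRun} directional-command trials whose ground-truth label
#' (left/right) comes from the pre-programmed dot path; with probability
#' \code{errorRate} the executed turn opposes the commanded direction,
#' eliciting an error-related potential.
#'
#' @param trialsPerRun directional-command trials per run (default 120).
#' @param nRuns number of runs, at most 10 (default 1).
#' @param errorRate artificial error probability (default 0.05).
#' @param stepInterval seconds between snake steps (default 2).
#' @param fs sampling rate in Hz (default 500).
#' @return an object of class \code{"SnakeProtocolConfig"}.
#' @export
snakeProtocolConfig <- function(trialsPerRun = 120L, nRuns = 1L,
                                errorRate = 0.05, stepInterval = 2,
                                fs = 500) {
  stopifnot(trialsPerRun > 0, nRuns >= 1, nRuns <= 10,
            errorRate >= 0, errorRate <= 1, stepInterval > 0, fs > 0)
  structure(list(trialsPerRun = as.integer(trialsPerRun),
                 nRuns = as.integer(nRuns), errorRate = errorRate,
                 stepInterval = stepInterval, fs = fs),
            class = "SnakeProtocolConfig")
}

#' Motor-imagery signal configuration
#'
#' Controls the synthetic sensorimotor EEG: mu and beta oscillations on C3,
#' Cz and C4 over a 1/f background. During the post-onset motor-imagery
#' period the channel contralateral to the imagined hand (right hand ->
#' C3, left hand -> C4) has its oscillation amplitude scaled by
#' \code{1 - erdDepth} (event-related desynchronization); the ipsilateral
#' channel and Cz are unscaled. \code{erdDepth} is therefore the single
#' class-separability knob: 0 gives no class signal, 1 full suppression.
#'
#' @param muFreq mu-rhythm frequency in Hz, inside \[6, 13\] (default 10).
#' @param betaFreq beta frequency in Hz, inside \[17, 30\] (default 20).
#' @param erdDepth contralateral amplitude attenuation fraction in \[0, 1\]
#'   (default 0.8, a strongly separable subject).
#' @param muAmpUV,betaAmpUV oscillation amplitudes in microvolts.
#' @param backgroundExponent 1/f spectral slope of the background (default 1).
#' @param noiseSd background standard deviation in microvolts (default 5).
#' @param channels ordered montage; must include C3, Cz, C4. Default is the
#'   8-channel fronto-centro-parietal montage used by the snake recordings.
#' @return an object of class \code{"MISignalConfig"}.
#' @export
miSignalConfig <- function(muFreq = 10, betaFreq = 20, erdDepth = 0.8,
                           muAmpUV = 10, betaAmpUV = 5,
                           backgroundExponent = 1, noiseSd = 5,
                           channels = c("FC1", "FC2", "C3", "Cz", "C4",
                                        "CP1", "CP2", "Pz")) {
  stopifnot(muFreq >= 6, muFreq <= 13, betaFreq >= 17, betaFreq <= 30,
            erdDepth >= 0, erdDepth <= 1, noiseSd >= 0,
            all(c("C3", "Cz", "C4") %in% channels))
  structure(list(muFreq = muFreq, betaFreq = betaFreq, erdDepth = erdDepth,
                 muAmpUV = muAmpUV, betaAmpUV = betaAmpUV,
                 backgroundExponent = backgroundExponent, noiseSd = noiseSd,
                 channels = channels),
            class = "MISignalConfig")
}

#' Error-related potential template
#'
#' Stereotyped interaction-ErrP waveform added on error trials at
#' fronto-central channels: Gaussian-windowed deflections with a positive
#' peak near 200 ms, a negative peak near 252 ms and a positive peak near
#' 348 ms after movement onset. Widths are full width at half maximum.
#'
#' @param latenciesMs strictly increasing component latencies in ms.
#' @param amplitudesUV signed component amplitudes in microvolts.
#' @param widthsMs component FWHM in ms (> 0).
#' @param channels channels receiving the deflections (fronto-central role).
#' @return an object of class \code{"ErrPTemplate"}.
#' @export
errpTemplate <- function(latenciesMs = c(200, 252, 348),
                         amplitudesUV = c(5, -5, 5),
                         widthsMs = c(60, 60, 60),
                         channels = c("FC1", "FC2", "Cz")) {
  stopifnot(length(latenciesMs) == length(amplitudesUV),
            length(latenciesMs) == length(widthsMs),
            all(diff(latenciesMs) > 0), all(widthsMs > 0))
  structure(list(latenciesMs = latenciesMs, amplitudesUV = amplitudesUV,
                 widthsMs = widthsMs, channels = channels),
            class = "ErrPTemplate")
}

#' Evaluate an ErrP template waveform on a time axis
#'
#' @param template an [errpTemplate()].
#' @param time time axis in seconds (0 = movement onset).
#' @return numeric waveform in microvolts.
#' @export
errpWaveform <- function(template, time) {
  w <- numeric(length(time))
  for (i in seq_along(template$latenciesMs)) {
    sigma <- template$widthsMs[i] / 1000 / (2 * sqrt(2 * log(2)))
    mu <- template$latenciesMs[i] / 1000
    w <- w + template$amplitudesUV[i] * exp(-(time - mu)^2 / (2 * sigma^2))
  }
  w
}

#' 1/f background EEG noise
#'
#' Zero-mean Gaussian noise whose power spectral density follows
#' \eqn{f^{-exponent}}, generated by spectral shaping of white noise
#' (amplitude weight \eqn{f^{-exponent/2}}, DC removed). \code{exponent = 0}
#' gives white noise. Each channel is independent; the realised standard
#' deviation equals \code{sd}.
#'
#' @param nChannels,nSamples output dimensions (\code{nSamples > 1}).
#' @param fs sampling rate in Hz.
#' @param exponent 1/f slope (default 1).
#' @param sd standard deviation in microvolts; 0 yields all zeros.
#' @return numeric matrix \code{nChannels x nSamples}.
#' @export
generateBackground <- function(nChannels, nSamples, fs, exponent = 1, sd = 1) {
  stopifnot(nSamples > 1, nChannels >= 1, sd >= 0)
  if (sd == 0) return(matrix(0, nChannels, nSamples))
  freqs <- seq(0, nSamples - 1) * fs / nSamples
  freqs <- pmin(freqs, fs - freqs)              # two-sided axis
  wgt <- c(0, freqs[-1]^(-exponent / 2))        # kill DC
  out <- matrix(0, nChannels, nSamples)
  for (ch in seq_len(nChannels)) {
    spec <- stats::fft(stats::rnorm(nSamples)) * wgt
    x <- Re(stats::fft(spec, inverse = TRUE)) / nSamples
    x <- x - mean(x)
    s <- stats::sd(x)
    out[ch, ] <- if (s > 0) x * (sd / s) else x
  }
  out
}

#' Synthesize one motor-imagery trial
#'
#' One epoched trial of the configured montage: mu and beta oscillations
#' (random phase per trial, channel and band) on C3, Cz and C4 over 1/f
#' background on all channels. From onset (t >= 0) to the end of the epoch
#' the channel contralateral to \code{label} has its oscillation amplitude
#' multiplied by \code{1 - erdDepth}; Cz and the ipsilateral channel carry
#' the baseline oscillation throughout.
#'
#' @param label \code{"left"} or \code{"right"} imagined hand.
#' @param miCfg a [miSignalConfig()].
#' @param window epoch window in seconds (must contain 0).
#' @param fs sampling rate in Hz.
#' @return numeric matrix \code{n_channels x n_samples}.
#' @export
generateMITrial <- function(label, miCfg = miSignalConfig(),
                            window = c(-1, 2), fs = 500) {
  if (!label %in% c("left", "right"))
    stop("unknown motor-imagery label: ", label)
  ns <- as.integer(round(diff(window) * fs))
  time <- window[1] + (seq_len(ns) - 1L) / fs
  chans <- miCfg$channels
  x <- generateBackground(length(chans), ns, fs,
                          miCfg$backgroundExponent, miCfg$noiseSd)
  rownames(x) <- chans
  contra <- if (label == "right") "C3" else "C4"
  post <- time >= 0
  for (ch in c("C3", "Cz", "C4")) {
    env <- rep(1, ns)
    if (ch == contra) env[post] <- 1 - miCfg$erdDepth
    for (band in c("mu", "beta")) {
      f <- if (band == "mu") miCfg$muFreq else miCfg$betaFreq
      a <- if (band == "mu") miCfg$muAmpUV else miCfg$betaAmpUV
      phi <- stats::runif(1, 0, 2 * pi)
      x[ch, ] <- x[ch, ] + a * env * sin(2 * pi * f * time + phi)
    }
  }
  x
}

#' Add an ErrP deflection to a trial
#'
#' Adds the template waveform, time-locked to \code{onsetS}, to the
#' template's fronto-central channels (those present in
#' \code{channelNames}). Correct trials are left untouched by the caller;
#' a zero-amplitude template leaves the trial unchanged.
#'
#' @param trial numeric matrix \code{n_channels x n_samples}.
#' @param template an [errpTemplate()].
#' @param window epoch window in seconds.
#' @param fs sampling rate in Hz.
#' @param onsetS onset of the eliciting event in seconds (default 0).
#' @param channelNames channel labels of \code{trial} rows; defaults to
#'   \code{rownames(trial)}.
#' @return the trial with deflections added.
#' @export
addErrP <- function(trial, template = errpTemplate(), window = c(-1, 2),
                    fs = 500, onsetS = 0, channelNames = rownames(trial)) {
  stopifnot(onsetS >= window[1], onsetS <= window[2])
  ns <- ncol(trial)
  time <- window[1] + (seq_len(ns) - 1L) / fs - onsetS
  wave <- errpWaveform(template, time)
  idx <- which(channelNames %in% template$channels)
  for (ch in idx) trial[ch, ] <- trial[ch, ] + wave
  trial
}

#' Simulate the snake-game protocol
#'
#' Generates the full protocol: per run, a pre-programmed dot path yields a
#' balanced sequence of ground-truth directional labels; the subject images
#' the corresponding hand movement on each command trial; with probability
#' \code{errorRate} (independent Bernoulli draws) the executed turn opposes
#' the path, the outcome is flagged \code{"error"} and the ErrP template is
#' added to the trial's fronto-central channels. Automatic forward steps
#' between commands are recorded in the event log only (epoching excludes
#' them, so they yield no trials).
#'
#' @param proto a [snakeProtocolConfig()].
#' @param miCfg a [miSignalConfig()].
#' @param template an [errpTemplate()].
#' @param window epoch window in seconds (default \code{c(-1, 2)}).
#' @param seed optional integer seed for full reproducibility.
#' @param signals if \code{FALSE}, skip EEG synthesis and return only the
#'   event log (fast path for protocol-level statistics).
#' @return a list with \code{trials} (a [TrialSet-class], or \code{NULL}
#'   when \code{signals = FALSE}) and \code{log} (a data.frame with columns
#'   run, trial, code, label, action, outcome).
#' @examples
#' sim <- simulateSnakeProtocol(snakeProtocolConfig(trialsPerRun = 10),
#'                              signals = FALSE, seed = 1)
#' table(sim$log$outcome)
#' @export
simulateSnakeProtocol <- function(proto = snakeProtocolConfig(),
                                  miCfg = miSignalConfig(),
                                  template = errpTemplate(),
                                  window = c(-1, 2), seed = NULL,
                                  signals = TRUE) {
  stopifnot(inherits(proto, "SnakeProtocolConfig"))
  if (!is.null(seed)) set.seed(seed)
  logs <- vector("list", proto$nRuns)
  for (r in seq_len(proto$nRuns)) {
    npr <- proto$trialsPerRun
    # balanced dot path: equal left/right turns in shuffled order
    labels <- sample(rep(c("left", "right"), length.out = npr))
    flip <- stats::runif(npr) < proto$errorRate
    action <- ifelse(flip, ifelse(labels == "left", "right", "left"), labels)
    auto <- sample(0:2, npr, replace = TRUE)    # straight steps before a turn
    logs[[r]] <- data.frame(
      run = r, trial = seq_len(npr), code = "command",
      label = labels, action = action,
      outcome = ifelse(flip, "error", "correct"),
      autoStepsBefore = auto)
  }
  log <- do.call(rbind, logs)
  trials <- NULL
  if (signals) {
    ns <- as.integer(round(diff(window) * proto$fs))
    dat <- array(0, dim = c(nrow(log), length(miCfg$channels), ns))
    for (i in seq_len(nrow(log))) {
      tr <- generateMITrial(log$label[i], miCfg, window, proto$fs)
      if (log$outcome[i] == "error")
        tr <- addErrP(tr, template, window, proto$fs,
                      channelNames = miCfg$channels)
      dat[i, , ] <- tr
    }
    trials <- TrialSet(dat, fs = proto$fs, window = window,
                       channelNames = miCfg$channels,
                       labels = log$label, outcome = log$outcome,
                       sessionId = 1L, runId = log$run,
                       metadata = list(protocol = proto,
                                       erdDepth = miCfg$erdDepth))
  }
  list(trials = trials, log = log)
}

#' Generate a synthetic multi-subject cohort
#'
#' Deterministically (given \code{seed}) simulates one snake-protocol
#' dataset per subject with per-subject class separability
#' \code{erdDepths[i]}.
#'
#' @param nSubjects number of subjects.
#' @param erdDepths separability per subject
#'   (length \code{nSubjects}).
#' @param seed integer seed.
#' @param proto,template,window,... passed to [simulateSnakeProtocol()];
#'   \code{...} reaches [miSignalConfig()].
#' @return a list of [TrialSet-class] objects.
#' @export
generateCohort <- function(nSubjects, erdDepths, seed,
                           proto = snakeProtocolConfig(),
                           template = errpTemplate(),
                           window = c(-1, 2), ...) {
  stopifnot(length(erdDepths) == nSubjects)
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, nSubjects)
  out <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    sim <- simulateSnakeProtocol(
      proto, miSignalConfig(erdDepth = erdDepths[i], ...), template,
      window = window, seed = subSeeds[i], signals = TRUE)
    ts <- sim$trials
    ts@subjectId <- sprintf("S%02d", i)
    out[[i]] <- ts
  }
  out
}
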