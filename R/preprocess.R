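#' FIR filter specification
#'
#' Band-pass plus notch specification for continuous EEG, implemented as
#' Hamming windowed-sinc FIR stages applied separately (high-pass, low-pass,
#' notch), each with zero phase via delay-compensated centred convolution.
#'
#' @param band \code{c(low, high)} pass band in Hz; defaults to the
#'   0.5--100 Hz band used for broadband EEG cleaning.
#' @param notch mains frequency in Hz (default 50, site-dependent);
#'   \code{NA} disables the notch stage.
#' @param notchWidth half-width of the notch stop band in Hz.
#' @param taps kernel length (odd). Default \code{NULL} picks a 1-second
#'   kernel, \code{2*floor(fs/2)+1} taps, at filter time.
#' @return an object of class \code{"FilterSpec"}.
#' @export
filterSpec <- function(band = c(0.5, 100), notch = 50, notchWidth = 2,
                       taps = NULL) {
  stopifnot(length(band) == 2L)
  if (!(band[1] > 0 && band[1] < band[2]))
    stop("invalid filter spec: need 0 < low < high")
  structure(list(band = as.numeric(band), notch = notch,
                 notchWidth = notchWidth, taps = taps),
            class = "FilterSpec")
}

# Odd-length Hamming windowed-sinc kernels. The high-pass is built by
# spectral inversion of a DC-normalised low-pass so its DC gain is exactly 0.
.firKernels <- function(spec, fs) {
  taps <- spec$taps
  if (is.null(taps)) taps <- 2L * floor(fs / 2) + 1L
  taps <- as.integer(taps)
  if (taps %% 2L == 0L) taps <- taps + 1L
  ny <- fs / 2
  lowc <- signal::fir1(taps - 1L, spec$band[1] / ny, type = "low")
  lowc <- lowc / sum(lowc)                     # unit DC gain
  hp <- -lowc
  hp[(taps + 1L) / 2L] <- hp[(taps + 1L) / 2L] + 1
  lp <- signal::fir1(taps - 1L, spec$band[2] / ny, type = "low")
  out <- list(hp = hp, lp = lp)
  if (!is.null(spec$notch) && !is.na(spec$notch)) {
    out$notch <- signal::fir1(taps - 1L,
      c(spec$notch - spec$notchWidth, spec$notch + spec$notchWidth) / ny,
      type = "stop")
  }
  out
}

# Zero-phase application of an odd, linear-phase FIR kernel: reflect-pad by
# the group delay, convolve, take the centred segment. For a symmetric kernel
# this compensates the delay exactly (no phase distortion at any frequency).
.zeroPhaseFIR <- function(x, h) {
  n <- length(x)
  half <- (length(h) - 1L) %/% 2L
  pad <- min(half, n - 1L)
  left <- if (pad > 0) 2 * x[1] - x[seq(pad + 1L, 2L)] else numeric()
  right <- if (pad > 0) 2 * x[n] - x[seq(n - 1L, n - pad)] else numeric()
  xp <- c(left, x, right, numeric(max(0L, half - pad) * 2L))
  y <- stats::convolve(xp, rev(h), type = "open")
  y[seq(half + pad + 1L, length.out = n)]
}

#' Zero-phase FIR filtering of a continuous recording
#'
#' Applies the high-pass, low-pass and notch stages of a [filterSpec()]
#' separately, each as a Hamming windowed-sinc FIR with exact group-delay
#' compensation (zero phase), so ERP component latencies are not shifted.
#'
#' @param rec an [EEGRecording-class].
#' @param spec a [filterSpec()].
#' @return the filtered [EEGRecording-class] (same shape and events).
#' @examples
#' rec <- EEGRecording(matrix(sin(2 * pi * 10 * (0:2499) / 500), 1), fs = 500)
#' out <- filterContinuous(rec, filterSpec())
#' @export
filterContinuous <- function(rec, spec = filterSpec()) {
  stopifnot(is(rec, "EEGRecording"), inherits(spec, "FilterSpec"))
  if (spec$band[2] >= rec@fs / 2)
    stop("invalid filter spec: band edge ", spec$band[2],
         " Hz is not below the Nyquist frequency ", rec@fs / 2, " Hz")
  ker <- .firKernels(spec, rec@fs)
  sig <- rec@signal
  for (h in ker) {
    for (ch in seq_len(nrow(sig))) sig[ch, ] <- .zeroPhaseFIR(sig[ch, ], h)
  }
  initialize(rec, signal = sig)
}

#' Epoch a recording around alignment events
#'
#' Cuts one trial per selected event using the half-open window convention:
#' trial sample 1 is recording sample \code{event + round(start * fs)} and
#' each trial holds \code{round((end - start) * fs)} samples. Events coded
#' \code{"auto_forward"} (automatic snake steps) never yield trials; events
#' whose window does not fit inside the recording are skipped with a warning.
#'
#' @param rec an [EEGRecording-class].
#' @param codes event codes to epoch around (default the directional
#'   commands \code{"left"}/\code{"right"}).
#' @param window epoch window \code{c(start, end)} in seconds.
#' @param ... passed to [TrialSet()] (\code{subjectId}, \code{sessionId}, ...).
#' @return a [TrialSet-class]; labels are taken from the event code when it
#'   is \code{"left"}/\code{"right"}, outcomes from an \code{outcome} event
#'   column when present.
#' @export
epochTrials <- function(rec, codes = c("left", "right"),
                        window = c(-1, 2), ...) {
  stopifnot(is(rec, "EEGRecording"))
  codes <- setdiff(codes, "auto_forward")
  ev <- rec@events[rec@events$code %in% codes, , drop = FALSE]
  ns <- as.integer(round(diff(window) * rec@fs))
  off <- as.integer(round(window[1] * rec@fs))
  start <- ev$sample + off
  ok <- start >= 1L & (start + ns - 1L) <= ncol(rec@signal)
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge; skipped")
  ev <- ev[ok, , drop = FALSE]
  dat <- array(0, dim = c(nrow(ev), nrow(rec@signal), ns))
  for (i in seq_len(nrow(ev))) {
    s <- ev$sample[i] + off
    dat[i, , ] <- rec@signal[, seq(s, length.out = ns), drop = FALSE]
  }
  labels <- ifelse(ev$code %in% c("left", "right"), ev$code, NA_character_)
  outcome <- if ("outcome" %in% names(ev)) ev$outcome else rep("correct", nrow(ev))
  TrialSet(dat, fs = rec@fs, window = window,
           channelNames = rec@channelNames,
           labels = labels, outcome = outcome, ...)
}

#' Amplitude-threshold artifact rejection
#'
#' Removes trials whose peak absolute amplitude on any channel exceeds the
#' threshold: an automated, reproducible stand-in for manual artifact
#' screening. The removal log (trial index, offending channel, peak value)
#' is kept in \code{metadata(ts)$rejectionLog}.
#'
#' @param ts a [TrialSet-class].
#' @param ampUV rejection threshold in microvolts (default 100).
#' @return the cleaned [TrialSet-class]. Idempotent.
#' @export
rejectArtifacts <- function(ts, ampUV = 100) {
  stopifnot(is(ts, "TrialSet"), ampUV > 0)
  n <- nTrials(ts)
  if (n == 0L) return(ts)
  peaks <- apply(abs(ts@data), c(1, 2), max)      # trials x channels
  worst <- apply(peaks, 1, max)
  bad <- which(worst > ampUV)
  log <- data.frame(
    trial = bad,
    channel = ts@channelNames[apply(peaks[bad, , drop = FALSE], 1, which.max)],
    peakUV = worst[bad],
    row.names = NULL
  )
  out <- if (length(bad)) ts[-bad] else ts
  out@metadata$rejectionLog <- rbind(ts@metadata$rejectionLog, log)
  out@metadata$rejectionThresholdUV <- ampUV
  out
}
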