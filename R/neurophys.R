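#' Baseline-corrected ERP average
#'
#' Per-trial baseline correction (mean over the baseline window subtracted
#' per channel) followed by the trial average over one outcome condition.
#'
#' @param ts a [TrialSet-class].
#' @param condition \code{"error"} or \code{"correct"} (matched against
#'   \code{trialOutcome}); \code{NULL} averages all trials.
#' @param baseline baseline window in seconds (default \code{c(-0.2, 0)}).
#' @return a list with \code{time} (s), \code{mean} (channels x time
#'   matrix, microvolts), \code{n} trials and \code{baseline}.
#' @export
erpAverage <- function(ts, condition = NULL, baseline = c(-0.2, 0)) {
  stopifnot(is(ts, "TrialSet"))
  idx <- if (is.null(condition)) seq_len(nTrials(ts)) else
    which(trialOutcome(ts) == condition)
  if (length(idx) == 0L)
    stop("no trials in condition '", condition, "'")
  time <- timeAxis(ts)
  bIdx <- which(time >= baseline[1] & time < baseline[2])
  if (length(bIdx) == 0L) stop("baseline window outside the epoch")
  dat <- ts@data[idx, , , drop = FALSE]
  bmean <- apply(dat[, , bIdx, drop = FALSE], c(1, 2), mean)
  corrected <- sweep(dat, c(1, 2), bmean)
  avg <- apply(corrected, c(2, 3), mean)
  rownames(avg) <- channelNames(ts)
  list(time = time, mean = avg, n = length(idx), baseline = baseline)
}

#' Error-minus-correct difference wave
#'
#' Pointwise difference of two ERP averages on identical time axes; the
#' ErrP estimate is the error average minus the correct average.
#'
#' @param errAvg,corAvg results of [erpAverage()].
#' @return a list with \code{time} and \code{wave} (channels x time).
#' @export
differenceWave <- function(errAvg, corAvg) {
  if (length(errAvg$time) != length(corAvg$time) ||
      max(abs(errAvg$time - corAvg$time)) > 1e-9)
    stop("ERP averages have mismatching time axes")
  list(time = errAvg$time, wave = errAvg$mean - corAvg$mean)
}

# vectorized Welch two-sample t statistic per column
.welchT <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df)
}

#' Pointwise two-sample test with FDR correction
#'
#' Welch's t test per time point between error and correct trials of one
#' channel, with Benjamini--Hochberg step-up control of the false
#' discovery rate across time points.
#'
#' @param errTrials,corTrials numeric matrices \code{trials x time} (>= 2
#'   trials each).
#' @param alpha FDR level (default 0.05).
#' @return list with \code{p} (raw p per time point), \code{pAdj}
#'   (BH-adjusted) and \code{mask} (logical rejections at \code{alpha}).
#' @export
pointwiseFDR <- function(errTrials, corTrials, alpha = 0.05) {
  stopifnot(nrow(errTrials) >= 2, nrow(corTrials) >= 2,
            ncol(errTrials) == ncol(corTrials))
  wt <- .welchT(errTrials, corTrials)
  p <- 2 * stats::pt(abs(wt$t), wt$df, lower.tail = FALSE)
  pAdj <- stats::p.adjust(p, method = "BH")
  list(p = p, pAdj = pAdj, mask = pAdj <= alpha, alpha = alpha)
}

#' Find signed peaks of a difference wave
#'
#' Local extrema whose absolute amplitude exceeds a prominence threshold,
#' ordered by latency with signed polarity. Peaks are filtered by
#' topographic prominence (height of the extremum above its highest
#' enclosing saddle), which suppresses the micro-extrema that averaged
#' background noise superimposes on broad components; a positive peak must
#' additionally be positive, a negative peak negative. The default
#' threshold combines a noise floor (twice the pre-onset, t < 0, standard
#' deviation of the wave) with a relative floor (half the largest absolute
#' amplitude inside the search window), so a flat wave yields no peaks and
#' noiseless template waves are recovered exactly; components smaller than
#' half the dominant one are treated as sub-threshold.
#'
#' @param wave numeric vector, uniformly sampled.
#' @param time time axis in seconds (same length).
#' @param searchWindow restrict peaks to this window in seconds
#'   (default \code{c(0, 0.6)}).
#' @param prominence prominence threshold in microvolts; \code{NULL} uses
#'   \code{max(2 * sd(wave[time < 0]), 0.5 * max(|wave|) in window)}.
#' @return data.frame with \code{latencyMs}, \code{polarity} (+1/-1) and
#'   \code{amplitude}, ordered by latency.
#' @export
findPeaks <- function(wave, time, searchWindow = c(0, 0.6),
                      prominence = NULL) {
  stopifnot(length(wave) == length(time))
  if (is.null(prominence)) {
    pre <- wave[time < 0]
    noiseFloor <- if (length(pre) > 1) 2 * stats::sd(pre) else 0
    inw <- wave[time >= searchWindow[1] & time <= searchWindow[2]]
    relFloor <- if (length(inw)) 0.5 * max(abs(inw)) else 0
    prominence <- max(noiseFloor, relFloor)
  }
  n <- length(wave)
  if (n < 3) return(data.frame(latencyMs = numeric(), polarity = numeric(),
                               amplitude = numeric()))
  d1 <- diff(wave)
  isMax <- c(FALSE, d1[-length(d1)] > 0 & d1[-1] <= 0, FALSE)
  isMin <- c(FALSE, d1[-length(d1)] < 0 & d1[-1] >= 0, FALSE)
  inWin <- time >= searchWindow[1] & time <= searchWindow[2]
  pos <- which(isMax & inWin & wave > 0)
  neg <- which(isMin & inWin & wave < 0)
  pos <- pos[.peakProminence(wave, pos) > prominence]
  neg <- neg[.peakProminence(-wave, neg) > prominence]
  out <- data.frame(
    latencyMs = time[c(pos, neg)] * 1000,
    polarity = c(rep(1, length(pos)), rep(-1, length(neg))),
    amplitude = wave[c(pos, neg)])
  out[order(out$latencyMs), , drop = FALSE]
}

# topographic prominence of local maxima of w: height above the higher of
# the two minima separating the peak from the nearest taller point (or the
# trace boundary) on each side
.peakProminence <- function(w, peaks) {
  n <- length(w)
  vapply(peaks, function(i) {
    j <- i; lmin <- w[i]
    while (j >= 1 && w[j] <= w[i]) { lmin <- min(lmin, w[j]); j <- j - 1 }
    r <- i; rmin <- w[i]
    while (r <= n && w[r] <= w[i]) { rmin <- min(rmin, w[r]); r <- r + 1 }
    w[i] - max(lmin, rmin)
  }, numeric(1))
}

# cycles(f): linear growth from c0 at the lowest frequency to
# c0 * (fmax/fmin) * (1 - q) at the highest, i.e. the expansion reaches
# (1 - q) of the fully linear (constant time-window) increase.
.erspCycles <- function(freqs, cycles = c(2, 0.1)) {
  c0 <- cycles[1]; q <- cycles[2]
  f0 <- freqs[1]; f1 <- freqs[length(freqs)]
  if (f1 == f0) return(rep(c0, length(freqs)))
  cmax <- c0 * (f1 / f0) * (1 - q)
  c0 + (freqs - f0) / (f1 - f0) * (cmax - c0)
}

#' Single-trial time-frequency decomposition
#'
#' Morlet power of one channel for every trial, with the wavelet cycle
#' count growing linearly across the frequency axis (see the \code{cycles}
#' parameterisation of [ersp()]). The time axis is downsampled to
#' \code{nTimes} points to keep matrices desk-sized.
#'
#' @param ts a [TrialSet-class].
#' @param channel channel name or index.
#' @param freqs frequency axis in Hz (default \code{3:30}).
#' @param cycles \code{c(c0, q)}: \code{c0} cycles at the lowest frequency,
#'   expanding to \code{(1 - q)} of the fully linear increase at the
#'   highest (default \code{c(2, 0.1)}).
#' @param nTimes number of output time points (default 200).
#' @return list with \code{power} (array trials x freqs x times),
#'   \code{freqs}, \code{time}.
#' @export
erspDecompose <- function(ts, channel, freqs = 3:30, cycles = c(2, 0.1),
                          nTimes = 200) {
  stopifnot(is(ts, "TrialSet"), nTrials(ts) >= 1)
  if (is.character(channel)) {
    channel <- match(channel, channelNames(ts))
    if (is.na(channel)) stop("unknown channel name")
  }
  time <- timeAxis(ts)
  ns <- length(time)
  tIdx <- unique(round(seq(1, ns, length.out = min(nTimes, ns))))
  ncyc <- .erspCycles(freqs, cycles)
  bank <- .morletBank(freqs, samplingRate(ts), ns,
                      function(f) ncyc[match(f, freqs)])
  n <- nTrials(ts)
  pow <- array(0, dim = c(n, length(freqs), length(tIdx)))
  for (i in seq_len(n))
    pow[i, , ] <- .morletPower(ts@data[i, channel, ], bank)[, tIdx]
  list(power = pow, freqs = freqs, time = time[tIdx])
}

#' Event-related spectral perturbation
#'
#' Trial-averaged Morlet time-frequency power expressed in dB relative to
#' the mean pre-stimulus baseline power per frequency (divisive baseline,
#' then \code{10 log10}), computed per condition. Stationary signals give
#' 0 dB everywhere; an oscillation whose amplitude is scaled by s after
#' the stimulus shows \code{20 log10(s)} dB, and the measure is invariant
#' to global amplitude scaling.
#'
#' @param ts a [TrialSet-class].
#' @param channel channel name or index.
#' @param by condition column: \code{"label"} (left/right motor imagery)
#'   or \code{"outcome"} (error/correct); \code{NULL} for all trials
#'   pooled.
#' @param freqs frequency axis in Hz (default \code{3:30}).
#' @param cycles wavelet cycle parameterisation (default \code{c(2, 0.1)}).
#' @param baseline pre-stimulus baseline window in seconds
#'   (default \code{c(-0.75, -0.5)}).
#' @param nTimes output time resolution.
#' @return list with per-condition entries, each holding \code{db}
#'   (freqs x times matrix), \code{freqs}, \code{time}, \code{n}.
#' @export
ersp <- function(ts, channel, by = "label", freqs = 3:30,
                 cycles = c(2, 0.1), baseline = c(-0.75, -0.5),
                 nTimes = 200) {
  if (baseline[1] < trialWindow(ts)[1] || baseline[2] > trialWindow(ts)[2])
    stop("baseline window outside the epoch")
  dec <- erspDecompose(ts, channel, freqs, cycles, nTimes)
  bIdx <- which(dec$time >= baseline[1] & dec$time < baseline[2])
  if (length(bIdx) == 0L) stop("baseline window outside the epoch")
  groups <- if (is.null(by)) rep("all", nTrials(ts)) else
    switch(by, label = trialLabels(ts), outcome = trialOutcome(ts),
           stop("'by' must be 'label', 'outcome' or NULL"))
  out <- list()
  for (g in unique(stats::na.omit(groups))) {
    idx <- which(groups == g)
    meanPow <- apply(dec$power[idx, , , drop = FALSE], c(2, 3), mean)
    base <- rowMeans(meanPow[, bIdx, drop = FALSE])
    out[[g]] <- list(db = 10 * log10(sweep(meanPow, 1, base, "/")),
                     freqs = dec$freqs, time = dec$time, n = length(idx),
                     baseline = baseline)
  }
  out
}

#' Permutation test between two ERSP conditions
#'
#' Pointwise comparison of single-trial log power between two conditions:
#' the observed Welch t statistic per (frequency, time) cell is compared
#' with its distribution under \code{nPerm} random relabelings of the
#' trials; p-values are the fraction of permuted \eqn{|t|} at least as
#' large as observed (with the add-one rule), and the Benjamini--Hochberg
#' mask controls the FDR at \code{alpha}.
#'
#' @param dec a decomposition from [erspDecompose()].
#' @param groups per-trial condition labels (two levels).
#' @param nPerm number of permutations (default 800).
#' @param alpha FDR level (default 0.05).
#' @param seed integer seed for the permutations.
#' @return list with \code{t}, \code{p}, \code{pAdj}, \code{mask}
#'   (freqs x times matrices), \code{freqs}, \code{time}.
#' @export
erspPermutationTest <- function(dec, groups, nPerm = 800, alpha = 0.05,
                                seed = 1L) {
  lev <- unique(stats::na.omit(groups))
  stopifnot(length(lev) == 2)
  ia <- which(groups == lev[1]); ib <- which(groups == lev[2])
  stopifnot(length(ia) >= 2, length(ib) >= 2)
  dims <- dim(dec$power)
  flat <- matrix(dec$power, dims[1], dims[2] * dims[3])
  flat <- 10 * log10(pmax(flat, .Machine$double.xmin))  # variance-stabilised
  obs <- .welchT(flat[ia, , drop = FALSE], flat[ib, , drop = FALSE])$t
  set.seed(seed)
  nA <- length(ia)
  all <- c(ia, ib)
  count <- numeric(length(obs))
  for (b in seq_len(nPerm)) {
    perm <- sample(all)
    tb <- .welchT(flat[perm[seq_len(nA)], , drop = FALSE],
                  flat[perm[-seq_len(nA)], , drop = FALSE])$t
    count <- count + (abs(tb) >= abs(obs))
  }
  p <- (count + 1) / (nPerm + 1)
  pAdj <- stats::p.adjust(p, method = "BH")
  shape <- c(dims[2], dims[3])
  list(t = matrix(obs, shape[1], shape[2]),
       p = matrix(p, shape[1], shape[2]),
       pAdj = matrix(pAdj, shape[1], shape[2]),
       mask = matrix(pAdj <= alpha, shape[1], shape[2]),
       freqs = dec$freqs, time = dec$time, nPerm = nPerm, alpha = alpha)
}
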