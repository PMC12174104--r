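#' Motor-imagery feature configuration
#'
#' Parameters of the CWT band-power feature pipeline: per channel and per
#' band (mu and beta), Morlet wavelet power is computed on the post-onset
#' window, resized to a fixed \code{targetShape} by cubic interpolation so
#' both bands are equally represented, and flattened into one context
#' vector (channel-major, band-minor, row-major within each matrix).
#'
#' @param muBand,betaBand frequency bands in Hz (defaults \[6, 13\] and
#'   \[17, 30\]).
#' @param targetShape resize target (frequencies x times), default
#'   \code{c(15, 32)}.
#' @param windowS feature window length in seconds from onset (2 s for the
#'   snake protocol; 0.5 s for short cue-based datasets).
#' @param freqStep pre-resize frequency sampling in Hz (default 1, giving
#'   8 mu and 14 beta rows).
#' @param channels channels to extract (default C3, Cz, C4).
#' @param nCycles function mapping frequency to Morlet cycles
#'   (default \code{max(3, f/2)}).
#' @param standardize \code{"online"} (running per-dimension z-score over
#'   the trial stream, the default: agents see a drifting stream),
#'   \code{"static"} (whole-set z-score) or \code{"none"}.
#' @return an object of class \code{"FeatureConfig"}.
#' @export
featureConfig <- function(muBand = c(6, 13), betaBand = c(17, 30),
                          targetShape = c(15, 32), windowS = 2,
                          freqStep = 1, channels = c("C3", "Cz", "C4"),
                          nCycles = function(f) pmax(3, f / 2),
                          standardize = c("online", "static", "none")) {
  stopifnot(all(targetShape > 0), windowS > 0, freqStep > 0,
            muBand[1] < muBand[2], betaBand[1] < betaBand[2],
            muBand[2] <= betaBand[1] || betaBand[2] <= muBand[1])
  structure(list(muBand = as.numeric(muBand), betaBand = as.numeric(betaBand),
                 targetShape = as.integer(targetShape), windowS = windowS,
                 freqStep = freqStep, channels = channels,
                 nCycles = nCycles, standardize = match.arg(standardize)),
            class = "FeatureConfig")
}

# Morlet wavelet bank for signals of length n: per frequency a complex
# kernel (Gaussian envelope, amplitude-normalised so a unit sinusoid at f
# yields |coefficient| = 1/2) stored as its FFT at padded length (one
# column per frequency), laid out for circular convolution with the kernel
# centre at index 1.
.morletBank <- function(freqs, fs, n, nCycles) {
  ncyc <- vapply(freqs, function(f) nCycles(f), numeric(1))
  half <- pmin(floor(3.5 * ncyc / (2 * pi * freqs) * fs), n - 1L)
  P <- 2^ceiling(log2(n + max(half) * 2 + 1))
  bank <- matrix(0 + 0i, P, length(freqs))
  for (i in seq_along(freqs)) {
    sigma <- ncyc[i] / (2 * pi * freqs[i])
    tt <- seq(-half[i], half[i]) / fs
    g <- exp(-tt^2 / (2 * sigma^2))
    k <- g * exp(1i * 2 * pi * freqs[i] * tt) / sum(g)
    kv <- complex(length.out = P)
    centre <- half[i] + 1L
    kv[1:(half[i] + 1L)] <- k[centre:length(k)]
    if (half[i] > 0) kv[(P - half[i] + 1L):P] <- k[1:half[i]]
    bank[, i] <- stats::fft(kv)
  }
  list(freqs = freqs, fft = bank, P = P, n = n)
}

.morletPower <- function(x, bank) {
  xp <- complex(length.out = bank$P)
  xp[seq_along(x)] <- x
  X <- stats::fft(xp)
  coef <- stats::mvfft(bank$fft * X, inverse = TRUE) / bank$P
  t(Mod(coef[seq_len(bank$n), , drop = FALSE])^2)
}

#' Morlet band power of a single-channel signal
#'
#' Squared magnitude of complex Morlet wavelet coefficients at frequencies
#' sampled every \code{freqStep} Hz across \code{band}. Wavelet support is
#' truncated at 3.5 Gaussian SDs (or the signal length, whichever is
#' shorter); edges are zero-padded, so power near the window boundaries is
#' attenuated rather than wrapped.
#'
#' @param x numeric vector, one channel of one trial.
#' @param band \code{c(low, high)} in Hz, inside (0, fs/2).
#' @param fs sampling rate in Hz.
#' @param freqStep frequency sampling step in Hz.
#' @param nCycles function mapping frequency to cycles.
#' @return non-negative matrix \code{n_freqs x n_times}, with the frequency
#'   axis in \code{rownames}.
#' @examples
#' p <- cwtBandPower(sin(2 * pi * 10 * (0:999) / 500), c(6, 13), fs = 500)
#' rownames(p)[which.max(rowMeans(p))]   # "10"
#' @export
cwtBandPower <- function(x, band, fs, freqStep = 1,
                         nCycles = function(f) pmax(3, f / 2)) {
  stopifnot(band[1] > 0, band[2] < fs / 2, band[1] < band[2])
  nmin <- ceiling(fs / band[1])
  if (length(x) < nmin)
    stop("signal too short for the lowest band frequency: need at least ",
         nmin, " samples (one period of ", band[1], " Hz), got ", length(x))
  freqs <- seq(band[1], band[2], by = freqStep)
  bank <- .morletBank(freqs, fs, length(x), nCycles)
  out <- .morletPower(x, bank)
  rownames(out) <- freqs
  out
}

#' Bicubic resize of a feature matrix
#'
#' Separable cubic-spline interpolation on a uniform grid (rows, then
#' columns) to a fixed target shape. Interpolation reproduces the input
#' exactly when the shape already matches, and reproduces constant and
#' linear ramps exactly; cubic ringing may slightly under/overshoot
#' elsewhere (callers with power semantics clip at 0).
#'
#' @param m numeric matrix with at least 2 rows and 2 columns.
#' @param target \code{c(rows, cols)} output shape (default 15 x 32).
#' @return numeric matrix of dimension \code{target}.
#' @export
resizeBicubic <- function(m, target = c(15, 32)) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("degenerate input: resize needs at least 2 rows and 2 columns")
  # cubic-spline interpolation at a fixed output grid is linear in the
  # data, so each direction is a precomputed (memoised) matrix operator
  step1 <- m %*% .resizeOperator(ncol(m), target[2])
  crossprod(.resizeOperator(nrow(m), target[1]), step1)
}

.errpCache <- new.env(parent = emptyenv())

.resizeOperator <- function(nin, nout) {
  key <- paste0("rs", nin, "x", nout)
  W <- get0(key, envir = .errpCache)
  if (!is.null(W)) return(W)
  xin <- seq(0, 1, length.out = nin)
  xout <- seq(0, 1, length.out = nout)
  W <- matrix(0, nin, nout)
  for (i in seq_len(nin)) {
    y <- numeric(nin); y[i] <- 1
    W[i, ] <- stats::spline(xin, y, xout = xout, method = "fmm")$y
  }
  assign(key, W, envir = .errpCache)
  W
}

.bandList <- function(cfg) list(mu = cfg$muBand, beta = cfg$betaBand)

# core per-trial extraction given prebuilt banks (one per band)
.featureVectorCore <- function(trial, chIdx, banks, cfg, segIdx) {
  blocks <- vector("list", length(chIdx) * length(banks))
  j <- 0L
  for (ci in chIdx) {
    x <- trial[ci, segIdx]
    for (b in seq_along(banks)) {
      p <- .morletPower(x, banks[[b]])
      r <- resizeBicubic(p, cfg$targetShape)
      r[r < 0] <- 0                        # power semantics
      j <- j + 1L
      blocks[[j]] <- as.vector(t(r))       # row-major within matrix
    }
  }
  unlist(blocks, use.names = FALSE)
}

.featureGeometry <- function(ts, cfg) {
  chIdx <- match(cfg$channels, channelNames(ts))
  if (anyNA(chIdx))
    stop("missing channel: ", paste(cfg$channels[is.na(chIdx)], collapse = ", "))
  time <- timeAxis(ts)
  nseg <- as.integer(round(cfg$windowS * samplingRate(ts)))
  first <- which(time >= 0)[1]
  if (is.na(first) || first + nseg - 1L > length(time))
    stop("trial window does not contain the [0, ", cfg$windowS,
         ") s feature window")
  list(chIdx = chIdx, segIdx = seq(first, length.out = nseg))
}

#' Extract the flattened context vector of one trial
#'
#' Runs \code{cwtBandPower -> resizeBicubic -> flatten} for every configured
#' channel and band of one trial and concatenates the blocks
#' (channel-major, band-minor). Deterministic; no standardization is
#' applied at the single-trial level. The feature window is the
#' \code{[0, windowS)} s post-onset segment.
#'
#' @param ts a [TrialSet-class].
#' @param trial trial index.
#' @param cfg a [featureConfig()].
#' @return numeric feature vector of length
#'   \code{n_channels * 2 * prod(targetShape)} (2880 for three channels at
#'   the default 15 x 32 shape).
#' @export
extractFeatureVector <- function(ts, trial, cfg = featureConfig()) {
  geo <- .featureGeometry(ts, cfg)
  fs <- samplingRate(ts)
  banks <- lapply(.bandList(cfg), function(b)
    .morletBank(seq(b[1], b[2], by = cfg$freqStep), fs,
                length(geo$segIdx), cfg$nCycles))
  .featureVectorCore(ts@data[trial, , ], geo$chIdx, banks, cfg, geo$segIdx)
}

#' Extract the feature table of a trial set
#'
#' Row i is the flattened context vector of trial i (see
#' [extractFeatureVector()]), optionally standardized per dimension. The
#' default online mode standardizes row i with running mean/variance
#' estimated from rows 1..i (the agents see a drifting stream and unscaled
#' band power spans orders of magnitude, which cripples UCB exploration
#' terms).
#'
#' @param ts a [TrialSet-class].
#' @param cfg a [featureConfig()].
#' @return an object of class \code{"MIFeatures"}: list with \code{x}
#'   (\code{n_trials x d} matrix), \code{labels}, \code{outcome},
#'   \code{sessionId}, \code{runId} and \code{config}.
#' @export
extractFeatures <- function(ts, cfg = featureConfig()) {
  n <- nTrials(ts)
  if (n == 0L) {
    d <- length(cfg$channels) * 2L * prod(cfg$targetShape)
    return(structure(list(x = matrix(0, 0, d), labels = character(),
                          outcome = character(), sessionId = integer(),
                          runId = integer(), config = cfg),
                     class = "MIFeatures"))
  }
  geo <- .featureGeometry(ts, cfg)
  fs <- samplingRate(ts)
  banks <- lapply(.bandList(cfg), function(b)
    .morletBank(seq(b[1], b[2], by = cfg$freqStep), fs,
                length(geo$segIdx), cfg$nCycles))
  rows <- vector("list", n)
  for (i in seq_len(n))
    rows[[i]] <- .featureVectorCore(ts@data[i, , ], geo$chIdx, banks, cfg,
                                    geo$segIdx)
  x <- do.call(rbind, rows)
  x <- switch(cfg$standardize,
    none = x,
    static = {
      mu <- colMeans(x)
      s <- pmax(apply(x, 2, stats::sd), 1e-8)
      sweep(sweep(x, 2, mu), 2, s, "/")
    },
    online = .onlineStandardize(x)
  )
  structure(list(x = x, labels = trialLabels(ts), outcome = trialOutcome(ts),
                 sessionId = sessionId(ts), runId = runId(ts), config = cfg),
            class = "MIFeatures")
}

# running per-dimension z-score: row i uses mean/variance of rows 1..i
# (Welford updates); variance floored at 1e-16 to keep early rows finite.
.onlineStandardize <- function(x) {
  n <- nrow(x); d <- ncol(x)
  out <- matrix(0, n, d)
  mu <- numeric(d); m2 <- numeric(d)
  for (i in seq_len(n)) {
    delta <- x[i, ] - mu
    mu <- mu + delta / i
    m2 <- m2 + delta * (x[i, ] - mu)
    s <- if (i > 1) sqrt(pmax(m2 / (i - 1), 1e-16)) else rep(1, d)
    out[i, ] <- (x[i, ] - mu) / s
  }
  out
}

#' @export
print.MIFeatures <- function(x, ...) {
  cat(sprintf("MIFeatures: %d trials x %d dims (%s standardization)\n",
              nrow(x$x), ncol(x$x), x$config$standardize))
  invisible(x)
}
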