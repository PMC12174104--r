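# Independent oracles and small fixture builders shared across tests.

# Brute-force Wilcoxon signed-rank p-value: enumerate all 2^n sign patterns
# of the observed midranks (zeros dropped first).
bruteWilcoxon <- function(x, y = rep(0, length(x)),
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(bits) {
    signs <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  pG <- mean(ws >= w - 1e-12)
  pL <- mean(ws <= w + 1e-12)
  switch(alternative,
         greater = pG, less = pL,
         two.sided = min(1, 2 * min(pG, pL)))
}

# Brute-force Benjamini-Hochberg step-up: largest k with p_(k) <= k/m*alpha.
bruteBH <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) / m * alpha)))
  mask <- rep(FALSE, m)
  if (is.finite(k)) mask[o[seq_len(k)]] <- TRUE
  mask
}

# Direct ridge solve of the LinUCB score (the contract the agent must meet).
ridgeOracleScores <- function(state, x, alpha) {
  vapply(seq_along(state$A), function(a) {
    Ai <- solve(state$A[[a]])
    th <- drop(Ai %*% state$b[[a]])
    sum(th * x) + alpha * sqrt(drop(t(x) %*% Ai %*% x))
  }, numeric(1))
}

# Naive time-domain Morlet power: same kernel definition as the package,
# evaluated by direct convolution with explicit zero padding.
naiveMorletPower <- function(x, freqs, fs, nCycles = function(f) pmax(3, f / 2)) {
  n <- length(x)
  out <- matrix(0, length(freqs), n)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    nc <- nCycles(f)
    sigma <- nc / (2 * pi * f)
    half <- min(floor(3.5 * sigma * fs), n - 1L)
    tt <- seq(-half, half) / fs
    g <- exp(-tt^2 / (2 * sigma^2))
    k <- g * exp(1i * 2 * pi * f * tt) / sum(g)
    for (t0 in seq_len(n)) {
      idx <- t0 + seq(-half, half)
      ok <- idx >= 1 & idx <= n
      out[fi, t0] <- Mod(sum(Conj(k[ok]) * x[idx[ok]]))^2
    }
  }
  out
}

# Recording with a deterministic ramp signal and a configurable event table.
makeRecording <- function(nCh = 2, nSamp = 5000, fs = 500,
                          events = data.frame(sample = c(1000, 2000, 3000),
                                              code = c("left", "right", "left"))) {
  sig <- matrix(seq_len(nCh * nSamp) / 1000, nCh, nSamp)
  EEGRecording(sig, fs = fs, channelNames = paste0("ch", seq_len(nCh)),
               events = events)
}

# Tiny trial set with known content.
makeTrialSet <- function(n = 4, nCh = 2, fs = 100, window = c(-0.5, 0.5),
                         labels = rep(c("left", "right"), length.out = n),
                         outcome = rep("correct", n)) {
  ns <- round(diff(window) * fs)
  dat <- array(rnorm(n * nCh * ns), c(n, nCh, ns))
  TrialSet(dat, fs = fs, window = window,
           channelNames = paste0("ch", seq_len(nCh)),
           labels = labels, outcome = outcome)
}

# Variance of a signal segment relative to the alignment event.
segmentVar <- function(x, time, from, to) stats::var(x[time >= from & time < to])
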