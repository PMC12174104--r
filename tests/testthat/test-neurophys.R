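test_that("ERP averaging removes the baseline and respects conditions", {
  ts <- makeTrialSet(n = 3, nCh = 2, fs = 100, window = c(-0.5, 0.5),
                     outcome = c("error", "correct", "correct"))
  avg <- erpAverage(ts, "error", baseline = c(-0.2, 0))
  time <- timeAxis(ts)
  bIdx <- time >= -0.2 & time < 0
  single <- sweep(ts@data[1, , ], 1, rowMeans(ts@data[1, , bIdx]))
  # single trial: that trial, baseline-corrected
  expect_equal(avg$mean, single, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(rowMeans(avg$mean[, bIdx])), c(0, 0), tolerance = 1e-12)

  # constant-offset trials vanish after correction
  tsC <- makeTrialSet(n = 4, nCh = 1, fs = 100)
  tsC@data[] <- 7.5
  expect_equal(max(abs(erpAverage(tsC, NULL)$mean)), 0)

  expect_error(erpAverage(ts, "missing-condition"), "no trials")
})

test_that("difference waves subtract pointwise and check axes", {
  ts <- makeTrialSet(n = 6, nCh = 1, fs = 100,
                     outcome = rep(c("error", "correct"), 3))
  e <- erpAverage(ts, "error"); c <- erpAverage(ts, "correct")
  dw <- differenceWave(e, c)
  expect_equal(dw$wave, e$mean - c$mean)
  expect_equal(differenceWave(c, e)$wave, -dw$wave)      # antisymmetric
  expect_equal(max(abs(differenceWave(e, e)$wave)), 0)
  c$time <- c$time + 0.01
  expect_error(differenceWave(e, c), "time axes")
})

test_that("noiseless synthetic error trials reconstruct the template", {
  fs <- 500; ns <- 1500
  tpl <- errpTemplate(channels = "Cz")
  time <- -1 + (0:(ns - 1)) / fs
  dat <- array(0, c(4, 1, ns))
  for (i in 1:2) dat[i, 1, ] <- errpWaveform(tpl, time) + 3  # offset too
  dat[3:4, 1, ] <- 3
  ts <- TrialSet(dat, fs = fs, window = c(-1, 2), channelNames = "Cz",
                 outcome = c("error", "error", "correct", "correct"))
  dw <- differenceWave(erpAverage(ts, "error"), erpAverage(ts, "correct"))
  # template has negligible mass in the baseline window, so recovery is
  # essentially exact
  expect_equal(dw$wave[1, ], errpWaveform(tpl, time), tolerance = 1e-6)
  pk <- findPeaks(dw$wave[1, ], dw$time, prominence = 1)
  expect_equal(pk$polarity, c(1, -1, 1))
  expect_equal(pk$latencyMs, c(196, 256, 348), tolerance = 1)
})

test_that("peak finding matches an exhaustive local-extremum scan", {
  expect_equal(nrow(findPeaks(rep(0, 100), seq(-0.2, 0.59, length.out = 100))),
               0)
  # well-separated bumps: topographic prominence and a plain amplitude
  # scan agree, so an exhaustive local-extremum scan is a fair oracle
  time <- seq(-0.2, 0.795, by = 0.005)
  wave <- 3 * exp(-(time - 0.10)^2 / (2 * 0.02^2)) -
    2 * exp(-(time - 0.25)^2 / (2 * 0.02^2)) +
    4 * exp(-(time - 0.40)^2 / (2 * 0.02^2)) -
    0.2 * exp(-(time - 0.55)^2 / (2 * 0.02^2))   # sub-threshold bump
  pk <- findPeaks(wave, time, searchWindow = c(0, 0.6), prominence = 0.5)
  lat <- c()
  for (i in 2:(length(wave) - 1)) {
    if (time[i] < 0 || time[i] > 0.6) next
    if (wave[i] > wave[i - 1] && wave[i] >= wave[i + 1] && wave[i] > 0.5)
      lat <- c(lat, time[i] * 1000)
    if (wave[i] < wave[i - 1] && wave[i] <= wave[i + 1] && wave[i] < -0.5)
      lat <- c(lat, time[i] * 1000)
  }
  expect_equal(sort(pk$latencyMs), sort(lat), tolerance = 1e-9)
  expect_equal(pk$polarity, c(1, -1, 1))

  # micro-extrema on a broad noisy hump are not reported as components
  set.seed(95)
  hump <- 5 * exp(-(time - 0.3)^2 / (2 * 0.05^2)) + rnorm(length(time), 0, 0.05)
  pkH <- findPeaks(hump, time)
  expect_equal(nrow(pkH), 1)
  expect_lt(abs(pkH$latencyMs - 300), 15)
})

test_that("pointwise FDR controls the null and detects planted effects", {
  set.seed(96)
  # planted difference at known samples is recovered
  err <- matrix(rnorm(200 * 60), 200, 60)
  cor <- matrix(rnorm(200 * 60), 200, 60)
  err[, 25:35] <- err[, 25:35] + 1.5
  res <- pointwiseFDR(err, cor, alpha = 0.05)
  expect_true(all(res$mask[25:35]))
  expect_lt(mean(res$mask[-(25:35)]), 0.2)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # mask only ever rejects adjusted p <= alpha
  expect_true(all(res$pAdj[res$mask] <= 0.05))
})

test_that("ERSP is near zero for stationary signals and tracks amplitude", {
  fs <- 250; ns <- 500
  set.seed(97)
  dat <- array(rnorm(100 * 1 * ns), c(100, 1, ns))
  ts <- TrialSet(dat, fs = fs, window = c(-1, 1), channelNames = "Cz")
  e <- ersp(ts, "Cz", by = NULL, freqs = seq(4, 30, 2),
            baseline = c(-0.75, -0.5), nTimes = 80)
  expect_lt(abs(mean(e$all$db)), 0.5)

  # amplitude halved post-stimulus: -6.02 dB in that band
  time <- -1 + (0:(ns - 1)) / fs
  dat2 <- array(0, c(40, 1, ns))
  set.seed(98)
  for (i in 1:40) {
    amp <- ifelse(time < 0, 1, 0.5)
    dat2[i, 1, ] <- amp * sin(2 * pi * 10 * time + runif(1, 0, 2 * pi))
  }
  ts2 <- TrialSet(dat2, fs = fs, window = c(-1, 1), channelNames = "Cz")
  e2 <- ersp(ts2, "Cz", by = NULL, freqs = seq(4, 30, 2),
             baseline = c(-0.75, -0.5), nTimes = 80)
  post <- e2$all$time > 0.3 & e2$all$time < 0.9   # clear of the transition
  expect_equal(mean(e2$all$db[4, post]), 10 * log10(0.25), tolerance = 0.35)

  # exact invariance to global amplitude scaling
  ts3 <- ts2; ts3@data <- ts3@data * 7
  e3 <- ersp(ts3, "Cz", by = NULL, freqs = seq(4, 30, 2),
             baseline = c(-0.75, -0.5), nTimes = 80)
  expect_equal(e3$all$db, e2$all$db, tolerance = 1e-9)

  expect_error(ersp(ts2, "Cz", baseline = c(-2, -1.5)), "baseline")
})

test_that("right-hand MI shows contralateral mu-band ERD in ERSP", {
  set.seed(99)
  proto <- snakeProtocolConfig(trialsPerRun = 40)
  sim <- simulateSnakeProtocol(proto, miSignalConfig(erdDepth = 0.8),
                               seed = 99)
  e <- ersp(sim$trials, "C3", by = "label", freqs = seq(4, 30, 2),
            nTimes = 80)
  muRows <- which(e$right$freqs >= 8 & e$right$freqs <= 12)
  post <- e$right$time > 0.2
  erdRight <- mean(e$right$db[muRows, post])
  erdLeft <- mean(e$left$db[muRows, post])
  expect_lt(erdRight, -6)          # strong desynchronization at C3 (contra)
  expect_gt(erdLeft, erdRight + 3) # ipsilateral far weaker
})

test_that("ERSP permutation testing flags the separable band and not null data", {
  set.seed(100)
  sim <- simulateSnakeProtocol(snakeProtocolConfig(trialsPerRun = 40),
                               miSignalConfig(erdDepth = 0.8), seed = 101)
  dec <- erspDecompose(sim$trials, "C3", freqs = seq(4, 30, 2), nTimes = 60)
  res <- erspPermutationTest(dec, trialLabels(sim$trials), nPerm = 300,
                             seed = 1)
  muRows <- which(dec$freqs >= 8 & dec$freqs <= 12)
  post <- dec$time > 0.2
  expect_gt(mean(res$mask[muRows, post]), 0.5)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$pAdj[res$mask] <= res$alpha))
})
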