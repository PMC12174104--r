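test_that("containers validate their invariants", {
  expect_error(EEGRecording(matrix(0, 2, 10), fs = -1), "positive")
  expect_error(EEGRecording(matrix(0, 2, 10), fs = 10,
                            channelNames = c("a", "a")), "unique")
  expect_error(EEGRecording(matrix(0, 1, 10), fs = 10, channelNames = "a",
                            events = data.frame(sample = 11, code = "left")),
               "within the recording")
  # sample-count convention: (-1, 2) s at 500 Hz is exactly 1500 samples
  expect_error(TrialSet(array(0, c(1, 1, 1499)), fs = 500, window = c(-1, 2)),
               "half-open")
  ts <- TrialSet(array(0, c(1, 1, 1500)), fs = 500, window = c(-1, 2))
  expect_s4_class(ts, "TrialSet")
  expect_error(TrialSet(array(0, c(1, 1, 500)), fs = 500, window = c(1, 2)),
               "alignment")
  expect_error(TrialSet(array(0, c(2, 1, 10)), fs = 10, window = c(0, 1),
                        labels = "left"), "length n_trials")
})

test_that("accessors and subsetting are consistent", {
  ts <- makeTrialSet(n = 6)
  expect_equal(nTrials(ts), 6)
  expect_equal(nChannels(ts), 2)
  expect_equal(length(timeAxis(ts)), dim(trialData(ts))[3])
  expect_equal(timeAxis(ts)[1], trialWindow(ts)[1])
  sub <- ts[c(2, 5)]
  expect_equal(nTrials(sub), 2)
  expect_equal(trialLabels(sub), trialLabels(ts)[c(2, 5)])
  expect_equal(trialData(sub, trial = 1, channel = "ch1"),
               trialData(ts, trial = 2, channel = "ch1"))
})

test_that("filtering rejects DC, notches mains and preserves the passband", {
  fs <- 500
  n <- 5000
  t <- (0:(n - 1)) / fs
  spec <- filterSpec(band = c(0.5, 100), notch = 50)

  dc <- EEGRecording(matrix(1, 1, n), fs = fs)
  out <- filterContinuous(dc, spec)
  expect_lt(max(abs(out@signal)), 0.01)

  mains <- EEGRecording(matrix(sin(2 * pi * 50 * t), 1, n), fs = fs)
  out <- filterContinuous(mains, spec)
  core <- 1000:4000                     # away from edges
  inRMS <- sqrt(mean(mains@signal[1, core]^2))
  expect_lt(sqrt(mean(out@signal[1, core]^2)) / inRMS, 0.05)

  # 10 Hz passband gain vs the analytically computed frequency response of
  # the three designed kernels
  tone <- EEGRecording(matrix(sin(2 * pi * 10 * t), 1, n), fs = fs)
  out <- filterContinuous(tone, spec)
  gain <- sd(out@signal[1, core]) / sd(tone@signal[1, core])
  ker <- errpBandit:::.firKernels(spec, fs)
  hGain <- prod(vapply(ker, function(h)
    Mod(sum(h * exp(-1i * 2 * pi * 10 / fs * (seq_along(h) - 1)))),
    numeric(1)))
  expect_equal(gain, hGain, tolerance = 1e-3)
  expect_gt(gain, 0.95)
  expect_lt(gain, 1.05)
})

test_that("filtering is linear and respects Nyquist", {
  fs <- 250
  x <- rnorm(2000)
  rec1 <- EEGRecording(matrix(x, 1, 2000), fs = fs)
  rec3 <- EEGRecording(matrix(3 * x, 1, 2000), fs = fs)
  spec <- filterSpec(band = c(0.5, 40), notch = 50)
  f1 <- filterContinuous(rec1, spec)@signal
  f3 <- filterContinuous(rec3, spec)@signal
  expect_lt(max(abs(f3 - 3 * f1)) / max(abs(f1)), 1e-9)
  expect_error(filterContinuous(rec1, filterSpec(band = c(0.5, 130))),
               "Nyquist")
})

test_that("epoching follows the half-open convention and skips autos/edges", {
  fs <- 500
  rec <- makeRecording(nCh = 2, nSamp = 5000, fs = fs,
                       events = data.frame(
                         sample = c(1000, 2000, 3000, 4900, 100),
                         code = c("left", "auto_forward", "right",
                                  "left", "right")))
  expect_warning(ts <- epochTrials(rec, window = c(-1, 2)), "skipped")
  # auto_forward excluded, two edge events skipped
  expect_equal(nTrials(ts), 2)
  expect_equal(dim(trialData(ts))[3], 1500)
  expect_equal(trialLabels(ts), c("left", "right"))
  # alignment: trial sample 1 is recording sample k + s*fs
  k <- 1000
  expect_equal(trialData(ts, trial = 1, channel = 1)[1],
               unname(rec@signal[1, k + round(-1 * fs)]))
  expect_equal(trialData(ts, trial = 1, channel = 1)[1500],
               unname(rec@signal[1, k + round(-1 * fs) + 1499]))

  onlyAuto <- makeRecording(events = data.frame(sample = 2000,
                                                code = "auto_forward"))
  expect_equal(nTrials(epochTrials(onlyAuto, window = c(-1, 2))), 0)
})

test_that("artifact rejection matches a brute-force scan and is idempotent", {
  set.seed(11)
  ts <- makeTrialSet(n = 20, nCh = 3, fs = 100)
  ts@data[7, 2, 30] <- 500          # inject a spike
  kept <- rejectArtifacts(ts, ampUV = 100)
  expect_false(7 %in% setdiff(seq_len(20), kept@metadata$rejectionLog$trial))
  expect_equal(kept@metadata$rejectionLog$channel, "ch2")

  # oracle: exhaustive per-trial max scan
  thr <- 2.5
  keptThr <- rejectArtifacts(ts, ampUV = thr)
  surv <- sum(vapply(seq_len(20), function(i)
    max(abs(ts@data[i, , ])) <= thr, logical(1)))
  expect_equal(nTrials(keptThr), surv)

  expect_equal(nTrials(rejectArtifacts(ts, ampUV = 1e9)), 20)
  twice <- rejectArtifacts(keptThr, ampUV = thr)
  expect_equal(trialData(twice), trialData(keptThr))
})

test_that("trial archives round trip losslessly", {
  ts <- makeTrialSet(n = 5, labels = c("right", "left", "left", "right", "left"))
  f <- tempfile(fileext = ".rds")
  saveTrialSet(ts, f)
  back <- loadTrialSet(f)
  expect_equal(trialData(back), trialData(ts), tolerance = 1e-12)
  expect_identical(trialLabels(back), trialLabels(ts))
  expect_identical(trialOutcome(back), trialOutcome(ts))
  expect_equal(trialWindow(back), trialWindow(ts))

  empty <- makeTrialSet(n = 4)[integer(0)]
  saveTrialSet(empty, f)
  expect_equal(nTrials(loadTrialSet(f)), 0)

  # malformed archive names the missing field
  bad <- readRDS(f)
  bad$labels <- NULL
  saveRDS(bad, f)
  expect_error(loadTrialSet(f), "missing field 'labels'")
  saveRDS(list(a = 1), f)
  expect_error(loadTrialSet(f), "malformed|format")
})

test_that("epoch - save - load - epoch identity holds", {
  rec <- makeRecording(nCh = 2, nSamp = 4000, fs = 500,
                       events = data.frame(sample = c(1000, 2500),
                                           code = c("left", "right")))
  ts <- epochTrials(rec, window = c(-0.5, 1))
  f <- tempfile(fileext = ".rds")
  saveTrialSet(ts, f)
  expect_equal(trialData(loadTrialSet(f)), trialData(ts), tolerance = 1e-12)
})
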