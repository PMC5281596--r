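test_that("band-pass filter preserves the passband and rejects DC and 60 Hz", {
  fs <- 1000
  t <- seq(0, 60, by = 1 / fs)
  mid <- 20000:40000 # away from edges
  rms <- function(x) sqrt(mean(x^2))

  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(x10, filter_spec(), rate = fs)
  expect_lt(abs(rms(y10[mid]) / rms(x10[mid]) - 1), 0.05)

  dc <- rep(13, length(t))
  ydc <- bandpass_filter(dc, filter_spec(), rate = fs)
  expect_lt(max(abs(ydc[mid])), 0.05)

  x60 <- sin(2 * pi * 60 * t)
  y60 <- bandpass_filter(x60, filter_spec(), rate = fs)
  expect_lt(rms(y60[mid]) / rms(x60[mid]), 0.10)
})

test_that("filtering is linear and zero-phase", {
  set.seed(21)
  fs <- 1000
  x <- rnorm(20000)
  y <- rnorm(20000)
  f <- function(v) bandpass_filter(v, filter_spec(), rate = fs)
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-9)

  # zero-phase: a 10 Hz sine keeps its phase (cross-correlation peak at lag 0)
  s <- sin(2 * pi * 10 * seq(0, 20, by = 1 / fs))
  fsig <- f(s)
  cc <- stats::ccf(fsig[5000:15000], s[5000:15000], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter application agrees with signal::filtfilt", {
  set.seed(22)
  x <- rnorm(5000)
  hp <- signal::butter(4, 0.02, type = "high")
  ours <- vmmn:::iir_filtfilt_mat(hp$b, hp$a, matrix(x, ncol = 1))[, 1]
  ref <- signal::filtfilt(hp, x)
  expect_lt(max(abs(ours[500:4500] - ref[500:4500])), 1e-5)
})

test_that("invalid filter parameters are rejected", {
  expect_error(filter_spec(low_cutoff = 30, high_cutoff = 0.1), "low_cutoff")
  expect_error(filter_spec(rolloff = 20), "multiple of 6")
  expect_error(bandpass_filter(rnorm(100), filter_spec(high_cutoff = 600),
                               rate = 1000), "Nyquist")
})

test_that("segmentation yields 701-sample epochs with both time axes", {
  sch <- generate_schedule(tiny_session(), 50, "pseudo-letter", seed = 1)
  rec <- generate_recording(sch, group_profile("older"), seed = 1,
                            channels = roi_channels())
  eps <- segment_epochs(rec)
  expect_equal(dim(eps$data)[1], 701)
  expect_equal(dim(eps$data)[3], nrow(sch$events))
  expect_equal(range(eps$times_acq), c(-100, 600))
  expect_equal(range(eps$times_ana), c(-150, 550)) # shifted by the 50 ms SOA
  expect_equal(eps$times_ana, eps$times_acq - 50)
  # condition labels copied from the schedule
  expect_identical(eps$info$role, sch$events$role)
  expect_identical(eps$info$category, sch$events$category)
})

test_that("baseline correction removes constant offsets and is idempotent", {
  sch <- generate_schedule(tiny_session(), 0, "letter", seed = 2)
  prof <- group_profile("young", noise_amplitude = 0)
  prof$components <- list()
  rec <- generate_recording(sch, prof, channels = c("PO7", "PO8"))
  rec$data[, "PO7"] <- rec$data[, "PO7"] + 13 # constant offset channel
  eps <- segment_epochs(rec)
  expect_equal(max(abs(eps$data[, "PO7", ])), 0, tolerance = 1e-12)

  # per-channel baseline means are zero, so re-correcting changes nothing
  sch2 <- generate_schedule(tiny_session(), 0, "letter", seed = 3)
  rec2 <- generate_recording(sch2, group_profile("young"), seed = 4,
                             channels = c("PO7", "PO8"))
  eps2 <- segment_epochs(rec2)
  bl <- eps2$times_acq >= -100 & eps2$times_acq <= 0
  for (e in 1:3) {
    means <- colMeans(eps2$data[bl, , e])
    expect_equal(max(abs(means)), 0, tolerance = 1e-9)
  }
})

test_that("epochs that do not fit the recording are flagged out-of-bounds", {
  sch <- generate_schedule(tiny_session(), 0, "letter", seed = 5)
  rec <- generate_recording(sch, group_profile("young"), seed = 5,
                            channels = "PO8")
  # truncate the recording so the last epochs cannot fit
  cut_ms <- sch$events$onset_fragment1[18]
  rec$data <- rec$data[seq_len(round(cut_ms)), , drop = FALSE]
  eps <- segment_epochs(rec)
  expect_true(all(eps$info$rejected[18:20]))
  expect_true(all(eps$info$reason[18:20] == "out-of-bounds"))
  expect_true(all(!eps$info$rejected[1:16]))
})

test_that("artifact rejection boundary sits exactly at the threshold", {
  # sweep of single-spike epochs, peak 90..110 uV in 1 uV steps
  rejected <- vapply(90:110, function(a) {
    arr <- array(0, dim = c(701, 2, 1))
    arr[350, 1, 1] <- a
    eps <- make_epochs(arr)
    reject_artifacts(eps, threshold = 100)$info$rejected[1]
  }, logical(1))
  expect_identical(rejected, 90:110 > 100)
})

test_that("spike epochs are rejected and clean epochs retained", {
  arr <- array(0, dim = c(701, 2, 3))
  arr[100, 2, 1] <- 150    # absolute excursion
  arr[, 1, 3] <- sin(seq(0, 10, length.out = 701)) # small, retained
  eps <- reject_artifacts(make_epochs(arr), threshold = 100)
  expect_identical(eps$info$rejected, c(TRUE, FALSE, FALSE))
  expect_identical(eps$info$reason[1], "amplitude")
  expect_equal(eps$counts$retained, 2L)
})

test_that("raising the rejection threshold never rejects a retained epoch", {
  set.seed(31)
  arr <- array(rnorm(701 * 2 * 30, sd = 30), dim = c(701, 2, 30))
  rejected_at <- function(thr) reject_artifacts(make_epochs(arr), thr)$info$rejected
  r80 <- rejected_at(80)
  r100 <- rejected_at(100)
  r150 <- rejected_at(150)
  expect_true(any(r80) && !all(r150)) # the sweep actually spans the boundary
  expect_true(all(which(r100) %in% which(r80)))
  expect_true(all(which(r150) %in% which(r100)))
})

test_that("segment-then-average recovers injected waveforms exactly (noiseless)", {
  cfg <- tiny_session()
  sch <- generate_schedule(cfg, 50, "pseudo-letter", seed = 6)
  prof <- group_profile("older", noise_amplitude = 0)
  rec <- generate_recording(sch, prof, channels = roi_channels())
  eps <- reject_artifacts(segment_epochs(rec))
  dev <- average_epochs(eps, "deviant", "pseudo-letter")
  # expected deviant epoch at PO8: P1 + N1 (fragment-1 locked, both
  # fragments' components modelled at fragment 1) + vMMN at soa+248
  t_acq <- dev$times_acq
  topo <- posterior_topography()
  expected <- 2.5 * topo[["PO8"]] * exp(-((t_acq - 110)^2) / (2 * 15^2)) -
    4 * topo[["PO8"]] * exp(-((t_acq - 178)^2) / (2 * 25^2)) -
    1 * topo[["PO8"]] * exp(-((t_acq - (50 + 248))^2) / (2 * 20^2))
  expected <- expected - mean(expected[t_acq >= -100 & t_acq <= 0])
  expect_equal(dev$data[, "PO8"], expected, tolerance = 0.02,
               ignore_attr = TRUE)
})
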