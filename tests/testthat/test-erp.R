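test_that("averaging identical epochs reproduces the epoch", {
  one <- matrix(rnorm(701 * 2), 701, 2, dimnames = list(NULL, c("PO7", "PO8")))
  arr <- array(rep(one, 10), dim = c(701, 2, 10),
               dimnames = list(NULL, c("PO7", "PO8")))
  avg <- average_epochs(make_epochs(arr), "deviant")
  expect_equal(avg$data, one, ignore_attr = TRUE)
  expect_equal(avg$n_epochs, 10)
})

test_that("averaging converges on the injected waveform under noise", {
  set.seed(41)
  wave <- 2 * exp(-((seq(-100, 600) - 245)^2) / (2 * 20^2))
  sigma <- 5
  n <- 400
  arr <- array(wave + rnorm(701 * n, sd = sigma), dim = c(701, 1, n),
               dimnames = list(NULL, "PO8", NULL))
  avg <- average_epochs(make_epochs(arr), "deviant")
  expect_true(all(abs(avg$data[, 1] - wave) < 4 * sigma / sqrt(n)))
})

test_that("both variants of a role are pooled unless requested otherwise", {
  arr <- array(0, dim = c(10, 1, 4), dimnames = list(NULL, "PO8", NULL))
  arr[, , 1] <- 1; arr[, , 2] <- 1 # variant 1
  arr[, , 3] <- 3; arr[, , 4] <- 3 # variant 2
  eps <- make_epochs(arr)
  eps$info$variant <- c(1L, 1L, 2L, 2L)
  pooled <- average_epochs(eps, "deviant")
  expect_equal(unique(as.numeric(pooled$data)), 2)
  expect_equal(pooled$n_epochs, 4)
  v2 <- average_epochs(eps, "deviant", variant = 2)
  expect_equal(unique(as.numeric(v2$data)), 3)
})

test_that("rejected epochs never enter an average and empty conditions error", {
  arr <- array(1, dim = c(10, 1, 3), dimnames = list(NULL, "PO8", NULL))
  eps <- make_epochs(arr)
  eps$info$rejected[3] <- TRUE
  expect_equal(average_epochs(eps, "deviant")$n_epochs, 2)
  expect_error(average_epochs(eps, "standard"), "no retained epochs")
})

test_that("opposite-condition subtraction is exact and antisymmetric", {
  arr <- array(rnorm(701 * 2 * 4), dim = c(701, 2, 4),
               dimnames = list(NULL, c("PO7", "PO8"), NULL))
  dev <- average_epochs(make_epochs(arr), "deviant", "pseudo-letter")
  std <- average_epochs(
    make_epochs(array(rnorm(701 * 2 * 4), dim = c(701, 2, 4),
                      dimnames = list(NULL, c("PO7", "PO8"), NULL)),
                role = "standard"), "standard", "pseudo-letter")
  dw <- difference_wave(dev, std)
  expect_equal(dw$data, dev$data - std$data)

  # identical inputs -> all-zero wave
  std_same <- std; std_same$data <- dev$data
  expect_equal(max(abs(difference_wave(dev, std_same)$data)), 0)

  # swapping minuend/subtrahend negates (construct the mirrored pair)
  dev2 <- dev; dev2$condition$role <- "standard"
  std2 <- std; std2$condition$role <- "deviant"
  expect_equal(difference_wave(std2, dev2)$data, -dw$data)
})

test_that("difference wave refuses mismatched category or SOA", {
  arr <- array(0, dim = c(10, 1, 2), dimnames = list(NULL, "PO8", NULL))
  dev <- average_epochs(make_epochs(arr, category = "letter"), "deviant")
  std_wrong_cat <- average_epochs(
    make_epochs(arr, role = "standard", category = "pseudo-letter"), "standard")
  expect_error(difference_wave(dev, std_wrong_cat), "pairing error")
  std_wrong_soa <- average_epochs(
    make_epochs(arr, role = "standard", category = "letter", soa = 50), "standard")
  expect_error(difference_wave(dev, std_wrong_soa), "pairing error")
  expect_error(difference_wave(dev, dev), "different roles")
})

test_that("difference of standard plus known Gaussian recovers it exactly", {
  gauss <- -1.0 * exp(-((seq(-100, 600) - 245)^2) / (2 * 20^2))
  base <- matrix(rnorm(701), 701, 1, dimnames = list(NULL, "PO8"))
  std <- average_epochs(
    make_epochs(array(base, c(701, 1, 1), dimnames = list(NULL, "PO8", NULL)),
                role = "standard"), "standard")
  dev <- average_epochs(
    make_epochs(array(base + gauss, c(701, 1, 1),
                      dimnames = list(NULL, "PO8", NULL))), "deviant")
  dw <- difference_wave(dev, std)
  expect_equal(dw$data[, 1], gauss, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("ROI pooling is the unweighted channel mean", {
  arr <- array(rnorm(50 * 4), dim = c(50, 4, 1),
               dimnames = list(NULL, c("PO7", "PO9", "PO8", "PO10"), NULL))
  erp <- average_epochs(make_epochs(arr, times = seq(0, 49)), "deviant")
  right <- roi_pool(erp, default_rois()$right)
  expect_equal(right$value, (arr[, "PO8", 1] + arr[, "PO10", 1]) / 2)

  single <- roi_pool(erp, roi_def("one", "PO7"))
  expect_equal(single$value, arr[, "PO7", 1])

  opp <- erp
  opp$data[, "PO8"] <- 2
  opp$data[, "PO10"] <- -2
  expect_equal(max(abs(roi_pool(opp, default_rois()$right)$value)), 0)

  expect_error(roi_pool(erp, roi_def("bad", c("PO8", "Cz"))), "not present")
})

test_that("averaging commutes with ROI pooling", {
  set.seed(42)
  arr <- array(rnorm(100 * 2 * 8), dim = c(100, 2, 8),
               dimnames = list(NULL, c("PO8", "PO10"), NULL))
  eps <- make_epochs(arr, times = seq(0, 99))
  pooled_then_avg <- rowMeans(vapply(1:8, function(e) {
    rowMeans(arr[, , e])
  }, numeric(100)))
  avg_then_pooled <- roi_pool(average_epochs(eps, "deviant"),
                              default_rois()$right)$value
  expect_equal(avg_then_pooled, pooled_then_avg, tolerance = 1e-12)
})

test_that("peak measurement finds extremum, breaks ties early, and shifts", {
  time <- seq(-100, 600)
  gauss <- -2 * exp(-((time - 245)^2) / (2 * 20^2))
  pk <- measure_peak(make_series(gauss, time), c(150, 300), "negative",
                     "subject-peak")
  expect_equal(pk$latency, 245)
  expect_equal(pk$amplitude, -2)

  # flat series: tie-break to the window start
  flat <- measure_peak(make_series(rep(-1, length(time)), time),
                       c(150, 300), "negative", "subject-peak")
  expect_equal(flat$latency, 150)
  expect_equal(flat$amplitude, -1)

  # shift-equivariance: translating the series shifts the latency
  for (delta in c(-20, 15)) {
    shifted <- -2 * exp(-((time - (245 + delta))^2) / (2 * 20^2))
    expect_equal(
      measure_peak(make_series(shifted, time), c(150, 300), "negative",
                   "subject-peak")$latency,
      245 + delta
    )
  }

  # positive polarity
  pos <- measure_peak(make_series(-gauss, time), c(150, 300), "positive",
                      "subject-peak")
  expect_equal(pos$latency, 245)
  expect_equal(pos$amplitude, 2)

  expect_error(
    measure_peak(make_series(gauss, time), c(150, 700), "negative",
                 "subject-peak"),
    "outside the series span"
  )
})

test_that("group-peak-centered amplitude equals the 20 ms window mean", {
  time <- seq(-100, 600)
  set.seed(43)
  v <- rnorm(length(time))
  s <- make_series(v, time)
  m <- measure_peak(s, c(150, 300), "negative", "group-peak-centered-mean",
                    group_peak_latency = 250)
  expect_equal(m$amplitude, mean(v[time >= 240 & time <= 260]))
  expect_false(m$clipped)

  # clipping at the search-window edge is flagged
  m2 <- measure_peak(s, c(150, 300), "negative", "group-peak-centered-mean",
                     group_peak_latency = 295)
  expect_true(m2$clipped)
  expect_equal(m2$amplitude, mean(v[time >= 285 & time <= 300]))

  expect_error(
    measure_peak(s, c(150, 300), "negative", "group-peak-centered-mean"),
    "group_peak_latency"
  )
})
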