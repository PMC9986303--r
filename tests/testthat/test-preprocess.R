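test_that("spline fill is exact on a linear trajectory", {
  tr <- linear_traj(n = 50)
  truth <- tr$positions
  tr$positions[20:22, ] <- NA
  tr$occluded[20:22] <- TRUE
  out <- fill_gaps(tr, "spline")
  expect_false(any(out$occluded))
  expect_lt(max(abs(out$positions - truth)), 1e-6)
})

test_that("cyclic fill reconstructs a sinusoid from flanking cycles", {
  fs <- 200
  t <- (0:(4 * fs - 1)) / fs                 # 4 s of a 2 Hz sinusoid
  pos <- cbind(x = 0, y = 10 * t, z = 500 + 20 * sin(2 * pi * 2 * t))
  truth <- pos
  m <- marker_trajectory("DPHAL_FL_L", pos)
  gap <- 300:312                             # inside one cycle, flanked by others
  m$positions[gap, ] <- NA
  m$occluded[gap] <- TRUE
  out <- fill_gaps(m, "cyclic")
  expect_false(any(out$occluded))
  expect_lt(max(abs(out$positions[gap, ] - truth[gap, ])), 0.1)
})

test_that("cyclic fill with a donor copies its offset-matched shape", {
  fs <- 200
  t <- (0:(2 * fs - 1)) / fs
  shape <- 15 * sin(2 * pi * 2 * t)
  donor <- marker_trajectory("PHAL_FL_L", cbind(0, 0, 600 + shape))
  m <- marker_trajectory("DPHAL_FL_L", cbind(0, 0, 500 + shape))
  truth <- 500 + shape
  gap <- 150:160
  m$positions[gap, ] <- NA; m$occluded[gap] <- TRUE
  out <- fill_gaps(m, "cyclic", donor = donor)
  expect_lt(max(abs(out$positions[gap, "z"] - truth[gap])), 0.1)
})

test_that("gaps beyond max_gap are left occluded and reported", {
  tr <- linear_traj(n = 80)
  tr$positions[10:40, ] <- NA; tr$occluded[10:40] <- TRUE
  out <- fill_gaps(tr, "spline", max_gap = 20)
  expect_true(all(out$occluded[10:40]))
  expect_equal(unname(attr(out, "unfilled")[1, ]), c(10, 40))
  # the threshold itself is inclusive: a run of exactly max_gap fills
  tr2 <- linear_traj(n = 80)
  tr2$positions[10:29, ] <- NA; tr2$occluded[10:29] <- TRUE
  expect_false(any(fill_gaps(tr2, "spline", max_gap = 20)$occluded))
})

test_that("fill_gaps never alters non-occluded frames", {
  set.seed(1)
  pos <- cbind(cumsum(rnorm(120)), cumsum(rnorm(120)), 500 + cumsum(rnorm(120)))
  m <- marker_trajectory("T1", pos)
  intact <- m$positions
  m$positions[50:54, ] <- NA; m$occluded[50:54] <- TRUE
  for (method in c("spline")) {
    out <- fill_gaps(m, method)
    expect_identical(out$positions[-(50:54), ], intact[-(50:54), ])
  }
  expect_error(fill_gaps(marker_trajectory("X", matrix(NA_real_, 10, 3),
                                           occluded = rep(TRUE, 10))),
               "entirely occluded")
})

test_that("the zero-lag filter passes DC exactly and is phaseless at 1 Hz", {
  fs <- 200
  const <- marker_trajectory("T1", matrix(123.456, 400, 3))
  out <- lowpass(const, filter_spec(), fs)
  expect_lt(max(abs(out$positions - 123.456)), 1e-9)

  t <- (0:(6 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * t)
  m <- marker_trajectory("T1", cbind(x, x, x))
  y <- lowpass(m, filter_spec(), fs)$positions[, 1]
  mid <- (fs + 1):(5 * fs)                 # away from the ends
  amp <- (max(y[mid]) - min(y[mid])) / 2
  expect_gte(amp, 0.999); expect_lte(amp, 1.001)
  # each interior input zero-crossing has a filtered counterpart within 1 ms
  zc_in <- t[mid][which(diff(sign(x[mid])) > 0)]
  zc_out <- t[mid][which(diff(sign(y[mid])) > 0)]
  zc_in <- zc_in[zc_in > min(t[mid]) + 0.1 & zc_in < max(t[mid]) - 0.1]
  shift <- max(vapply(zc_in, function(z) min(abs(zc_out - z)), 0))
  expect_lt(shift, 1e-3)
  # cross-correlation peak at zero lag
  cc <- stats::ccf(y[mid], x[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("50 Hz content is attenuated as the analytic response predicts", {
  fs <- 200
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 50 * t)
  y <- lowpass(marker_trajectory("T1", cbind(x, 0 * t, 0 * t)),
               filter_spec(), fs)$positions[, 1]
  mid <- (fs + 1):(3 * fs)
  # two passes of a 4th-order Butterworth: |H|^2 = 1/(1 + (f/fc)^8)
  predicted <- 1 / (1 + (50 / 10)^8)
  expect_lt(max(abs(y[mid])), 1e-4)
  expect_lt(max(abs(y[mid])), 10 * predicted)
})

test_that("filtering twice changes sub-cutoff content by < 0.1% RMS", {
  fs <- 200
  t <- (0:(6 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 2 * t)
  m <- marker_trajectory("T1", cbind(x, x, x))
  y1 <- lowpass(m, filter_spec(), fs)
  y2 <- lowpass(y1, filter_spec(), fs)
  mid <- (fs + 1):(5 * fs)
  rel <- sqrt(mean((y2$positions[mid, 1] - y1$positions[mid, 1])^2)) /
    sqrt(mean(y1$positions[mid, 1]^2))
  expect_lt(rel, 0.001)
})

test_that("lowpass demands gap-free input and enough frames", {
  m <- linear_traj(n = 100)
  m$occluded[5] <- TRUE
  expect_error(lowpass(m, filter_spec(), 200), "occluded")
  expect_error(lowpass(linear_traj(n = 10), filter_spec(), 200), "frames")
  expect_error(filter_spec(order = 3), "even")
  expect_error(filter_spec(cutoff = -1), "positive")
})

test_that("differentiation matches analytic derivatives", {
  fs <- 200
  lin <- differentiate(linear_traj(n = 50, slope = c(0, 1, 0)), fs)
  expect_equal(unname(lin[, "y"]), rep(0.2, 50))      # 1 mm/frame = 0.2 m/s
  expect_equal(unname(lin[, "x"]), rep(0, 50))

  stat <- differentiate(marker_trajectory("T1", matrix(7, 30, 3)), fs)
  expect_equal(max(abs(stat)), 0)

  t <- (0:(2 * fs - 1)) / fs
  amp_mm <- 30
  m <- marker_trajectory("T1", cbind(0 * t, amp_mm * sin(2 * pi * 2 * t), 0 * t))
  v <- differentiate(m, fs)[, "y"]
  v_true <- (amp_mm / 1000) * 2 * pi * 2 * cos(2 * pi * 2 * t)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(v[interior] - v_true[interior])), 0.01 * max(abs(v_true)))

  expect_error(differentiate(marker_trajectory(
    "T1", matrix(1, 5, 3), occluded = c(FALSE, TRUE, FALSE, FALSE, FALSE)),
    fs), "occluded")
})
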