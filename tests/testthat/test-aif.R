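test_that("population blood curve is zero pre-bolus and biexponential after", {
  t <- default_times()
  aif <- aif_model(onset_time = 10)
  cb <- population_blood_curve(aif, t)
  expect_true(all(cb$values[t < 10] == 0))
  expect_true(all(cb$values >= 0))

  # equal rates collapse to a single exponential, monotone decreasing
  m <- 0.2
  a2 <- aif_model(a1 = 1, a2 = 1, m1 = m, m2 = m, dose = 1, scale = 1,
                  onset_time = 10)
  cb2 <- population_blood_curve(a2, t)
  post <- t >= 10
  expect_equal(cb2$values[post], 2 * exp(-m * (t[post] - 10) / 60))
  expect_true(all(diff(cb2$values[post]) < 0))

  # default constants on the 50-frame/7.6 s grid: discrete max at the
  # first post-onset frame (biexponential decays from onset)
  expect_equal(which.max(cb$values), which(post)[1])

  expect_error(population_blood_curve(aif, c(0, 0, 1)), "increasing")
})

test_that("blood-to-plasma conversion is the (1-HCT) scaling", {
  t <- default_times()
  cb <- population_blood_curve(aif_model(), t)
  expect_equal(blood_to_plasma(cb, 0)$values, cb$values)

  flat <- conc_curve(t, rep(1, length(t)), "blood")
  cp <- blood_to_plasma(flat, 0.45)
  expect_equal(cp$values, rep(0.55, length(t)))
  expect_identical(cp$compartment, "plasma")

  # composition of scalings and linearity
  cb2 <- conc_curve(t, 3 * cb$values, "blood", onset_time = 10)
  expect_equal(blood_to_plasma(cb2, 0.45)$values,
               3 * blood_to_plasma(cb, 0.45)$values)
  twice <- conc_curve(t, blood_to_plasma(cb, 0.45)$values, "blood",
                      onset_time = 10)
  expect_equal(blood_to_plasma(twice, 0.45)$values,
               (1 - 0.45)^2 * cb$values)

  expect_error(blood_to_plasma(cb, 1), "hct")
  expect_error(blood_to_plasma(cp, 0.45), "blood")
})

test_that("AIF calibration recovers scale and onset", {
  t <- default_times()
  pop <- aif_model(onset_time = 10)
  self <- population_blood_curve(pop, t)

  cal <- calibrate_aif(pop, list(self))
  expect_equal(cal$scale, 1, tolerance = 1e-6)
  expect_equal(cal$onset_time, 10, tolerance = 1e-3)

  # exact multiplicative factors, property over several c > 0
  for (c_fac in c(0.5, 2, 7.25)) {
    meas <- conc_curve(t, c_fac * self$values, "blood", onset_time = 10)
    cal_c <- calibrate_aif(pop, list(meas, meas, meas))
    expect_equal(cal_c$scale, c_fac, tolerance = 1e-6)
  }

  # 10 noisy patient curves with a known generating factor
  set.seed(11)
  gen <- 1.8
  meas <- lapply(1:10, function(i) {
    noise <- 1 + rnorm(length(t), 0, 0.05)
    conc_curve(t, pmax(gen * self$values * noise, 0), "blood",
               onset_time = 10)
  })
  cal_n <- calibrate_aif(pop, meas)
  expect_lt(abs(cal_n$scale - gen) / gen, 0.05)

  expect_error(calibrate_aif(pop, list()), "non-empty")
  zero <- conc_curve(t, rep(0, length(t)), "blood")
  expect_error(suppressWarnings(calibrate_aif(pop, list(zero))),
               "degenerate")

  # residual sum of squares non-increasing relative to scale = 1
  meas2 <- conc_curve(t, 2.5 * self$values, "blood", onset_time = 10)
  cal2 <- calibrate_aif(pop, list(meas2))
  rss <- function(s) {
    m <- pop; m$scale <- s
    sum((population_blood_curve(m, t)$values - meas2$values)^2)
  }
  expect_lte(rss(cal2$scale), rss(1))
})

test_that("bolus arrival detection finds steps, falls back on flat curves", {
  ec <- enhancement_curve(c(0, 1, 2, 3), c(0.5, 0.5, 10, 10),
                          injection_time = 1.5)
  expect_equal(detect_bolus_arrival(ec, n_baseline_frames = 2), 2)

  flat <- enhancement_curve(c(0, 1, 2, 3), rep(5, 4), injection_time = 1.5)
  expect_warning(arr <- detect_bolus_arrival(flat, n_baseline_frames = 2),
                 "falling back")
  expect_equal(arr, 1.5)

  # noisy curve with known onset frame, SNR 20
  p <- default_protocol()
  t <- protocol_times(p)
  onset_frame <- 6L  # first enhancing frame
  set.seed(5)
  amp <- 100
  sig <- 100 + ifelse(seq_along(t) >= onset_frame,
                      amp * (1 - exp(-(t - t[onset_frame] + 2) / 15)), 0) +
    rnorm(length(t), 0, amp / 20)
  ec2 <- enhancement_curve(t, sig, injection_time = t[onset_frame] - 1)
  det <- detect_bolus_arrival(ec2, n_baseline_frames = 5)
  expect_lte(abs(det - t[onset_frame]), p$frame_interval)

  expect_error(detect_bolus_arrival(ec, n_baseline_frames = 0), "baseline")
})

test_that("Cb/Cp non-negativity and zero-before-onset hold across models", {
  t <- default_times()
  set.seed(7)
  for (i in 1:20) {
    aif <- aif_model(a1 = runif(1, 0.5, 8), a2 = runif(1, 0.5, 8),
                     m1 = runif(1, 0.01, 0.5), m2 = runif(1, 0.001, 0.05),
                     dose = runif(1, 0.05, 0.2),
                     scale = runif(1, 0.2, 5),
                     onset_time = sample(c(0, 7.6, 10, 22.8), 1))
    cb <- population_blood_curve(aif, t)
    cp <- blood_to_plasma(cb, aif$hct)
    expect_true(all(cb$values >= 0))
    expect_true(all(cp$values >= 0))
    expect_true(all(cb$values[t < aif$onset_time] == 0))
    expect_true(all(cp$values[t < aif$onset_time] == 0))
  }
})

test_that("AIF model constructor enforces invariants", {
  expect_error(aif_model(a1 = -1), "positive")
  expect_error(aif_model(scale = 0), "scale")
  expect_error(aif_model(hct = 1), "hct")
  expect_error(conc_curve(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(conc_curve(c(1, 2), c(0, Inf)), "finite")
})
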