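test_that("forward model limits: vascular-only and Patlak", {
  cp <- default_cp()
  t <- cp$times
  frame <- diff(t)[1]

  # ktrans = 0: pure vascular term, shifted Cp
  ct_v <- forward_extended_tofts(pk_params(0, 1, 0.1, delta = frame), cp)
  expect_equal(ct_v$values, 0.1 * c(0, cp$values[-length(t)]))

  # vp = 0, kep = 0: cumulative integral of the shifted input
  kt <- 0.04
  ct_p <- forward_extended_tofts(pk_params(kt, 0, 0), cp)
  manual <- kt * c(0, cumsum(diff(t) / 60 *
                               (cp$values[-1] + cp$values[-length(t)]) / 2))
  expect_equal(ct_p$values, manual)
})

test_that("discrete convolution matches the analytic closed form within 0.5%", {
  p <- default_protocol()
  t <- protocol_times(p)
  # exponential plasma input from t = 0, lag 0: closed-form solution
  for (kep in c(0.5, 2, 5, 20)) {
    m <- 0.144
    cp <- conc_curve(t, exp(-m * t / 60), "plasma", onset_time = 0)
    vp <- 0.1; kt <- 0.05
    ct <- forward_extended_tofts(pk_params(kt, kep, vp), cp)
    analytic <- vp * exp(-m * t / 60) +
      kt * (exp(-m * t / 60) - exp(-kep * t / 60)) / (kep - m)
    expect_lt(max(abs(ct$values - analytic)) / max(analytic), 0.005)
  }
})

test_that("forward model is linear in (ktrans, vp) at fixed kep and delta", {
  cp <- default_cp()
  set.seed(3)
  for (i in 1:10) {
    kt <- runif(1, 0, 0.3); kep <- runif(1, 0.1, 8); vp <- runif(1, 0, 0.4)
    d <- sample(0:2, 1) * 7.6
    a <- forward_extended_tofts(pk_params(kt, kep, vp, d), cp)
    b <- forward_extended_tofts(pk_params(2 * kt, kep, min(2 * vp, 1), d), cp)
    if (2 * vp <= 1)
      expect_equal(b$values, 2 * a$values, tolerance = 1e-12)
  }
})

test_that("noiseless round trip recovers parameters within 1% and exact lag", {
  cp <- default_cp()
  truth <- pk_params(0.05, 2.0, 0.15, delta = 7.6)
  ct <- forward_extended_tofts(truth, cp)
  fit <- tofts_fit(ct, cp)
  cf <- coef(fit)
  expect_lt(abs(cf["ktrans"] - truth$ktrans) / truth$ktrans, 0.01)
  expect_lt(abs(cf["kep"] - truth$kep) / truth$kep, 0.01)
  expect_lt(abs(cf["vp"] - truth$vp) / truth$vp, 0.01)
  expect_identical(unname(cf["delta"]), 7.6)
  expect_gt(fit$r2, 0.9999)

  # ve is the derived ratio
  expect_equal(unname(cf["ve"]), unname(cf["ktrans"] / cf["kep"]))
})

test_that("all-zero tissue curve yields zero parameters with flag", {
  cp <- default_cp()
  ct0 <- conc_curve(cp$times, rep(0, length(cp$times)), "tissue")
  fit <- tofts_fit(ct0, cp)
  expect_identical(fit$status, "zero")
  expect_equal(unname(coef(fit)[c("ktrans", "kep", "vp")]), c(0, 0, 0))
})

test_that("fit is scale-consistent in (Ct, Cp) and SSE-optimal in delta", {
  cp <- default_cp()
  truth <- pk_params(0.08, 1.2, 0.1, delta = 15.2)
  ct <- forward_extended_tofts(truth, cp)
  set.seed(9)
  ctn <- conc_curve(ct$times,
                    ct$values + rnorm(length(ct$times), 0,
                                      0.02 * max(ct$values)), "tissue")
  fit1 <- tofts_fit(ctn, cp)
  for (c_fac in c(0.1, 10)) {
    ct_s <- conc_curve(ctn$times, c_fac * ctn$values, "tissue")
    cp_s <- conc_curve(cp$times, c_fac * cp$values, "plasma",
                       onset_time = cp$onset_time)
    fit2 <- tofts_fit(ct_s, cp_s)
    expect_equal(coef(fit2), coef(fit1), tolerance = 1e-4)
  }
  # the chosen lag minimizes SSE over the grid
  expect_equal(min(fit1$delta_sse), fit1$sse, tolerance = 1e-10)
  expect_equal(as.numeric(names(which.min(fit1$delta_sse))) * 7.6,
               unname(coef(fit1)["delta"]))
})

test_that("parameter recovery is <1% on noiseless cohort-like curves", {
  cp <- default_cp()
  set.seed(21)
  spec <- cohort_spec()
  worst <- 0
  for (cl in c("benign", "malignant")) {
    for (i in 1:5) {
      truth <- sample_lesion_params(cl, spec)
      ct <- forward_extended_tofts(truth, cp)
      if (max(ct$values) == 0) next
      cf <- coef(tofts_fit(ct, cp))
      for (par in c("ktrans", "kep", "vp")) {
        tv <- truth[[par]]
        if (tv > 1e-6)
          worst <- max(worst, abs(cf[par] - tv) / tv)
      }
    }
  }
  expect_lt(worst, 0.01)
})

test_that("noisy replicates: median recovered ktrans within 10% of truth", {
  cp <- default_cp()
  truth <- pk_params(0.05, 2.0, 0.15, delta = 7.6)
  ct <- forward_extended_tofts(truth, cp)
  set.seed(42)
  sd_abs <- 0.05 * max(ct$values)
  est <- replicate(100, {
    ctn <- conc_curve(ct$times, ct$values + rnorm(length(ct$times), 0, sd_abs),
                      "tissue")
    unname(coef(tofts_fit(ctn, cp))["ktrans"])
  })
  expect_lt(abs(median(est) - truth$ktrans) / truth$ktrans, 0.10)
})

test_that("voxelwise fitting reproduces region truths and is order-independent", {
  p <- default_protocol()
  aif <- cohort_aif(p)
  cp <- default_cp(p, aif)
  dims <- c(6, 6, 2)
  m1 <- array(FALSE, dims); m1[1:3, 1:3, 1] <- TRUE
  m2 <- array(FALSE, dims); m2[4:6, 4:6, 2] <- TRUE
  tr <- list(list(mask = m1, params = pk_params(0.03, 1.0, 0.10)),
             list(mask = m2, params = pk_params(0.06, 2.5, 0.25)))
  set.seed(4)
  series <- generate_phantom_volume(tr, aif, p, noise_sd = 0.005)
  maps <- fit_voxelwise(series, cp, m1 | m2, p, delay_grid = 0:2)

  expect_lt(abs(median(maps$ktrans[m1]) - 0.03) / 0.03, 0.05)
  expect_lt(abs(median(maps$ktrans[m2]) - 0.06) / 0.06, 0.05)
  expect_true(all(is.na(maps$ktrans[!(m1 | m2)])))
  expect_true(all(maps$status[!(m1 | m2)] == "absent"))

  # single-voxel mask equals fit_curve on that voxel's curve
  mv <- array(FALSE, dims); mv[2, 2, 1] <- TRUE
  maps1 <- fit_voxelwise(series, cp, mv, p, delay_grid = 0:2)
  ec <- enhancement_curve(protocol_times(p), series[2, 2, 1, ],
                          injection_time = p$baseline_s)
  ref <- tofts_fit(signal_to_concentration(ec), cp, delay_grid = 0:2)
  expect_equal(maps1$ktrans[2, 2, 1], unname(coef(ref)["ktrans"]))

  expect_error(fit_voxelwise(series, cp, array(FALSE, dims), p), "mask")
})
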