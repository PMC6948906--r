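test_that("parameter draws are deterministic given the seed and respect bounds", {
  spec <- cohort_spec()
  set.seed(100); d1 <- sample_lesion_params("malignant", spec)
  set.seed(100); d2 <- sample_lesion_params("malignant", spec)
  expect_identical(d1, d2)

  set.seed(101)
  draws <- replicate(500, {
    pk <- sample_lesion_params(sample(c("benign", "borderline",
                                        "malignant"), 1), spec)
    c(pk$ktrans, pk$kep, pk$vp, pk$delta)
  })
  expect_true(all(draws[1, ] >= 0))
  expect_true(all(draws[2, ] >= 0))
  expect_true(all(draws[3, ] >= 0 & draws[3, ] <= 1))
  expect_true(all(draws[4, ] %in% (0:2 * 7.6)))
})

test_that("sampler means match analytic oracles (law of large numbers)", {
  n <- 10000
  # lognormal family (default): moment-matched, mean is the class mean
  set.seed(7)
  spec_ln <- cohort_spec(family = "lognormal")
  kt_ln <- replicate(n, sample_lesion_params("benign", spec_ln)$ktrans)
  se <- sd(kt_ln) / sqrt(n)
  expect_lt(abs(mean(kt_ln) - 0.03), 3 * se)

  # truncated-normal family: oracle is the analytic truncated mean
  set.seed(8)
  spec_tn <- cohort_spec(family = "truncnorm")
  kt_tn <- replicate(n, sample_lesion_params("benign", spec_tn)$ktrans)
  mu_trunc <- truncnorm_mean(0.03, 0.02)
  se_tn <- sd(kt_tn) / sqrt(n)
  expect_lt(abs(mean(kt_tn) - mu_trunc), 3 * se_tn)
})

test_that("simulated curves behave: flat truth, determinism, round trip", {
  p <- default_protocol()
  aif <- cohort_aif(p)
  set.seed(1)
  flat <- simulate_lesion_curve(pk_params(0, 0, 0), aif, p, noise_sd = 0,
                                si0 = 100)
  expect_equal(flat$signal, rep(100, p$n_frames))

  truth <- pk_params(0.04, 1.8, 0.12, delta = 7.6)
  set.seed(2); c1 <- simulate_lesion_curve(truth, aif, p, noise_sd = 0.05)
  set.seed(2); c2 <- simulate_lesion_curve(truth, aif, p, noise_sd = 0.05)
  set.seed(3); c3 <- simulate_lesion_curve(truth, aif, p, noise_sd = 0.05)
  expect_identical(c1$signal, c2$signal)
  expect_false(identical(c1$signal, c3$signal))

  # noiseless simulate -> fit recovers truth within 1%
  clean <- simulate_lesion_curve(truth, aif, p, noise_sd = 0)
  fit <- tofts_fit(signal_to_concentration(clean), default_cp(p, aif))
  cf <- coef(fit)
  expect_lt(abs(cf["ktrans"] - truth$ktrans) / truth$ktrans, 0.01)
  expect_lt(abs(cf["kep"] - truth$kep) / truth$kep, 0.01)
  expect_lt(abs(cf["vp"] - truth$vp) / truth$vp, 0.01)

  expect_error(simulate_lesion_curve(truth, aif, p, noise_sd = -0.1),
               "noise_sd")
})

test_that("default cohort bookkeeping: 49 lesions, 43 patients, 27/3/19", {
  co <- generate_cohort(seed = 0)
  m <- co$manifest
  expect_equal(nrow(m), 49)
  expect_equal(sum(m$class == "benign"), 27)
  expect_equal(sum(m$class == "borderline"), 3)
  expect_equal(sum(m$class == "malignant"), 19)
  expect_equal(length(unique(m$patient_id)), 43)

  # bilateral patients carry exactly two malignant lesions
  tab <- table(m$patient_id)
  bi <- names(tab[tab == 2])
  expect_length(bi, 6)
  expect_true(all(m$class[m$patient_id %in% bi] == "malignant"))

  # bit-reproducible given (spec, seed)
  co2 <- generate_cohort(seed = 0)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(lapply(co$curves, `[[`, "signal"),
                   lapply(co2$curves, `[[`, "signal"))
})

test_that("degenerate class counts still generate and run", {
  spec <- cohort_spec(n_benign = 6, n_borderline = 0, n_malignant = 6,
                      n_bilateral = 2)
  co <- generate_cohort(spec, seed = 4)
  expect_equal(nrow(co$manifest), 12)
  expect_equal(length(unique(co$manifest$patient_id)), 10)
  expect_false(any(co$manifest$class == "borderline"))
})

test_that("phantom volumes honor region truths and reject overlaps", {
  p <- default_protocol()
  aif <- cohort_aif(p)
  dims <- c(4, 4, 1)
  m1 <- array(FALSE, dims); m1[1:2, 1:2, 1] <- TRUE
  truth <- pk_params(0.05, 2, 0.2)
  series <- generate_phantom_volume(list(list(mask = m1, params = truth)),
                                    aif, p, noise_sd = 0)
  # every in-region voxel curve identical to the region curve
  ref <- series[1, 1, 1, ]
  expect_equal(series[2, 2, 1, ], ref)
  expect_gt(max(ref), 100)
  # background flat at baseline
  expect_equal(series[4, 4, 1, ], rep(100, p$n_frames))

  m2 <- array(FALSE, dims); m2[2:3, 2:3, 1] <- TRUE  # overlaps m1
  expect_error(generate_phantom_volume(
    list(list(mask = m1, params = truth), list(mask = m2, params = truth)),
    aif, p), "overlap")
})

test_that("cohort round-trips through CSV", {
  co <- generate_cohort(cohort_spec(n_benign = 3, n_borderline = 1,
                                    n_malignant = 2, n_bilateral = 1),
                        seed = 9)
  dir <- tempfile()
  write_cohort(co, dir)
  curves <- read_curves_csv(file.path(dir, "cohort_curves.csv"))
  expect_length(curves, 6)
  expect_equal(curves[["L01"]]$signal, co$curves[[1]]$signal,
               tolerance = 1e-8)
  man <- read.csv(file.path(dir, "cohort_manifest.csv"))
  expect_equal(man$class, co$manifest$class)
})
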