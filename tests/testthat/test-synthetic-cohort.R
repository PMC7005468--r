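test_that("default cohort has the study's class sizes", {
  cfg <- cohort_config(seed = 1)
  subs <- generate_cohort(cfg)
  expect_length(subs, 49)
  labs <- vapply(subs, `[[`, "", "label")
  expect_equal(sum(labs == "pilocytic_astrocytoma"), 22)
  expect_equal(sum(labs == "medulloblastoma"), 17)
  expect_equal(sum(labs == "ependymoma"), 10)
})

test_that("config validation rejects bad inputs", {
  expect_error(cohort_config(n_per_class = c(pilocytic_astrocytoma = 0)),
               "counts")
  expect_error(cohort_config(b_values_s_per_mm2 = c(1000, 1000)), "b")
  expect_error(cohort_config(b_values_s_per_mm2 = c(0, 500, 1000)),
               "two b-values")
  expect_error(cohort_config(tr_s = 0), "TR")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  bad_profile <- default_class_profile()
  bad_profile$sd[1] <- 0
  expect_error(generate_cohort(cohort_config(), bad_profile), "positive")
})

test_that("zero bolus amplitude gives a flat signal at S0", {
  t <- seq(0, 60, by = 1.5)
  s <- gamma_variate_signal(A = 0, alpha = 3, beta = 1.5, t0 = 10, t = t,
                            S0 = 100, TE_s = 0.03)
  expect_equal(s, rep(100, length(t)))
})

test_that("gamma-variate forward model peaks at t0 + alpha*beta", {
  tt <- seq(0, 40, by = 1e-3)
  c1 <- gamma_variate(tt, 2, 3, 1.5, 10)
  expect_equal(tt[which.max(c1)], 10 + 3 * 1.5, tolerance = 1e-2)
  c2 <- gamma_variate(tt, 1, 4.2, 0.9, 5)
  expect_equal(tt[which.max(c2)], 5 + 4.2 * 0.9, tolerance = 1e-2)
})

test_that("gamma-variate signal inverts through Delta-R2* and refits", {
  t <- seq(0, 88.5, by = 1.5)
  s <- gamma_variate_signal(A = 1, alpha = 3, beta = 1.5, t0 = 10,
                            K2_true = 0, t = t, S0 = 100, TE_s = 0.03)
  sig <- array(s, c(1, 1, 1, length(t)))
  conc <- signal_to_delta_r2star(sig, 0.03, 1:5, array(TRUE, c(1, 1, 1)))
  fit <- fit_gamma_variate(conc[1, 1, 1, ], t)
  expect_true(fit$converged)
  rel <- abs(c(fit$A - 1, fit$alpha - 3, fit$beta - 1.5, fit$t0 - 10) /
               c(1, 3, 1.5, 10))
  expect_lt(max(rel), 1e-3)
})

test_that("invalid bolus parameters are rejected", {
  t <- seq(0, 60, by = 1.5)
  expect_error(gamma_variate_signal(1, alpha = -1, beta = 1.5, t0 = 10, t = t),
               "positive")
  expect_error(gamma_variate_signal(1, alpha = 3, beta = 0, t0 = 10, t = t),
               "positive")
  expect_error(gamma_variate_signal(1, 3, 1.5, t0 = 500, t = t), "t0")
})

test_that("diffusion signal follows the mono-exponential model", {
  expect_equal(diffusion_signal(1.0e-3, 0, 100), 100)
  expect_equal(diffusion_signal(1.0e-3, 1000, 100), 100 * exp(-1))
  expect_error(diffusion_signal(1e-3, -10, 100), "b-value")
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  cfg <- small_config(seed = 11, noise_sd = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- small_config(seed = 12, noise_sd = 1)
  c <- generate_cohort(cfg2)
  expect_false(identical(a[[1]]$dsc, c[[1]]$dsc))
})

test_that("masks nest correctly and NAWM avoids the tumour", {
  s <- quantified_subject()$subject
  expect_true(all(s$brain_mask[s$roi_mask]))
  expect_true(all(s$brain_mask[s$nawm_mask]))
  expect_false(any(s$roi_mask & s$nawm_mask))
})

test_that("noiseless ADC ROI class means converge to the profile", {
  cfg <- small_config(n_per_class = c(pilocytic_astrocytoma = 22,
                                      medulloblastoma = 17,
                                      ependymoma = 10),
                      noise_sd = 0, seed = 5)
  subs <- generate_cohort(cfg)
  prof <- default_class_profile()
  labs <- vapply(subs, `[[`, "", "label")
  roi_means <- vapply(subs, function(s) {
    adc <- compute_adc(s$dwi_b0, s$dwi_b1, s$b_values[1], s$b_values[2],
                       s$brain_mask)
    mean(adc[s$roi_mask]) * 1e3
  }, numeric(1))
  for (cl in unique(labs)) {
    pv <- prof[prof$feature == "ADC_ROI_mean" & prof$class == cl, ]
    n <- sum(labs == cl)
    se <- pv$sd / sqrt(n)
    expect_lt(abs(mean(roi_means[labs == cl]) - pv$mean), 3 * se + 0.1 * pv$sd)
  }
})

test_that("larger bolus amplitude gives strictly larger UCBV", {
  t <- seq(0, 88.5, by = 1.5)
  ucbv <- vapply(c(1, 2, 5), function(A) {
    conc <- gamma_variate(t, A, 3, 1.5, 12)
    compute_ucbv(fit_gamma_variate(conc, t))
  }, numeric(1))
  expect_true(all(diff(ucbv) > 0))
  expect_equal(ucbv[2] / ucbv[1], 2, tolerance = 1e-6)
})
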