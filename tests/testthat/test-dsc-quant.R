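test_that("Delta-R2* is zero for baseline-level signal and inverts the model", {
  t <- seq(0, 45, by = 1.5)
  mask <- array(TRUE, c(2, 1, 1))
  sig <- array(80, c(2, 1, 1, length(t)))
  known_c <- gamma_variate(t, 2, 3, 1.5, 12)
  sig[2, 1, 1, ] <- 80 * exp(-0.03 * known_c)
  conc <- signal_to_delta_r2star(sig, 0.03, 1:5, mask)
  expect_equal(conc[1, 1, 1, ], rep(0, length(t)))
  expect_equal(conc[2, 1, 1, ], known_c, tolerance = 1e-12)
})

test_that("non-positive signal voxels are flagged and excluded", {
  t <- seq(0, 45, by = 1.5)
  mask <- array(TRUE, c(2, 1, 1))
  sig <- array(80, c(2, 1, 1, length(t)))
  sig[2, 1, 1, 5] <- -1
  conc <- signal_to_delta_r2star(sig, 0.03, 1:3, mask)
  expect_true(all(is.na(conc[2, 1, 1, ])))
  expect_false(anyNA(conc[1, 1, 1, ]))
  expect_equal(attr(conc, "n_bad_voxels"), 1L)
})

test_that("gamma fit handles degenerate curves with the A = 0 convention", {
  t <- seq(0, 45, by = 1.5)
  f <- fit_gamma_variate(rep(0, length(t)), t)
  expect_false(f$converged)
  expect_equal(f$A, 0)
  f2 <- fit_gamma_variate(c(NA, rep(0, length(t) - 1)), t)
  expect_false(f2$converged)
  expect_error(fit_gamma_variate(1:5, (1:5) * 1.5), "10 samples")
})

test_that("noise strictly degrades the gamma-fit RMSE", {
  t <- seq(0, 88.5, by = 1.5)
  conc <- gamma_variate(t, 5, 3, 1.5, 15)
  clean <- fit_gamma_variate(conc, t)
  noisy <- with_seed(3, fit_gamma_variate(conc + rnorm(length(t), 0, 0.3), t))
  expect_lt(clean$rmse, 1e-8)
  expect_gt(noisy$rmse, clean$rmse)
})

test_that("closed-form curve integral matches numerical quadrature", {
  with_seed(21, {
    for (i in 1:20) {
      A <- runif(1, 0.5, 10); al <- runif(1, 1, 6)
      be <- runif(1, 0.5, 4); t0 <- runif(1, 5, 20)
      num <- stats::integrate(function(x) gamma_variate(x, A, al, be, t0),
                              t0, Inf, rel.tol = 1e-10)$value
      expect_equal(gamma_variate_integral(A, al, be), num,
                   tolerance = 1e-6)
    }
  })
  expect_equal(gamma_variate_integral(1, 3, 1.5), 30.375)
})

test_that("UCBV is the calibrated analytic integral, NA when unconverged", {
  t <- seq(0, 88.5, by = 1.5)
  fit <- fit_gamma_variate(gamma_variate(t, 1, 3, 1.5, 10), t)
  expect_equal(compute_ucbv(fit), 30.375, tolerance = 1e-6)
  expect_equal(compute_ucbv(fit, calibration = 2), 60.75, tolerance = 1e-6)
  bad <- fit_gamma_variate(rep(0, length(t)), t)
  expect_true(is.na(compute_ucbv(bad)))
})

test_that("leakage correction recovers K2 and leaves no-leak voxels alone", {
  t <- seq(0, 88.5, by = 1.5)
  with_seed(9, {
    amps <- c(exp(rnorm(30, log(7), 0.2)), 8, 9, 10)
    k2s <- c(rep(0, 30), 0, 0.01, 0.05)
  })
  ph <- make_leakage_phantom(amps, k2s, t)
  fits <- fit_dsc_volume(ph$conc, t, ph$mask)
  ucbv <- ucbv_from_fits(fits)
  lc <- leakage_correct(ph$conc, t, ph$reference_mask, ucbv)
  k2_hat <- lc$k2[, 1, 1]
  expect_lt(max(abs(k2_hat[k2s == 0])), 1e-8)
  expect_lt(max(abs(k2_hat[32:33] - k2s[32:33]) / k2s[32:33]), 0.01)
  # no-leak voxel: CCBV equals UCBV to float tolerance
  expect_equal(lc$ccbv[31, 1, 1], ucbv[31, 1, 1], tolerance = 1e-9)
  # leaky voxels: corrected CBV closer to the amplitude-implied truth
  truth <- amps * gamma_variate_integral(1, 3, 1.5)
  for (i in 32:33) {
    expect_lt(abs(lc$ccbv[i, 1, 1] - truth[i]),
              abs(ucbv[i, 1, 1] - truth[i]))
  }
})

test_that("identical curves give a constant K2 map; flat reference warns", {
  t <- seq(0, 88.5, by = 1.5)
  ph <- make_leakage_phantom(rep(5, 8), rep(0, 8), t)
  ph$reference_mask <- array(c(TRUE, TRUE, rep(FALSE, 6)), ph$dims)
  fits <- fit_dsc_volume(ph$conc, t, ph$mask)
  ucbv <- ucbv_from_fits(fits)
  lc <- leakage_correct(ph$conc, t, ph$reference_mask, ucbv)
  expect_lt(diff(range(lc$k2[ph$mask])), 1e-10)

  flat <- array(1, c(4, 1, 1, length(t)))
  refm <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  u <- array(1, c(4, 1, 1))
  expect_warning(res <- leakage_correct(flat * 0, t, refm, u), "flat")
  expect_equal(res$ccbv, u)
})

test_that("QC masking removes exactly the predicate-failing voxels", {
  vals <- c(1.0, 2.9, 3.5)
  maps <- structure(list(ucbv = array(vals, c(3, 1, 1)),
                         ccbv = array(vals, c(3, 1, 1)),
                         qc_mask = array(TRUE, c(3, 1, 1))),
                    class = "perfusion_maps")
  rmse <- array(0, c(3, 1, 1))
  out <- apply_qc_mask(maps, rmse, rmse_threshold = 1, cbv_ceiling = 3.0)
  expect_equal(as.vector(out$qc_mask), c(TRUE, TRUE, FALSE))
  # infinite thresholds leave the mask unchanged
  out2 <- apply_qc_mask(maps, rmse, Inf, Inf)
  expect_equal(out2$qc_mask, maps$qc_mask)
  # brute-force predicate oracle + idempotence on random maps
  with_seed(13, {
    u <- array(rnorm(60, 0, 2), c(5, 4, 3))
    cc <- array(rnorm(60, 0, 2), c(5, 4, 3))
    rm_ <- array(abs(rnorm(60)), c(5, 4, 3))
    m <- structure(list(ucbv = u, ccbv = cc, qc_mask = array(TRUE, dim(u))),
                   class = "perfusion_maps")
    once <- apply_qc_mask(m, rm_, 0.8, 3.0)
    brute <- array(rm_ <= 0.8 & abs(u) <= 3 & abs(cc) <= 3, dim(u))
    expect_equal(once$qc_mask, brute)
    twice <- apply_qc_mask(once, rm_, 0.8, 3.0)
    expect_identical(twice$qc_mask, once$qc_mask)
  })
})

test_that("NAWM normalisation rescales to unit reference", {
  m <- array(3, c(4, 4, 2))
  nawm <- array(FALSE, c(4, 4, 2)); nawm[1:2, 1, 1] <- TRUE
  m[nawm] <- 2
  out <- normalise_to_nawm(m, nawm)
  expect_equal(out[3, 3, 1], 1.5)
  expect_equal(mean(out[nawm]), 1)
  # constant map -> constant 1; scale invariance; zero reference errors
  expect_equal(unique(as.vector(normalise_to_nawm(array(5, c(2, 2, 2)),
                                                  array(TRUE, c(2, 2, 2))))), 1)
  with_seed(4, {
    r <- array(rexp(32) + 0.5, c(4, 4, 2))
    n1 <- normalise_to_nawm(r, nawm)
    n2 <- normalise_to_nawm(r * 7.3, nawm)
    expect_equal(mean(n1[nawm]), 1)
    expect_equal(as.vector(n1), as.vector(n2), tolerance = 1e-12)
  })
  expect_error(normalise_to_nawm(array(0, c(2, 2, 2)),
                                 array(TRUE, c(2, 2, 2))), "zero")
})

test_that("subject quantification is internally consistent", {
  q <- quantified_subject()
  s <- q$subject; m <- q$maps
  expect_true(all(m$qc_mask[!s$brain_mask] == FALSE))
  expect_equal(mean(m$ucbv[s$nawm_mask & m$qc_mask]), 1, tolerance = 1e-9)
  expect_gt(m$fit_report$fraction_converged, 0.95)
  # voxel-wise K2 inside the tumour tracks the generator's ground truth
  gt <- s$ground_truth$k2[s$roi_mask]
  est <- m$k2[s$roi_mask]
  expect_gt(cor(gt, est), 0.99)
})
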