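# Shared small fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_config <- function(n_per_class = c(pilocytic_astrocytoma = 1,
                                         medulloblastoma = 1,
                                         ependymoma = 1),
                         noise_sd = 0, seed = 7, ...) {
  cohort_config(n_per_class = n_per_class, grid_shape = c(16, 16, 10),
                noise_sd = noise_sd, seed = seed, ...)
}

# one noiseless subject plus its quantified maps (used across modules)
quantified_subject <- function() {
  cached("quantified_subject", {
    s <- generate_cohort(small_config())[[1]]
    list(subject = s, maps = quantify_subject(s),
         adc = compute_adc(s$dwi_b0, s$dwi_b1, s$b_values[1], s$b_values[2],
                           s$brain_mask))
  })
}

# a small quantified image cohort for feature-table tests
image_cohort <- function() {
  cached("image_cohort", {
    cfg <- small_config(n_per_class = c(pilocytic_astrocytoma = 4,
                                        medulloblastoma = 3,
                                        ependymoma = 3),
                        noise_sd = 0.5, seed = 42)
    subjects <- generate_cohort(cfg)
    q <- quantify_cohort(subjects)
    list(subjects = subjects, maps = q$maps, adc = q$adc,
         table = build_feature_table(subjects, q$maps, q$adc))
  })
}

# construct a synthetic concentration 4-D array from per-voxel amplitudes and
# leakage rates sharing one bolus shape (exactly the leakage-correction model)
make_leakage_phantom <- function(amps, k2s, t, alpha = 3, beta = 1.5,
                                 t0 = 15) {
  n <- length(amps)
  stopifnot(length(k2s) == n)
  dims <- c(n, 1, 1)
  shape <- gamma_variate(t, 1, alpha, beta, t0)
  ref_amps <- amps[k2s == 0]
  ref_curve <- mean(ref_amps) * shape
  rint <- pedmri:::cumtrapz1(t, ref_curve)
  conc <- array(NA_real_, c(dims, length(t)))
  for (i in seq_len(n))
    conc[i, 1, 1, ] <- amps[i] * shape - k2s[i] * rint
  list(conc = conc, dims = dims, shape = shape,
       reference_mask = array(k2s == 0, dims),
       mask = array(TRUE, dims))
}

brute_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu, sd = sqrt(sum((x - mu)^2) / (n - 1)),
    skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

brute_auc <- function(values, pos) {
  vp <- values[pos]; vn <- values[!pos]
  tot <- sum(outer(vp, vn, ">")) + 0.5 * sum(outer(vp, vn, "=="))
  tot / (length(vp) * length(vn))
}
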