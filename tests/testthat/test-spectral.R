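test_that("bin segmentation drops the onset bin and validates sizes", {
  sp <- noiseless_spec("nl")
  su <- tuning_surface(sp)
  tr <- simulate_trial(su, sp, list(tf_hz = 4, sf_cpd = 0.11), fs_hz = 1000)
  w <- segment_bins(tr)
  expect_equal(dim(w), c(1000L, 10L))
  expect_equal(ncol(segment_bins(tr, discard_lead_bins = 0)), 11L)
  short <- simulate_trial(su, sp, list(tf_hz = 4, sf_cpd = 0.11),
                          fs_hz = 1000, trial_s = 1)
  expect_error(segment_bins(short), "insufficient-data")
})

test_that("coherent averaging preserves locked signals and cancels antiphase", {
  t <- (0:999) / 1000
  w_same <- matrix(rep(3 * cos(2 * pi * 12 * t), 10), 1000)
  sp <- coherent_spectrum(w_same, 1000)
  expect_equal(harmonic_amplitude(sp, 6, 2), 3, tolerance = 1e-12)

  w_anti <- sapply(1:10, function(k) cos(2 * pi * 12 * t + pi * (k %% 2)))
  expect_equal(harmonic_amplitude(coherent_spectrum(w_anti, 1000), 6, 2), 0,
               tolerance = 1e-12)

  expect_error(coherent_spectrum(list(), 1000), "insufficient-data")
  expect_error(coherent_spectrum(list(rnorm(10), rnorm(9)), 1000), "shape")
})

test_that("coherent gain on pure noise follows the 1/sqrt(N) law", {
  set.seed(42)
  amp_at <- function(n_win) {
    w <- matrix(rnorm(1000 * n_win), 1000)
    harmonic_amplitude(coherent_spectrum(w, 1000), 6, 2)
  }
  # ratio of Monte-Carlo mean amplitudes: E[amp] ~ 1/sqrt(N) gives 0.5
  r <- mean(replicate(200, amp_at(40))) / mean(replicate(200, amp_at(10)))
  expect_gt(r, 0.35)
  expect_lt(r, 0.70)
})

test_that("coherent averaging beats incoherent modulus averaging on noise", {
  set.seed(7)
  coh <- inc <- numeric(300)
  for (i in 1:300) {
    w <- matrix(rnorm(200 * 20), 200)
    sp <- apply(w, 2, function(col)
      Mod(coherent_spectrum(matrix(col), 200)$complex_amps[["12"]]))
    coh[i] <- harmonic_amplitude(coherent_spectrum(w, 200), 6, 2)
    inc[i] <- mean(sp)
  }
  expect_lt(mean(coh), mean(inc))
  expect_true(t.test(coh, inc, alternative = "less")$p.value < 1e-6)
})

test_that("harmonic lookup is exact-bin only", {
  sp <- coherent_spectrum(matrix(0, 1000, 2), 1000)
  expect_equal(harmonic_amplitude(sp, 4, 2), 0)        # reads the 8 Hz bin
  expect_error(harmonic_amplitude(sp, 0.25, 2), "frequency-grid")
  # 72 Hz (2F of 36) requires fs >= 144
  sp200 <- coherent_spectrum(matrix(0, 200, 1), 200)
  expect_equal(harmonic_amplitude(sp200, 36, 2), 0)
})

test_that("noiseless features recover the generating surface times the animal gain", {
  specs <- list(noiseless_spec("a", gain = 8), noiseless_spec("b", gain = 3))
  co <- simulate_cohort(specs, n_flies = 2, n_reps = 2, fs_hz = 200, seed = 9)
  # hand the animals non-unit gains through the spec instead: use fly_cv = 0,
  # so features must equal the flattened surface exactly
  fm <- feature_matrix(co)
  for (g in c("a", "b")) {
    su <- t(tuning_surface(specs[[match(g, c("a", "b"))]])$amplitude)
    for (f in fm$fly_id[fm$genotype == g]) {
      got <- as.numeric(fm[fm$fly_id == f, feature_names()])
      expect_lt(max(abs(got - as.vector(su))), 1e-8)
    }
  }
})

test_that("linearity: scaling the gain scales every feature", {
  co1 <- simulate_cohort(list(noiseless_spec("a", gain = 2)), n_flies = 1,
                         n_reps = 1, fs_hz = 200, seed = 4)
  co2 <- simulate_cohort(list(noiseless_spec("a", gain = 6)), n_flies = 1,
                         n_reps = 1, fs_hz = 200, seed = 4)
  f1 <- build_feature_vector(co1, "a_f01")$amplitudes
  f2 <- build_feature_vector(co2, "a_f01")$amplitudes
  expect_equal(f2, 3 * f1, tolerance = 1e-10)
})

test_that("repetition order does not affect the pooled coherent average", {
  set.seed(10)
  w <- matrix(rnorm(200 * 30), 200)
  a <- coherent_spectrum(w, 200)$complex_amps
  b <- coherent_spectrum(w[, sample(30)], 200)$complex_amps
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("incomplete flies are rejected with the missing condition named", {
  co <- simulate_cohort(list(noiseless_spec("a")), n_flies = 1, n_reps = 2,
                        fs_hz = 200, seed = 2)
  co$manifest <- co$manifest[co$manifest$cond_index != 10, ]
  expect_error(build_feature_vector(co, "a_f01"), "incomplete-fly")
  expect_error(build_feature_vector(co, "a_f01"), ssvep_design()$feature[10])
  expect_error(build_feature_vector(co, "nope"), "unknown fly_id")
})

test_that("the feature matrix has one row per animal in canonical column order", {
  specs <- list(noiseless_spec("a"), noiseless_spec("b"))
  co <- simulate_cohort(specs, n_flies = 3, n_reps = 1, fs_hz = 200, seed = 6)
  fm <- feature_matrix(co)
  expect_equal(dim(fm), c(6L, 66L))
  expect_identical(names(fm), c("fly_id", "genotype", feature_names()))
  # deterministic re-extraction
  expect_identical(fm, feature_matrix(co))
  co$manifest <- co$manifest[0, ]
  expect_error(feature_matrix(co), "empty-table")
})
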