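test_that("tuning surfaces have the documented shape", {
  # zero gain is a legal degenerate spec giving an all-zero surface
  zero <- tuning_surface(noiseless_spec("z", gain = 0))
  expect_true(all(zero$amplitude == 0))
  expect_error(genotype_spec("bad", gain = -1), "gain")

  ctrl <- tuning_surface(genotype_presets()[["ctrl_w1118"]])
  expect_true(all(ctrl$amplitude >= 0))
  # temporal bandpass peaks at the 6 Hz column
  tf_means <- colMeans(ctrl$amplitude)
  expect_equal(unname(which.max(tf_means)), match(6, temporal_freqs_hz()))
  # spatial roll-off above 0.88 cpd
  sf_means <- rowMeans(ctrl$amplitude)
  expect_lt(sf_means[match(1.76, spatial_freqs_cpd())],
            sf_means[match(0.44, spatial_freqs_cpd())])
  # the 1F admixture declines with spatial frequency
  w <- ctrl$f1_weight(spatial_freqs_cpd())
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0 & w <= 1))
  # deterministic
  expect_identical(ctrl$amplitude,
                   tuning_surface(genotype_presets()[["ctrl_w1118"]])$amplitude)
})

test_that("early-PD presets elevate the low-spatial-frequency response", {
  ps <- genotype_presets()
  ctrl <- tuning_surface(ps[["ctrl_w1118"]])$amplitude
  pd <- tuning_surface(ps[["pd_DJ1a"]])$amplitude
  low_sf <- 1:2
  expect_gt(mean(pd[low_sf, ] / ctrl[low_sf, ]), mean(pd[5:8, ] / ctrl[5:8, ]))
})

test_that("a noiseless trial carries the exact 2F amplitude and no 1F at high SF", {
  sp <- noiseless_spec("nl", gain = 5, low_sf_boost = 1, tf_peak_hz = 6,
                       tf_bandwidth_oct = 100, sf_cutoff_cpd = 1000)
  su <- tuning_surface(sp)
  # near-flat surface: amplitude at (6 Hz, 0.014 cpd) is ~5 by construction
  cond <- list(tf_hz = 6, sf_cpd = 0.014)
  tr <- simulate_trial(su, sp, cond, fs_hz = 1000)
  spec <- coherent_spectrum(segment_bins(tr), 1000)
  expect_equal(harmonic_amplitude(spec, 6, 2), su$amplitude["sf0.014", "tf6"],
               tolerance = 1e-12)

  # at the highest spatial frequency the 1F weight is ~0: spectral energy at
  # 1F is negligible relative to 2F
  tr2 <- simulate_trial(su, sp, list(tf_hz = 6, sf_cpd = 1.76), fs_hz = 1000)
  sp2 <- coherent_spectrum(segment_bins(tr2), 1000)
  e1 <- harmonic_amplitude(sp2, 6, 1)^2
  e2 <- harmonic_amplitude(sp2, 6, 2)^2
  expect_lt(e1, 1e-9 * e2)
})

test_that("trial simulation is seed-deterministic and Nyquist-guarded", {
  sp <- genotype_presets()[["ctrl_w1118"]]
  su <- tuning_surface(sp)
  cond <- list(tf_hz = 36, sf_cpd = 0.11)
  a <- simulate_trial(su, sp, cond, fs_hz = 200, seed = 7)
  b <- simulate_trial(su, sp, cond, fs_hz = 200, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_equal(length(a$samples), 200 * 11)
  d <- simulate_trial(su, sp, cond, fs_hz = 200, seed = 8)
  expect_false(identical(a$samples, d$samples))
  expect_error(simulate_trial(su, sp, cond, fs_hz = 100), "Nyquist|fs_hz")
  expect_error(simulate_trial(su, sp, list(tf_hz = 5, sf_cpd = 0.11),
                              fs_hz = 200), "design grid")
})

test_that("phase coherence: all bins of a noiseless trial share the 2F phase", {
  sp <- noiseless_spec("nl")
  su <- tuning_surface(sp)
  tr <- simulate_trial(su, sp, list(tf_hz = 12, sf_cpd = 0.056), fs_hz = 1000)
  w <- segment_bins(tr)
  phases <- apply(w, 2, function(col) {
    Arg(coherent_spectrum(matrix(col), 1000)$complex_amps[["24"]])
  })
  # circular SD
  R <- Mod(mean(exp(1i * phases)))
  expect_lt(sqrt(-2 * log(R)), 1e-6)
})

test_that("cohorts have the full factorial structure and seeded reproducibility", {
  ps <- genotype_presets()
  specs <- ps[c("ctrl_w1118", "pd_DJ1a")]
  co <- simulate_cohort(specs, n_flies = 20, n_reps = 10, fs_hz = 1000, seed = 5)
  expect_equal(nrow(co$manifest), 2 * 20 * 64 * 10)
  counts <- table(co$manifest$fly_id, co$manifest$cond_index)
  expect_true(all(counts == 10))

  # zero between-animal variability collapses all gains to 1
  co0 <- simulate_cohort(list(noiseless_spec("a")), n_flies = 5, n_reps = 1,
                         fs_hz = 200, seed = 1)
  expect_true(all(co0$manifest$fly_gain == 1))

  # different seeds: same design, different noise
  c1 <- simulate_cohort(ps["ctrl_w1118"], n_flies = 1, n_reps = 1,
                        fs_hz = 200, seed = 11)
  c2 <- simulate_cohort(ps["ctrl_w1118"], n_flies = 1, n_reps = 1,
                        fs_hz = 200, seed = 12)
  expect_equal(c1$manifest$cond_index, c2$manifest$cond_index)
  expect_false(identical(cohort_trial(c1, 1)$samples, cohort_trial(c2, 1)$samples))

  expect_error(simulate_cohort(list(noiseless_spec("x"), noiseless_spec("x")),
                               seed = 1), "duplicate")
  expect_error(simulate_cohort(specs, n_flies = 2, n_reps = 2, fs_hz = 200),
               "seed")
})

test_that("per-animal gains follow the requested log-normal variability", {
  sp <- genotype_spec("g", fly_cv = 0.3, noise_amp = 0)
  co <- simulate_cohort(list(sp), n_flies = 400, n_reps = 1, fs_hz = 200, seed = 3)
  gains <- unique(co$manifest[, c("fly_id", "fly_gain")])$fly_gain
  expect_equal(mean(gains), 1, tolerance = 0.05)
  expect_equal(sd(gains) / mean(gains), 0.3, tolerance = 0.05)
})
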