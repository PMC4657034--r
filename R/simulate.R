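#' Spatiotemporal tuning surface of a genotype
#'
#' Deterministically maps a `genotype_spec` to its expected second-harmonic
#' amplitude over the 8 x 8 stimulus grid. The surface is separable:
#' `amplitude[s, t] = gain * T(tf_t) * S(sf_s) * B(sf_s)` where `T` is a
#' log-Gaussian bandpass in temporal frequency (centre `tf_peak_hz`, SD
#' `tf_bandwidth_oct` octaves), `S` a logistic low-pass in log2 spatial
#' frequency with half-height at `sf_cutoff_cpd`, and `B` equals
#' `low_sf_boost` at the two lowest spatial frequencies and 1 elsewhere.
#'
#' The relative first-harmonic admixture `f1_weight(sf)` is a descending
#' logistic in log2 spatial frequency with half-point 0.05 cpd: at very low
#' spatial frequency the photoreceptors track the reversal frequency itself,
#' while at higher spatial frequencies their pooled response also moves to
#' the second harmonic.
#'
#' @param spec A `genotype_spec`.
#' @return An object of class `tuning_surface`: a list with `amplitude`
#'   (8 x 8 matrix, rows = spatial frequency ascending, cols = temporal
#'   frequency ascending, microvolts), `phase_2f` (radians) and `f1_weight`
#'   (a function of spatial frequency in cpd returning a value in `[0, 1]`).
#' @export
tuning_surface <- function(spec) {
  if (!inherits(spec, "genotype_spec")) stop("invalid-spec: expected a genotype_spec")
  tf <- temporal_freqs_hz()
  sf <- spatial_freqs_cpd()
  T_tf <- exp(-log2(tf / spec$tf_peak_hz)^2 / (2 * spec$tf_bandwidth_oct^2))
  # logistic low-pass in octaves; slope constant 0.5 oct gives the sharp
  # roll-off above the cutoff seen in wild-type spatial tuning
  S_sf <- 1 / (1 + exp((log2(sf) - log2(spec$sf_cutoff_cpd)) / 0.5))
  B_sf <- rep(1, length(sf))
  B_sf[1:2] <- spec$low_sf_boost
  amp <- spec$gain * outer(S_sf * B_sf, T_tf)
  dimnames(amp) <- list(sprintf("sf%g", sf), sprintf("tf%g", tf))
  # descending logistic, half-point 0.05 cpd, slope 0.4 octaves: 1F dominates
  # only at the very lowest spatial frequency and is negligible (< 1e-6
  # relative amplitude) above ~1 cpd
  f1w <- function(sf_cpd) 1 / (1 + exp((log2(sf_cpd) - log2(0.05)) / 0.4))
  structure(list(amplitude = amp, phase_2f = spec$phase_2f, f1_weight = f1w),
            class = "tuning_surface")
}

#' @export
print.tuning_surface <- function(x, ...) {
  cat("<tuning_surface> 8 x 8, peak", format(max(x$amplitude), digits = 4), "uV\n")
  print(round(x$amplitude, 3))
  invisible(x)
}

# Frequency-shaped Gaussian noise, synthesized independently per 1-s segment
# at 1 Hz spectral resolution: complex Gaussian Fourier coefficients are
# drawn directly with amplitude weight f^-alpha (DC removed) and
# inverse-transformed, so the time series is Gaussian with random phase per
# trial and cancels under coherent averaging.
.shaped_noise <- function(n_seg, fs_hz, noise_amp, noise_alpha) {
  n <- fs_hz
  nf <- n %/% 2L
  even <- n %% 2L == 0L
  m <- if (even) nf - 1L else nf          # number of paired (conjugate) bins
  hpos <- (1:nf)^(-noise_alpha)
  ndraw <- 2L * m + if (even) 1L else 0L
  R <- matrix(stats::rnorm(ndraw * n_seg), ndraw, n_seg)
  E <- matrix(0 + 0i, n, n_seg)
  E[2:(m + 1L), ] <- sqrt(n / 2) * hpos[1:m] *
    (R[1:m, , drop = FALSE] + 1i * R[(m + 1L):(2L * m), , drop = FALSE])
  if (even) E[nf + 1L, ] <- sqrt(n) * hpos[nf] * R[2L * m + 1L, ]
  E[n:(n - m + 1L), ] <- Conj(E[2:(m + 1L), , drop = FALSE])
  noise_amp * Re(stats::mvfft(E, inverse = TRUE)) / n
}

# Deterministic stimulus-locked component of one trial: 2F cosine plus the
# low-spatial-frequency 1F admixture, scaled by the per-animal gain.
.locked_signal <- function(surface, sf_index, tf_index, tf_hz, sf_cpd,
                           fly_gain, fs_hz, n) {
  t <- (seq_len(n) - 1) / fs_hz
  a2 <- surface$amplitude[sf_index, tf_index]
  a1 <- surface$f1_weight(sf_cpd) * a2
  fly_gain * (a2 * cos(2 * pi * 2 * tf_hz * t + surface$phase_2f) +
              a1 * cos(2 * pi * tf_hz * t + surface$phase_2f / 2))
}

#' Simulate one SSVEP trial
#'
#' Generates an 11-second voltage trace for a single animal, condition and
#' repetition: a stimulus-locked second-harmonic cosine at `2 * tf` (plus a
#' first-harmonic admixture at low spatial frequency, phase-locked at half
#' the 2F phase) scaled by the animal's gain, with additive random-phase
#' 1/f^alpha Gaussian noise. Because all reversal frequencies divide the 1-s
#' analysis bin exactly, the locked components have identical phase in every
#' bin.
#'
#' @param surface A `tuning_surface` (from [tuning_surface()]).
#' @param spec The generating `genotype_spec` (noise parameters).
#' @param condition List or one-row data frame with `tf_hz` and `sf_cpd`,
#'   both on the design grid.
#' @param fly_gain Positive multiplicative per-animal gain.
#' @param fs_hz Sampling rate, Hz; must be an integer >= 144 (Nyquist for the
#'   highest analysed frequency, 2 x 36 Hz).
#' @param seed Optional integer seed; when given the trial is exactly
#'   reproducible.
#' @param fly_id,genotype,repetition Metadata carried on the recording.
#' @param trial_s Trial duration in seconds (default 11).
#' @return An object of class `trial_recording` with elements `samples`
#'   (numeric, `fs_hz * trial_s` values, microvolts), `fs_hz`, `condition`,
#'   `fly_id`, `genotype`, `repetition`.
#' @export
simulate_trial <- function(surface, spec, condition, fly_gain = 1,
                           fs_hz = 1000, seed = NULL, fly_id = "fly1",
                           genotype = spec$name, repetition = 1L,
                           trial_s = 11) {
  if (fs_hz != round(fs_hz) || fs_hz < 2 * 2 * max(temporal_freqs_hz()))
    stop("configuration error: fs_hz must be an integer >= ",
         2 * 2 * max(temporal_freqs_hz()), " Hz (Nyquist for the highest 2F)")
  tf <- condition$tf_hz
  sf <- condition$sf_cpd
  si <- match(TRUE, abs(spatial_freqs_cpd() - sf) < 1e-9)
  ti <- match(TRUE, abs(temporal_freqs_hz() - tf) < 1e-9)
  if (is.na(si) || is.na(ti))
    stop("configuration error: condition (", tf, " Hz, ", sf, " cpd) is not on the design grid")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(fs_hz * trial_s))
  x <- .locked_signal(surface, si, ti, tf, sf, fly_gain, fs_hz, n)
  if (spec$noise_amp > 0) {
    n_seg <- n %/% fs_hz
    noise <- as.vector(.shaped_noise(n_seg, fs_hz, spec$noise_amp, spec$noise_alpha))
    if (length(noise) < n) noise <- c(noise, rep(0, n - length(noise)))
    x <- x + noise
  }
  structure(list(samples = x, fs_hz = fs_hz,
                 condition = list(tf_hz = tf, sf_cpd = sf),
                 fly_id = fly_id, genotype = genotype,
                 repetition = as.integer(repetition)),
            class = "trial_recording")
}

#' Simulate a seeded cohort of animals
#'
#' Builds the full experimental design: for each genotype, `n_flies` animals
#' each receive a log-normal per-animal gain (mean 1, coefficient of
#' variation `fly_cv`) and `n_reps` trials of every one of the 64 conditions,
#' presented in a per-repetition randomized order. Trials are not held in
#' memory; the cohort stores a manifest of per-trial seeds from which any
#' recording can be rematerialized exactly with [cohort_trial()]. The whole
#' cohort is reproducible from `seed`.
#'
#' @param specs List of `genotype_spec` objects with distinct names.
#' @param n_flies Animals per genotype (default 20).
#' @param n_reps Repetitions per condition (default 10).
#' @param fs_hz Sampling rate (default 1000 Hz, so every analysed frequency
#'   falls on an exact 1-Hz bin of a 1-s window).
#' @param seed Integer RNG seed (mandatory).
#' @return An object of class `ssvep_cohort` with the specs, precomputed
#'   tuning surfaces, the design grid, and a trial `manifest` data frame
#'   (one row per trial: genotype, fly_id, fly_gain, condition, repetition,
#'   presentation order, trial seed).
#' @export
simulate_cohort <- function(specs, n_flies = 20, n_reps = 10, fs_hz = 1000,
                            seed) {
  if (missing(seed) || is.null(seed)) stop("configuration error: seed is mandatory")
  if (length(specs) < 1) stop("invalid-design: at least one genotype_spec required")
  if (inherits(specs, "genotype_spec")) specs <- list(specs)
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("invalid-design: duplicate genotype names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (n_flies < 1 || n_reps < 1) stop("invalid-design: n_flies and n_reps must be >= 1")
  names(specs) <- nms
  design <- ssvep_design()
  set.seed(as.integer(seed))
  rows <- vector("list", length(specs))
  for (g in seq_along(specs)) {
    sp <- specs[[g]]
    if (sp$fly_cv > 0) {
      sdlog <- sqrt(log(1 + sp$fly_cv^2))
      gains <- stats::rlnorm(n_flies, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else gains <- rep(1, n_flies)
    per_fly <- vector("list", n_flies)
    for (f in seq_len(n_flies)) {
      # per-repetition random presentation order; pos[i] is the position of
      # manifest row i (condition within repetition) in the recording session
      ord <- as.vector(vapply(seq_len(n_reps), function(r) sample.int(64L), integer(64L)))
      pos <- integer(64L * n_reps)
      for (r in seq_len(n_reps)) {
        block <- ord[(r - 1L) * 64L + seq_len(64L)]
        pos[(r - 1L) * 64L + block] <- (r - 1L) * 64L + seq_len(64L)
      }
      per_fly[[f]] <- data.frame(
        genotype = sp$name,
        fly_id = sprintf("%s_f%02d", sp$name, f),
        fly_gain = gains[f],
        cond_index = rep(seq_len(64L), times = n_reps),
        repetition = rep(seq_len(n_reps), each = 64L),
        present_order = pos
      )
    }
    rows[[g]] <- do.call(rbind, per_fly)
  }
  manifest <- do.call(rbind, rows)
  manifest$sf_cpd <- design$sf_cpd[manifest$cond_index]
  manifest$tf_hz <- design$tf_hz[manifest$cond_index]
  manifest$trial_seed <- sample.int(.Machine$integer.max - 1L, nrow(manifest))
  rownames(manifest) <- NULL
  structure(list(
    specs = specs,
    surfaces = lapply(specs, tuning_surface),
    design = design,
    n_flies_per_genotype = as.integer(n_flies),
    n_reps = as.integer(n_reps),
    fs_hz = fs_hz,
    seed = as.integer(seed),
    manifest = manifest
  ), class = "ssvep_cohort")
}

#' @export
print.ssvep_cohort <- function(x, ...) {
  cat(sprintf("<ssvep_cohort> %d genotypes x %d flies x 64 conditions x %d reps = %d trials (fs %g Hz, seed %d)\n",
              length(x$specs), x$n_flies_per_genotype, x$n_reps,
              nrow(x$manifest), x$fs_hz, x$seed))
  invisible(x)
}

#' Materialize one trial of a cohort
#'
#' Regenerates a single `trial_recording` from the cohort manifest; the same
#' manifest row always yields an identical sample vector.
#'
#' @param cohort An `ssvep_cohort`.
#' @param row Manifest row index, or alternatively supply `fly_id`,
#'   `cond_index` and `repetition`.
#' @param fly_id,cond_index,repetition Trial coordinates (used when `row` is
#'   missing).
#' @return A `trial_recording`.
#' @export
cohort_trial <- function(cohort, row = NULL, fly_id = NULL, cond_index = NULL,
                         repetition = NULL) {
  m <- cohort$manifest
  if (is.null(row)) {
    row <- which(m$fly_id == fly_id & m$cond_index == cond_index &
                 m$repetition == repetition)
    if (length(row) != 1L) stop("trial not found in manifest")
  }
  r <- m[row, ]
  simulate_trial(cohort$surfaces[[r$genotype]], cohort$specs[[r$genotype]],
                 condition = list(tf_hz = r$tf_hz, sf_cpd = r$sf_cpd),
                 fly_gain = r$fly_gain, fs_hz = cohort$fs_hz,
                 seed = r$trial_seed, fly_id = r$fly_id,
                 genotype = r$genotype, repetition = r$repetition)
}

#' Export a cohort to a directory of CSV time series
#'
#' Writes `manifest.json` (design, specs, seed) and one two-column CSV per
#' trial (`time_s, microvolts`), named
#' `fly_<id>_cond_<tf>Hz_<sf>cpd_rep<k>.csv`. Intended for small cohorts;
#' files are rematerialized from the manifest seeds.
#'
#' @param cohort An `ssvep_cohort`.
#' @param dir Output directory (created if needed).
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    seed = cohort$seed, fs_hz = cohort$fs_hz,
    n_flies_per_genotype = cohort$n_flies_per_genotype, n_reps = cohort$n_reps,
    design = cohort$design,
    specs = lapply(cohort$specs, unclass)
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  m <- cohort$manifest
  for (i in seq_len(nrow(m))) {
    tr <- cohort_trial(cohort, row = i)
    fn <- sprintf("fly_%s_cond_%gHz_%gcpd_rep%d.csv", tr$fly_id,
                  tr$condition$tf_hz, tr$condition$sf_cpd, tr$repetition)
    utils::write.csv(data.frame(
      time_s = (seq_along(tr$samples) - 1) / tr$fs_hz,
      microvolts = tr$samples
    ), file.path(dir, fn), row.names = FALSE)
  }
  invisible(dir)
}
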