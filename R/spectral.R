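#' Segment a trial into analysis bins
#'
#' Cuts a recording into consecutive non-overlapping windows of `bin_s`
#' seconds and discards the leading bins (the first second of every trial is
#' dropped to eliminate stimulus-onset transients). With the defaults an
#' 11-s trial yields exactly 10 analysed bins.
#'
#' @param trial A `trial_recording`.
#' @param bin_s Bin duration in seconds (default 1).
#' @param discard_lead_bins Number of leading bins to drop (default 1).
#' @return A numeric matrix with one column per retained window
#'   (`fs_hz * bin_s` rows).
#' @export
segment_bins <- function(trial, bin_s = 1, discard_lead_bins = 1) {
  stopifnot(inherits(trial, "trial_recording"))
  n_bin <- trial$fs_hz * bin_s
  if (n_bin != round(n_bin)) stop("configuration error: bin_s * fs_hz must be an integer")
  n_bin <- as.integer(n_bin)
  n <- length(trial$samples)
  if (n %% n_bin != 0L)
    stop("configuration error: trial length is not a multiple of the bin length")
  k <- n %/% n_bin
  if (k <= discard_lead_bins)
    stop("insufficient-data: trial has ", k, " bins but ", discard_lead_bins,
         " are discarded; need at least ", discard_lead_bins + 1)
  w <- matrix(trial$samples, nrow = n_bin, ncol = k)
  w[, (discard_lead_bins + 1):k, drop = FALSE]
}

#' Coherent (phase-sensitive) spectrum of a set of windows
#'
#' Fourier-transforms each window and averages the complex coefficients
#' across windows before any modulus is taken. Stimulus-locked components
#' share the same phase in every window and add; non-locked components have
#' random phase and cancel on average. Coefficients are scaled one-sided so
#' that a cosine of amplitude A yields modulus A at its frequency bin.
#'
#' @param windows Numeric matrix (samples x windows) or list of equal-length
#'   numeric vectors.
#' @param fs_hz Sampling rate in Hz.
#' @return An object of class `spectral_estimate`: `complex_amps` (complex,
#'   one per frequency from 0 to the Nyquist bin, named in Hz), `freq_hz`,
#'   `fs_hz`, `bin_duration_s`.
#' @export
coherent_spectrum <- function(windows, fs_hz) {
  if (is.list(windows)) {
    if (length(windows) == 0L) stop("insufficient-data: no windows supplied")
    len <- lengths(windows)
    if (length(unique(len)) != 1L) stop("shape error: windows have unequal lengths")
    windows <- matrix(unlist(windows), nrow = len[1])
  }
  if (!is.matrix(windows)) windows <- matrix(windows, ncol = 1)
  if (ncol(windows) == 0L) stop("insufficient-data: no windows supplied")
  n <- nrow(windows)
  # the complex mean across windows commutes with the DFT, so one transform
  # of the mean window suffices
  co <- stats::fft(rowMeans(windows)) / n
  nf <- n %/% 2L
  one_sided <- co[seq_len(nf + 1L)]
  one_sided[-1L] <- 2 * one_sided[-1L]
  if (n %% 2L == 0L) one_sided[nf + 1L] <- one_sided[nf + 1L] / 2
  freq <- (0:nf) * fs_hz / n
  names(one_sided) <- format(freq, trim = TRUE)
  structure(list(complex_amps = one_sided, freq_hz = freq, fs_hz = fs_hz,
                 bin_duration_s = n / fs_hz),
            class = "spectral_estimate")
}

#' Harmonic amplitude of a spectral estimate
#'
#' Reads the modulus at `harmonic * input_freq_hz`; for the default second
#' harmonic the 1, 2 and 4 Hz reversal inputs are read at 2, 4 and 8 Hz
#' respectively. The requested frequency must fall exactly on the spectral
#' bin grid; the function never interpolates.
#'
#' @param spectrum A `spectral_estimate`.
#' @param input_freq_hz Stimulus reversal frequency, Hz.
#' @param harmonic Harmonic number (default 2).
#' @return Non-negative modulus at the harmonic frequency.
#' @export
harmonic_amplitude <- function(spectrum, input_freq_hz, harmonic = 2L) {
  stopifnot(inherits(spectrum, "spectral_estimate"))
  target <- harmonic * input_freq_hz
  i <- which(abs(spectrum$freq_hz - target) < 1e-9)
  if (length(i) != 1L)
    stop("frequency-grid error: ", target, " Hz is not an exact bin of the ",
         "1/", spectrum$bin_duration_s, " Hz grid (fs ", spectrum$fs_hz, " Hz)")
  Mod(spectrum$complex_amps[[i]])
}

# Pool the post-discard bins of all repetitions of every condition for one
# fly and return the complex 2F coefficient per condition (canonical order).
.fly_complex_2f <- function(cohort, fly_id, bin_s = 1, discard_lead_bins = 1) {
  m <- cohort$manifest[cohort$manifest$fly_id == fly_id, ]
  if (nrow(m) == 0L) stop("incomplete-fly error: unknown fly_id '", fly_id, "'")
  design <- cohort$design
  have <- table(factor(m$cond_index, levels = seq_len(64L)))
  if (any(have < cohort$n_reps)) {
    miss <- design$feature[have < cohort$n_reps]
    stop("incomplete-fly error: fly '", fly_id, "' is missing recordings for ",
         "condition(s): ", paste(miss, collapse = ", "))
  }
  # plain vectors: data-frame row access inside the trial loop is the
  # dominant cost at cohort scale
  cond_i <- m$cond_index; seeds <- m$trial_seed
  tf_v <- m$tf_hz; sf_v <- m$sf_cpd
  gain <- m$fly_gain[1]
  geno <- m$genotype[1]
  spec <- cohort$specs[[geno]]
  surface <- cohort$surfaces[[geno]]
  fs <- cohort$fs_hz
  n <- as.integer(round(fs * 11))
  n_bin <- fs * bin_s
  if (n_bin != round(n_bin)) stop("configuration error: bin_s * fs_hz must be an integer")
  n_bin <- as.integer(n_bin)
  k <- n %/% n_bin
  if (k <= discard_lead_bins)
    stop("insufficient-data: trial has ", k, " bins but ", discard_lead_bins,
         " are discarded")
  out <- complex(64L)
  for (ci in seq_len(64L)) {
    rows <- which(cond_i == ci)
    si <- (ci - 1L) %/% 8L + 1L
    ti <- (ci - 1L) %% 8L + 1L
    # the locked signal is identical across repetitions; only the noise is
    # redrawn (same sample arithmetic as simulate_trial, per trial seed)
    sig <- .locked_signal(surface, si, ti, tf_v[rows[1]], sf_v[rows[1]],
                          gain, fs, n)
    wmats <- lapply(rows, function(i) {
      set.seed(seeds[i])
      x <- sig
      if (spec$noise_amp > 0) {
        noise <- as.vector(.shaped_noise(n %/% fs, fs, spec$noise_amp,
                                         spec$noise_alpha))
        if (length(noise) < n) noise <- c(noise, rep(0, n - length(noise)))
        x <- x + noise
      }
      matrix(x, n_bin, k)[, (discard_lead_bins + 1):k, drop = FALSE]
    })
    pooled <- do.call(cbind, wmats)
    sp <- coherent_spectrum(pooled, cohort$fs_hz)
    target <- 2 * design$tf_hz[ci]
    j <- which(abs(sp$freq_hz - target) < 1e-9)
    if (length(j) != 1L)
      stop("frequency-grid error: 2F = ", target, " Hz not on the bin grid")
    out[ci] <- sp$complex_amps[[j]]
  }
  out
}

#' Second-harmonic feature vector for one animal
#'
#' For each of the 64 conditions, pools the post-discard 1-s bins of all
#' repetitions into a single flat coherent average and takes the modulus at
#' the second harmonic of the reversal frequency. Equal-weight pooling across
#' all bins of all repetitions implements within-animal coherent averaging.
#'
#' @param cohort An `ssvep_cohort`.
#' @param fly_id Animal identifier present in the cohort manifest.
#' @param bin_s,discard_lead_bins Binning parameters, see [segment_bins()].
#' @return An object of class `feature_vector`: `amplitudes` (named numeric,
#'   64 non-negative values in canonical order), `fly_id`, `genotype`.
#' @export
build_feature_vector <- function(cohort, fly_id, bin_s = 1, discard_lead_bins = 1) {
  z <- .fly_complex_2f(cohort, fly_id, bin_s, discard_lead_bins)
  amps <- Mod(z)
  names(amps) <- cohort$design$feature
  geno <- cohort$manifest$genotype[match(fly_id, cohort$manifest$fly_id)]
  structure(list(amplitudes = amps, fly_id = fly_id, genotype = geno),
            class = "feature_vector")
}

#' Feature matrix of a whole cohort
#'
#' One row per animal, 64 canonical amplitude columns plus `fly_id` and
#' `genotype` label columns. This table is the interchange format between the
#' spectral and classification halves of the pipeline (see
#' [write_features_csv()]).
#'
#' @param cohort An `ssvep_cohort`.
#' @param bin_s,discard_lead_bins Binning parameters, see [segment_bins()].
#' @return Data frame `fly_id`, `genotype`, then the 64 amplitude columns.
#' @export
feature_matrix <- function(cohort, bin_s = 1, discard_lead_bins = 1) {
  flies <- unique(cohort$manifest$fly_id)
  if (length(flies) == 0L) stop("empty-table error: cohort contains no recordings")
  rows <- lapply(flies, function(f)
    build_feature_vector(cohort, f, bin_s, discard_lead_bins))
  amps <- do.call(rbind, lapply(rows, function(r) r$amplitudes))
  out <- data.frame(
    fly_id = vapply(rows, `[[`, "", "fly_id"),
    genotype = vapply(rows, `[[`, "", "genotype"),
    amps, check.names = FALSE
  )
  rownames(out) <- NULL
  out
}
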