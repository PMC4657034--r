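#' Genotype specification for the synthetic SSVEP generator
#'
#' A `genotype_spec` parameterizes the phenomenological response model of one
#' fly line: an overall response gain, a log-Gaussian temporal bandpass, a
#' logistic spatial low-pass, an optional multiplicative elevation at the two
#' lowest spatial frequencies (the signature of the early-onset parkinsonism
#' lines, which respond much more strongly to coarse gratings), between-animal
#' gain variability and an additive 1/f^alpha noise floor.
#'
#' All preset parameter values shipped with the package are synthetic free
#' parameters chosen to reproduce the qualitative tuning structure of real
#' recordings (temporal bandpass peaking near 6 Hz, spatial roll-off above
#' 0.88 cpd); they are not measured values.
#'
#' @param name Genotype label (unique within a cohort).
#' @param class_label One of `"control"`, `"early_PD"`, `"late_PD"`,
#'   `"neurodegeneration"`.
#' @param gain Overall response scale in microvolts; must be >= 0 (a zero gain
#'   yields an all-zero tuning surface, useful for pure-noise simulations).
#' @param tf_peak_hz Centre of the temporal bandpass, in Hz (within 1--36).
#' @param tf_bandwidth_oct Bandwidth (SD) of the temporal bandpass, octaves.
#' @param sf_cutoff_cpd Half-height point of the spatial low-pass, cpd.
#' @param low_sf_boost Multiplicative elevation applied at the two lowest
#'   spatial frequencies (1 = none).
#' @param fly_cv Between-animal gain coefficient of variation (>= 0).
#' @param noise_amp Noise spectral scale, microvolts (>= 0).
#' @param noise_alpha Exponent of the 1/f^alpha noise amplitude spectrum.
#' @param phase_2f Stimulus-locked phase of the 2F component, radians.
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(name, class_label = "control", gain = 10,
                          tf_peak_hz = 6, tf_bandwidth_oct = 1.5,
                          sf_cutoff_cpd = 0.88, low_sf_boost = 1,
                          fly_cv = 0.2, noise_amp = 2, noise_alpha = 1,
                          phase_2f = pi / 4) {
  classes <- c("control", "early_PD", "late_PD", "neurodegeneration")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("invalid-spec: 'name' must be a non-empty string")
  if (!class_label %in% classes)
    stop("invalid-spec: class_label must be one of ", paste(classes, collapse = ", "))
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("invalid-spec: '", what, "' must be a finite number")
    x
  }
  gain <- num1(gain, "gain")
  if (gain < 0) stop("invalid-spec: gain must be non-negative")
  tf_peak_hz <- num1(tf_peak_hz, "tf_peak_hz")
  if (tf_peak_hz < 1 || tf_peak_hz > 36)
    stop("invalid-spec: tf_peak_hz must lie within [1, 36]")
  tf_bandwidth_oct <- num1(tf_bandwidth_oct, "tf_bandwidth_oct")
  if (tf_bandwidth_oct <= 0) stop("invalid-spec: tf_bandwidth_oct must be positive")
  sf_cutoff_cpd <- num1(sf_cutoff_cpd, "sf_cutoff_cpd")
  if (sf_cutoff_cpd <= 0) stop("invalid-spec: sf_cutoff_cpd must be positive")
  low_sf_boost <- num1(low_sf_boost, "low_sf_boost")
  if (low_sf_boost <= 0) stop("invalid-spec: low_sf_boost must be positive")
  fly_cv <- num1(fly_cv, "fly_cv")
  if (fly_cv < 0) stop("invalid-spec: fly_cv must be non-negative")
  noise_amp <- num1(noise_amp, "noise_amp")
  if (noise_amp < 0) stop("invalid-spec: noise_amp must be non-negative")
  noise_alpha <- num1(noise_alpha, "noise_alpha")
  phase_2f <- num1(phase_2f, "phase_2f")
  structure(list(
    name = name, class_label = class_label, gain = gain,
    tf_peak_hz = tf_peak_hz, tf_bandwidth_oct = tf_bandwidth_oct,
    sf_cutoff_cpd = sf_cutoff_cpd, low_sf_boost = low_sf_boost,
    fly_cv = fly_cv, noise_amp = noise_amp, noise_alpha = noise_alpha,
    phase_2f = phase_2f
  ), class = "genotype_spec")
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat(sprintf("<genotype_spec> %s (%s)\n", x$name, x$class_label))
  cat(sprintf("  gain %.3g uV | tf peak %.3g Hz (bw %.3g oct) | sf cutoff %.3g cpd | low-SF boost %.3g\n",
              x$gain, x$tf_peak_hz, x$tf_bandwidth_oct, x$sf_cutoff_cpd, x$low_sf_boost))
  cat(sprintf("  fly CV %.3g | noise %.3g uV (1/f^%.3g)\n", x$fly_cv, x$noise_amp, x$noise_alpha))
  invisible(x)
}

#' Bundled genotype presets
#'
#' Loads the ten synthetic genotype presets shipped with the package (four
#' control-like white-eyed lines, four early-onset-parkinsonism-like lines
#' with an elevated low-spatial-frequency response and a temporal bandpass
#' shifted slightly upward, one late-onset-like line and one general
#' neurodegeneration-like line with control-level gain but distinct tuning).
#' All numbers are synthetic free parameters.
#'
#' @param path Optional path to a JSON preset file (a mapping from genotype
#'   name to `genotype_spec` fields). Defaults to the bundled preset file.
#' @return A named list of `genotype_spec` objects.
#' @export
genotype_presets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "genotype_presets.json", package = "ssvepscreen",
                        mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(names(raw), function(nm) {
    fields <- as.list(raw[[nm]])
    do.call(genotype_spec, c(list(name = nm), fields))
  })
  names(specs) <- names(raw)
  specs
}

#' Write genotype specs to a JSON preset file
#'
#' @param specs Named list of `genotype_spec` objects.
#' @param path Output file path.
#' @export
write_genotype_presets <- function(specs, path) {
  stopifnot(is.list(specs), length(specs) > 0)
  out <- lapply(specs, function(s) {
    stopifnot(inherits(s, "genotype_spec"))
    unclass(s)[setdiff(names(s), "name")]
  })
  names(out) <- vapply(specs, `[[`, "", "name")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
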