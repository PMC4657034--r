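#' Stimulus design grid
#'
#' The stimulus ensemble crosses 8 contrast-reversal (temporal) frequencies
#' with 8 grating spatial frequencies, giving 64 distinct conditions. Each
#' condition is presented as an 11-second trial; the response is analysed at
#' the second harmonic (2F) of the reversal frequency, because
#' polarity-insensitive visual mechanisms respond twice per reversal cycle.
#'
#' The canonical condition (and feature) order is spatial frequency ascending
#' in the outer loop and temporal frequency ascending in the inner loop; every
#' feature table produced by this package uses this order.
#'
#' @return `ssvep_design()` returns a data frame with 64 rows and columns
#'   `sf_cpd`, `tf_hz` and `feature` (the canonical column label), in
#'   canonical order.
#' @examples
#' nrow(ssvep_design())  # 64
#' @export
ssvep_design <- function() {
  sf <- spatial_freqs_cpd()
  tf <- temporal_freqs_hz()
  grid <- expand.grid(tf_hz = tf, sf_cpd = sf, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("sf_cpd", "tf_hz")]
  grid$feature <- sprintf("sf%g_tf%g", grid$sf_cpd, grid$tf_hz)
  rownames(grid) <- NULL
  grid
}

#' @rdname ssvep_design
#' @export
temporal_freqs_hz <- function() c(1, 2, 4, 6, 8, 12, 18, 36)

#' @rdname ssvep_design
#' @export
spatial_freqs_cpd <- function() c(0.014, 0.028, 0.056, 0.11, 0.22, 0.44, 0.88, 1.76)

#' @rdname ssvep_design
#' @export
feature_names <- function() ssvep_design()$feature
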