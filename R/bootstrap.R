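#' Bootstrap distribution of cross-validated classification accuracy
#'
#' Each iteration resamples animals with replacement, stratified within class
#' so that class sizes are preserved, refits the classifier under k-fold (by
#' default leave-one-out) cross-validation on the resample and records the
#' accuracy `1 - loss`. Cross-validation folds within a resample are grouped
#' by animal of origin: all bootstrap copies of an animal share a fold, so
#' duplicates cannot leak between training and test sides (ungrouped folds
#' would bias the no-effect null visibly above chance). The resulting distribution estimates how the
#' classifier generalizes. Classification is deemed significantly above
#' chance when fewer than 1% of bootstrap accuracies fall at or below 0.5
#' (two classes), or strictly below 1/K (K-way); the boundary inclusion
#' differs between the two criteria by design.
#'
#' An iteration whose resample cannot be fitted (e.g. a class collapsing to
#' one repeated point) is retried with a fresh draw; a retry rate above 1%
#' raises an instability warning recorded on the report.
#'
#' @param X,y Features and labels.
#' @param n_iter Number of bootstrap iterations (the reference analysis uses
#'   10,000; a reduced count such as 1,000 is adequate for test work).
#' @param k_folds Folds for the per-iteration loss; `NULL` = leave-one-out.
#' @param gamma,delta Regularization parameters (typically from
#'   [optimize_regularization()]).
#' @param seed Integer seed (mandatory).
#' @param allow_pseudoinverse Permit raw-mode pseudo-inverse fits.
#' @return An object of class `classification_report`: `accuracy_point`
#'   (cross-validated accuracy of the full sample), `boot_accuracies`,
#'   `chance`, `p_at_or_below_chance`, `significant`, `n_components`,
#'   `per_class_accuracy` (mean per-class out-of-fold accuracy across
#'   iterations), `n_retries`, `retry_warning`, `pseudo_inverse`, `rank`.
#' @export
bootstrap_accuracy <- function(X, y, n_iter = 1000, k_folds = NULL,
                               gamma = 0.5, delta = 0, seed,
                               allow_pseudoinverse = FALSE) {
  if (missing(seed) || is.null(seed)) stop("configuration error: seed is mandatory")
  if (n_iter < 100) stop("invalid-input error: n_iter must be >= 100")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2L) stop("degenerate-class error: need at least 2 classes")
  nk <- tabulate(y)
  if (any(nk < 2L)) stop("degenerate-class error: every class needs >= 2 members")
  full_fit <- fit_lda(X, y, gamma = gamma, delta = delta,
                      allow_pseudoinverse = allow_pseudoinverse)
  acc_point <- 1 - kfold_loss(X, y, k = k_folds, gamma = gamma, delta = delta,
                              allow_pseudoinverse = allow_pseudoinverse)
  chance <- 1 / K
  set.seed(as.integer(seed))
  class_idx <- split(seq_along(y), y)
  acc <- numeric(n_iter)
  pc_sum <- stats::setNames(numeric(K), levels(y))
  pc_n <- stats::setNames(numeric(K), levels(y))
  n_retries <- 0L
  for (it in seq_len(n_iter)) {
    ok <- FALSE
    for (attempt in 1:25) {
      idx <- unlist(lapply(class_idx, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      # copies of one animal share a CV fold (groups = origin index), so a
      # duplicated animal never appears on both sides of a split
      pred <- tryCatch(
        kfold_predict(X[idx, , drop = FALSE], y[idx], k = k_folds,
                      gamma = gamma, delta = delta,
                      allow_pseudoinverse = allow_pseudoinverse,
                      groups = idx),
        error = function(e) NULL)
      if (!is.null(pred)) { ok <- TRUE; break }
      n_retries <- n_retries + 1L
    }
    if (!ok) stop("bootstrap iteration ", it, " failed after 25 retries")
    yb <- y[idx]
    acc[it] <- mean(pred == yb)
    hit <- tapply(pred == yb, yb, mean)
    present <- !is.na(hit)
    pc_sum[names(hit)[present]] <- pc_sum[names(hit)[present]] + hit[present]
    pc_n[names(hit)[present]] <- pc_n[names(hit)[present]] + 1
  }
  p_chance <- if (K == 2L) mean(acc <= 0.5) else mean(acc < chance)
  structure(list(
    accuracy_point = acc_point,
    boot_accuracies = acc,
    chance = chance,
    p_at_or_below_chance = p_chance,
    significant = p_chance < 0.01,
    n_components = full_fit$n_components,
    gamma = gamma, delta = delta,
    per_class_accuracy = pc_sum / pmax(pc_n, 1),
    n_retries = n_retries,
    retry_warning = n_retries > 0.01 * n_iter,
    pseudo_inverse = full_fit$pseudo_inverse,
    rank = full_fit$rank,
    n = nrow(X)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n = %d, chance = %.3g\n", x$n, x$chance))
  cat(sprintf("  point accuracy %.3f | bootstrap mean %.3f (sd %.3f, %d iters)\n",
              x$accuracy_point, mean(x$boot_accuracies), stats::sd(x$boot_accuracies),
              length(x$boot_accuracies)))
  cat(sprintf("  P(accuracy %s chance) = %.4f -> %s at the 1%% criterion\n",
              if (x$chance == 0.5) "<=" else "<", x$p_at_or_below_chance,
              if (x$significant) "significant" else "not significant"))
  cat(sprintf("  components retained: %d (gamma %.3g, delta %.4g)%s\n",
              x$n_components, x$gamma, x$delta,
              if (isTRUE(x$pseudo_inverse)) sprintf(" [raw mode, pseudo-inverse rank %d]", x$rank) else ""))
  if (x$retry_warning)
    cat(sprintf("  WARNING: unstable resampling, %d retries\n", x$n_retries))
  invisible(x)
}

# Quantile summary used when serializing reports to JSON.
.report_summary <- function(r, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  list(
    accuracy_point = r$accuracy_point,
    boot_mean = mean(r$boot_accuracies),
    boot_sd = stats::sd(r$boot_accuracies),
    boot_quantiles = as.list(stats::setNames(
      stats::quantile(r$boot_accuracies, probs), paste0("q", probs * 100))),
    chance = r$chance,
    p_at_or_below_chance = r$p_at_or_below_chance,
    significant = r$significant,
    n_components = r$n_components,
    gamma = r$gamma, delta = r$delta,
    per_class_accuracy = as.list(r$per_class_accuracy),
    n_retries = r$n_retries,
    pseudo_inverse = r$pseudo_inverse,
    rank = r$rank
  )
}
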