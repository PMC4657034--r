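# Internal fitting core shared by the public fitting and cross-validation
# functions. Performs no input coercion; X must be a numeric matrix and y a
# factor with >= 2 levels present.
.lda_core <- function(X, y, gamma = 0, delta = 0, allow_pseudoinverse = FALSE,
                      priors = NULL) {
  n <- nrow(X); p <- ncol(X)
  nk <- tabulate(y, nbins = nlevels(y))
  if (any(nk < 2L))
    stop("degenerate-class error: class(es) ",
         paste(levels(y)[nk < 2L], collapse = ", "),
         " have fewer than 2 members")
  K <- nlevels(y)
  M <- rowsum(X, y) / nk                       # K x p class means
  Xc <- X - M[as.integer(y), , drop = FALSE]
  Sigma <- crossprod(Xc) / (n - K)             # pooled within-class covariance
  d <- diag(Sigma)
  Sg <- (1 - gamma) * Sigma
  diag(Sg) <- diag(Sg) + gamma * d
  inv <- .safe_inverse(Sg, allow_pseudoinverse)
  mu_bar <- colMeans(M)
  C <- inv$inv %*% t(M - matrix(mu_bar, K, p, byrow = TRUE))  # p x K
  cmax <- apply(abs(C), 1L, max)
  mask <- cmax > delta
  if (!any(mask))
    stop("empty-model error: delta = ", format(delta),
         " eliminates every feature; lower delta")
  if (is.null(priors)) priors <- nk / n
  Ms <- M[, mask, drop = FALSE]
  inv_s <- if (all(mask)) inv else .safe_inverse(Sg[mask, mask, drop = FALSE],
                                                 allow_pseudoinverse)
  W <- inv_s$inv %*% t(Ms)                     # p_s x K
  const <- -0.5 * colSums(t(Ms) * W) + log(priors)
  list(labels = levels(y), means = M, pooled_cov = Sg, gamma = gamma,
       delta = delta, retained_mask = mask, n_components = sum(mask),
       priors = priors, coef = C, W = W, const = const,
       pseudo_inverse = inv_s$pseudo, rank = inv_s$rank)
}

.safe_inverse <- function(S, allow_pseudoinverse) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  # guard against a numerically successful factorization of an effectively
  # singular matrix (tiny trailing pivots)
  if (!is.null(ch) && min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch)))
    ch <- NULL
  if (!is.null(ch))
    return(list(inv = chol2inv(ch), pseudo = FALSE, rank = ncol(S)))
  if (!allow_pseudoinverse)
    stop("singularity error: regularized covariance is singular (n < p or ",
         "duplicated rows); increase gamma, or set allow_pseudoinverse = TRUE ",
         "to fall back to a Moore-Penrose pseudo-inverse with rank logging")
  sv <- svd(S)
  tol <- max(dim(S)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  inv <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  list(inv = inv, pseudo = TRUE, rank = sum(pos))
}

#' Fit a shrinkage-regularized linear discriminant classifier
#'
#' Computes per-class means and the pooled within-class covariance
#' (denominator n - K), shrinks the covariance toward its diagonal,
#' `Sigma_gamma = (1 - gamma) * Sigma + gamma * diag(Sigma)`, and eliminates
#' weak predictors: feature j is dropped when the largest absolute linear
#' coefficient `|C_kj|`, with `C_k = Sigma_gamma^-1 (mu_k - mu_bar)`, does not
#' exceed `delta`. The surviving features form the model; their count is the
#' "number of components" quoted in reports. Discriminant scores are the
#' usual Gaussian-equal-covariance linear scores with class priors.
#'
#' With `gamma = 0` and fewer samples than features the pooled covariance is
#' singular; by default this is an error. `allow_pseudoinverse = TRUE`
#' reproduces the raw (unregularized) analysis mode with a Moore-Penrose
#' pseudo-inverse; the rank actually used is stored on the model and flagged
#' in downstream reports.
#'
#' @param X Numeric matrix or data frame of features (rows = animals).
#' @param y Class labels (coerced to factor; >= 2 classes of >= 2 members).
#' @param gamma Covariance shrinkage weight in `[0, 1]`.
#' @param delta Coefficient-elimination threshold, >= 0.
#' @param allow_pseudoinverse Permit a pseudo-inverse for singular
#'   covariances (raw analysis mode).
#' @param priors Optional class priors (default: empirical frequencies).
#' @return An object of class `ssvep_lda`.
#' @export
fit_lda <- function(X, y, gamma = 0, delta = 0, allow_pseudoinverse = FALSE,
                    priors = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("invalid-input error: X contains non-finite values")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("degenerate-class error: need at least 2 classes")
  if (length(y) != nrow(X)) stop("invalid-input error: length(y) != nrow(X)")
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("invalid-input error: gamma must lie in [0, 1]")
  if (!is.numeric(delta) || delta < 0)
    stop("invalid-input error: delta must be >= 0")
  if (!is.null(priors)) {
    if (length(priors) != nlevels(y) || abs(sum(priors) - 1) > 1e-8)
      stop("invalid-input error: priors must sum to 1, one per class")
  }
  fit <- .lda_core(X, y, gamma, delta, allow_pseudoinverse, priors)
  fit$feature_names <- colnames(X)
  class(fit) <- "ssvep_lda"
  fit
}

#' @export
print.ssvep_lda <- function(x, ...) {
  cat(sprintf("<ssvep_lda> %d classes, %d/%d components retained (gamma %.3g, delta %.4g)%s\n",
              length(x$labels), x$n_components, length(x$retained_mask),
              x$gamma, x$delta,
              if (x$pseudo_inverse) sprintf(" [pseudo-inverse, rank %d]", x$rank) else ""))
  invisible(x)
}

#' Predict class labels
#'
#' Assigns each observation to the class with the highest discriminant score;
#' exact ties break deterministically toward the first class in label order.
#'
#' @param object An `ssvep_lda` model.
#' @param newdata Numeric vector (one observation) or matrix/data frame.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.ssvep_lda <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("invalid-input error: non-finite feature value")
  if (ncol(X) != length(object$retained_mask))
    stop("invalid-input error: expected ", length(object$retained_mask), " features")
  S <- X[, object$retained_mask, drop = FALSE] %*% object$W
  S <- sweep(S, 2L, object$const, `+`)
  factor(object$labels[max.col(S, ties.method = "first")], levels = object$labels)
}

# Fast leave-one-out predictions: the pooled scatter and the left-out
# animal's class mean are down-dated by rank-one updates instead of refitting
# from scratch. Algebraically identical to the generic per-fold refit; folds
# whose down-dated covariance is not numerically positive definite fall back
# to the generic fitter.
.loo_predict_fast <- function(X, y, gamma, delta, priors = NULL) {
  n <- nrow(X); p <- ncol(X); K <- nlevels(y)
  nk <- tabulate(y, nbins = K)
  if (any(nk < 2L))
    stop("degenerate-class error: class(es) ",
         paste(levels(y)[nk < 2L], collapse = ", "), " have fewer than 2 members")
  M <- rowsum(X, y) / nk
  Xc <- X - M[as.integer(y), , drop = FALSE]
  S <- crossprod(Xc)
  denom <- n - 1L - K
  pred <- integer(n)
  for (i in seq_len(n)) {
    k <- as.integer(y[i])
    if (nk[k] - 1L < 2L)
      stop("fold ", i, " failed: degenerate-class error: class ", levels(y)[k],
           " would have fewer than 2 members")
    dx <- X[i, ] - M[k, ]
    Si <- S - (nk[k] / (nk[k] - 1)) * tcrossprod(dx)
    Mi <- M
    Mi[k, ] <- (nk[k] * M[k, ] - X[i, ]) / (nk[k] - 1)
    Sigma <- Si / denom
    d <- diag(Sigma)
    Sg <- (1 - gamma) * Sigma
    diag(Sg) <- diag(Sg) + gamma * d
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (!is.null(ch) && min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch)))
      ch <- NULL
    if (is.null(ch)) {
      # rare numerical fallback: full refit of this fold
      fit <- tryCatch(
        .lda_core(X[-i, , drop = FALSE], droplevels(y[-i]), gamma, delta,
                  FALSE, priors),
        error = function(e) stop("fold ", i, " failed: ", conditionMessage(e),
                                 call. = FALSE))
      sc <- X[i, fit$retained_mask, drop = FALSE] %*% fit$W
      pred[i] <- match(fit$labels[which.max(sc + fit$const)], levels(y))
      next
    }
    inv <- chol2inv(ch)
    mu_bar <- colMeans(Mi)
    C <- inv %*% t(Mi - matrix(mu_bar, K, p, byrow = TRUE))
    mask <- apply(abs(C), 1L, max) > delta
    if (!any(mask))
      stop("fold ", i, " failed: empty-model error: delta eliminates every feature")
    pk <- if (is.null(priors)) {
      nn <- nk; nn[k] <- nn[k] - 1L; nn / (n - 1L)
    } else priors
    Ms <- Mi[, mask, drop = FALSE]
    inv_s <- if (all(mask)) inv else chol2inv(chol(Sg[mask, mask, drop = FALSE]))
    W <- inv_s %*% t(Ms)
    sc <- X[i, mask, drop = FALSE] %*% W - 0.5 * colSums(t(Ms) * W) + log(pk)
    pred[i] <- which.max(sc)
  }
  factor(levels(y)[pred], levels = levels(y))
}

# Deterministic stratified fold assignment: within each class (row order),
# folds cycle 1..k; k >= the number of groups gives leave-one-group-out.
# `groups` ties rows that are resampled copies of the same animal into the
# same fold, so a bootstrap duplicate can never sit in both the training and
# the test side of a split.
.make_folds <- function(y, k, groups = NULL) {
  n <- length(y)
  if (is.null(groups)) groups <- seq_len(n)
  ug <- unique(groups)
  gy <- y[match(ug, groups)]
  gfold <- integer(length(ug))
  if (k >= length(ug)) {
    gfold <- seq_along(ug)
  } else {
    for (lv in levels(y)) {
      ix <- which(gy == lv)
      gfold[ix] <- ((seq_along(ix) - 1L) %% k) + 1L
    }
  }
  gfold[match(groups, ug)]
}

#' Cross-validated predictions and loss
#'
#' `kfold_predict()` refits the classifier with each stratified fold held out
#' and predicts the held-out animals; `kfold_loss()` is the resulting
#' misclassification fraction and `loo_accuracy()` the leave-one-out accuracy
#' (`k = n`).
#'
#' When `priors` is `NULL` the class priors are estimated once from the full
#' sample and held fixed across folds; re-estimating priors inside each
#' training fold would bias cross-validated accuracy away from chance under
#' label permutation (leaving out one animal tilts the fold's class
#' frequencies against its own class).
#'
#' @param X,y Features and labels as in [fit_lda()].
#' @param k Number of folds; `k >= n` (or `NULL`) gives leave-one-out.
#' @param gamma,delta,allow_pseudoinverse,priors Passed to the fitter.
#' @param groups Optional integer vector tying rows to their animal of
#'   origin: rows sharing a group always share a fold, so bootstrap copies
#'   of one animal never straddle a train/test split. Default: every row its
#'   own group.
#' @return `kfold_predict()`: factor of out-of-fold predictions;
#'   `kfold_loss()`: loss in `[0, 1]`; `loo_accuracy()`: accuracy in `[0, 1]`.
#' @export
kfold_predict <- function(X, y, k = NULL, gamma = 0, delta = 0,
                          allow_pseudoinverse = FALSE, priors = NULL,
                          groups = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("invalid-input error: X contains non-finite values")
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  if (n < 3L) stop("insufficient-data: need n >= 3")
  if (is.null(k)) k <- n
  if (k < 2L) stop("invalid-input error: k must be >= 2")
  if (is.null(priors)) priors <- as.vector(table(y)) / n
  if (k >= n && !allow_pseudoinverse &&
      (is.null(groups) || !anyDuplicated(groups)))
    return(.loo_predict_fast(X, y, gamma, delta, priors))
  fold <- .make_folds(y, k, groups)
  pred <- factor(rep(levels(y)[1], n), levels = levels(y))
  for (f in unique(fold)) {
    test <- fold == f
    fit <- tryCatch(
      .lda_core(X[!test, , drop = FALSE], droplevels(y[!test]), gamma, delta,
                allow_pseudoinverse, priors),
      error = function(e) stop("fold ", f, " failed: ", conditionMessage(e),
                               call. = FALSE))
    S <- X[test, fit$retained_mask, drop = FALSE] %*% fit$W
    S <- sweep(S, 2L, fit$const, `+`)
    pred[test] <- factor(fit$labels[max.col(S, ties.method = "first")],
                         levels = levels(y))
  }
  pred
}

#' @rdname kfold_predict
#' @export
kfold_loss <- function(X, y, k = NULL, gamma = 0, delta = 0,
                       allow_pseudoinverse = FALSE, priors = NULL,
                       groups = NULL) {
  y <- droplevels(as.factor(y))
  mean(kfold_predict(X, y, k, gamma, delta, allow_pseudoinverse, priors,
                     groups) != y)
}

#' @rdname kfold_predict
#' @export
loo_accuracy <- function(X, y, gamma = 0, delta = 0,
                         allow_pseudoinverse = FALSE, priors = NULL) {
  1 - kfold_loss(X, y, k = NULL, gamma = gamma, delta = delta,
                 allow_pseudoinverse = allow_pseudoinverse, priors = priors)
}

#' Joint search over shrinkage and elimination strength
#'
#' For every `gamma` in the grid the candidate elimination thresholds are
#' `n_delta` quantiles (from 0 up to the maximum) of the per-feature largest
#' absolute linear coefficients of the full-data fit at that `gamma`. Each
#' `(gamma, delta)` pair is scored by stratified k-fold misclassification
#' loss; the minimizer is returned, with ties broken toward fewer retained
#' components and then toward larger `gamma` (stronger smoothing).
#'
#' @param X,y Features and labels.
#' @param gamma_grid Numeric vector of shrinkage weights in `[0, 1]`.
#' @param n_delta Number of candidate thresholds per gamma.
#' @param k_folds Folds for the internal cross-validation (default 10).
#' @return List with `gamma`, `delta`, `n_components`, `cv_loss` and `grid`
#'   (a data frame of every candidate evaluated).
#' @export
optimize_regularization <- function(X, y, gamma_grid = seq(0, 1, by = 0.1),
                                    n_delta = 10, k_folds = 10) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(y))
  if (length(gamma_grid) < 1L || n_delta < 1L)
    stop("invalid-input error: empty search grid")
  if (k_folds < 2L) stop("invalid-input error: k_folds must be >= 2")
  res <- list()
  for (g in gamma_grid) {
    full <- tryCatch(.lda_core(X, y, gamma = g, delta = 0), error = function(e) NULL)
    if (is.null(full)) next
    cmax <- apply(abs(full$coef), 1L, max)
    deltas <- unname(stats::quantile(cmax, probs = seq(0, 1, length.out = n_delta)))
    deltas[1] <- 0
    for (dl in unique(deltas)) {
      ncomp <- sum(cmax > dl)
      if (ncomp == 0L) next   # would empty the full model; never a candidate
      loss <- tryCatch(kfold_loss(X, y, k = k_folds, gamma = g, delta = dl),
                       error = function(e) NA_real_)
      res[[length(res) + 1L]] <- data.frame(gamma = g, delta = dl,
                                            n_components = ncomp, cv_loss = loss)
    }
  }
  if (length(res) == 0L)
    stop("optimization-failure error: no (gamma, delta) candidate could be fitted")
  grid <- do.call(rbind, res)
  ok <- grid[is.finite(grid$cv_loss), , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("optimization-failure error: every (gamma, delta) candidate failed")
  ord <- order(ok$cv_loss, ok$n_components, -ok$gamma)
  best <- ok[ord[1L], ]
  list(gamma = best$gamma, delta = best$delta,
       n_components = best$n_components, cv_loss = best$cv_loss, grid = grid)
}
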