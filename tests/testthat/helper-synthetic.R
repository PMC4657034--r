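# Shared fixtures: everything is generated in code under fixed seeds.

# a quiet, deterministic line for exact-recovery checks
noiseless_spec <- function(name = "nl", gain = 10, ...) {
  genotype_spec(name, gain = gain, fly_cv = 0, noise_amp = 0, ...)
}

# clone a preset under a new name (identical physiology, distinct label)
respec <- function(spec, name, ...) {
  fields <- unclass(spec)
  fields$name <- NULL
  dots <- list(...)
  fields[names(dots)] <- dots
  do.call(genotype_spec, c(list(name = name), fields))
}

# small Gaussian feature-table generator for classifier tests:
# two classes, `shift` added to the first `n_inf` features of class b
gauss_features <- function(n_per = 20, p = 64, shift = 2, n_inf = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  X[(n_per + 1):(2 * n_per), seq_len(n_inf)] <-
    X[(n_per + 1):(2 * n_per), seq_len(n_inf)] + shift
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = factor(rep(c("a", "b"), each = n_per)))
}

# generic per-fold leave-one-out refit, used as the independent route when
# checking the rank-one-downdate fast path
refit_loo <- function(X, y, gamma, delta) {
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  pri <- as.vector(table(y)) / n   # cross-validation holds priors fixed
  pred <- factor(rep(levels(y)[1], n), levels = levels(y))
  for (i in seq_len(n)) {
    fit <- fit_lda(X[-i, , drop = FALSE], droplevels(y[-i]), gamma, delta,
                   priors = pri)
    pred[i] <- predict(fit, X[i, ])
  }
  pred
}
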