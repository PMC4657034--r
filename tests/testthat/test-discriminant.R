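test_that("the linear rule recovers the mid-hyperplane geometry", {
  set.seed(1)
  n <- 200; p <- 6
  X <- matrix(rnorm(n * p), n)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X[y == "b", 1] <- X[y == "b", 1] + 2
  fit <- fit_lda(X, y, gamma = 0, delta = 0)
  expect_equal(fit$n_components, p)
  # class means themselves are classified to their own class
  expect_equal(as.character(predict(fit, fit$means["a", ])), "a")
  expect_equal(as.character(predict(fit, fit$means["b", ])), "b")
  # a point clearly on class a's side of the midpoint
  x <- fit$means["a", ]; x[1] <- x[1] + 0.45 * (fit$means["b", 1] - fit$means["a", 1])
  expect_equal(as.character(predict(fit, x)), "a")
})

test_that("exact score ties break toward the first label", {
  X <- rbind(c(0, 1), c(0, -1), c(0.2, 0), c(-0.2, 0),
             c(2, 1), c(2, -1), c(2.2, 0), c(1.8, 0))
  y <- factor(rep(c("a", "b"), each = 4))
  fit <- fit_lda(X, y, 0, 0)
  expect_equal(as.character(predict(fit, c(1, 0))), "a")
})

test_that("delta elimination never silently empties the model", {
  d <- gauss_features(n_per = 15, p = 8, shift = 3, n_inf = 2, seed = 3)
  fit0 <- fit_lda(d$X, d$y, gamma = 0.5, delta = 0)
  big <- max(abs(fit0$coef)) * 1.01
  expect_error(fit_lda(d$X, d$y, gamma = 0.5, delta = big), "eliminates every feature")
  fit <- fit_lda(d$X, d$y, gamma = 0.5, delta = max(abs(fit0$coef)) * 0.5)
  expect_gte(fit$n_components, 1)
  expect_lt(fit$n_components, 8)
})

test_that("an unregularized fit with n < p is singular unless a pseudo-inverse is allowed", {
  set.seed(2)
  X <- matrix(rnorm(40 * 64), 40)
  y <- factor(rep(c("a", "b"), 20))
  expect_error(fit_lda(X, y, gamma = 0, delta = 0), "singularity")
  fit <- fit_lda(X, y, 0, 0, allow_pseudoinverse = TRUE)
  expect_true(fit$pseudo_inverse)
  expect_lte(fit$rank, 38)
})

test_that("input contracts: finite features, valid classes", {
  d <- gauss_features(n_per = 5, p = 4, n_inf = 2, seed = 4)
  fit <- fit_lda(d$X, d$y, 0.5, 0)
  expect_error(predict(fit, c(1, NA, 0, 2)), "non-finite")
  expect_error(fit_lda(d$X, rep("a", 10), 0.5, 0), "2 classes")
  expect_error(fit_lda(d$X, c("b", rep("a", 9)), 0.5, 0), "degenerate-class")
  expect_error(fit_lda(d$X, d$y, gamma = 2, delta = 0), "gamma")
})

test_that("leave-one-out is exact on separated clusters and errors on n = 3", {
  d <- gauss_features(n_per = 10, p = 5, shift = 8, n_inf = 5, seed = 5)
  expect_equal(loo_accuracy(d$X, d$y, gamma = 0.2, delta = 0), 1.0)
  X3 <- matrix(rnorm(9), 3)
  y3 <- factor(c("a", "a", "b"))
  expect_error(kfold_predict(X3, y3, NULL, 0.5, 0), "degenerate-class|fewer than 2")
})

test_that("the rank-one-downdate LOO path agrees with per-fold refitting", {
  set.seed(6)
  for (r in 1:8) {
    n <- sample(15:30, 1); p <- sample(3:8, 1); K <- sample(2:3, 1)
    y <- factor(sample(letters[1:K], n, TRUE))
    while (any(table(y) < 3)) y <- factor(sample(letters[1:K], n, TRUE))
    X <- matrix(rnorm(n * p), n)
    X[, 1] <- X[, 1] + as.integer(y)
    g <- runif(1, 0.05, 1)
    # threshold kept low enough that no fold loses every feature
    dl <- unname(quantile(abs(fit_lda(X, y, g, 0)$coef), runif(1, 0, 0.3)))
    expect_identical(kfold_predict(X, y, NULL, g, dl), refit_loo(X, y, g, dl))
  }
})

test_that("permuted labels on separable data classify at chance", {
  d <- gauss_features(n_per = 10, p = 5, shift = 4, n_inf = 5, seed = 8)
  set.seed(9)
  acc <- replicate(300, {
    yp <- sample(d$y)
    loo_accuracy(d$X, yp, gamma = 0.5, delta = 0)
  })
  expect_equal(mean(acc), 0.5, tolerance = 0.05)
})

test_that("a fully shrunk covariance gives the independent-feature rule", {
  d <- gauss_features(n_per = 12, p = 5, shift = 2, n_inf = 2, seed = 10)
  fit <- fit_lda(d$X, d$y, gamma = 1, delta = 0)
  # closed form with diagonal pooled covariance
  nk <- table(d$y)
  M <- rowsum(d$X, d$y) / as.vector(nk)
  Xc <- d$X - M[as.integer(d$y), ]
  v <- colSums(Xc^2) / (nrow(d$X) - 2)
  score <- function(x, k) sum(x * M[k, ] / v) - 0.5 * sum(M[k, ]^2 / v) + log(nk[k] / sum(nk))
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(5)
    ref <- c("a", "b")[which.max(c(score(x, 1), score(x, 2)))]
    expect_equal(as.character(predict(fit, x)), ref)
  }
})

test_that("regularization search scans quantile thresholds and respects ties", {
  d <- gauss_features(n_per = 20, p = 16, shift = 2.5, n_inf = 3, seed = 12)
  opt <- optimize_regularization(d$X, d$y, gamma_grid = c(0.2, 0.6, 1),
                                 n_delta = 6, k_folds = 5)
  expect_true(opt$gamma %in% c(0.2, 0.6, 1))
  expect_gte(opt$n_components, 1)
  expect_lte(opt$n_components, 16)
  expect_true(all(opt$grid$cv_loss >= 0 & opt$grid$cv_loss <= 1, na.rm = TRUE))
  # informative features survive the selected threshold
  fit <- fit_lda(d$X, d$y, opt$gamma, opt$delta)
  expect_true(all(fit$retained_mask[1:3]))
  expect_error(optimize_regularization(d$X, d$y, gamma_grid = numeric(0)),
               "empty")
})

test_that("bootstrap reports are internally consistent", {
  d <- gauss_features(n_per = 12, p = 6, shift = 3, n_inf = 3, seed = 13)
  r <- bootstrap_accuracy(d$X, d$y, n_iter = 200, k_folds = 6, gamma = 0.5,
                          delta = 0, seed = 14)
  expect_true(all(r$boot_accuracies >= 0 & r$boot_accuracies <= 1))
  expect_equal(r$chance, 0.5)
  expect_identical(r$significant, r$p_at_or_below_chance < 0.01)
  expect_true(r$significant)
  expect_gt(mean(r$boot_accuracies), 0.9)
  expect_error(bootstrap_accuracy(d$X, d$y, n_iter = 50, gamma = 0.5,
                                  delta = 0, seed = 1), "n_iter")
  expect_error(bootstrap_accuracy(d$X, d$y, n_iter = 200, gamma = 0.5,
                                  delta = 0), "seed")
})

test_that("the significance flag has controlled type-I error under the null", {
  set.seed(15)
  flags <- logical(40)
  for (i in 1:40) {
    X <- matrix(rnorm(40 * 5), 40)
    y <- factor(rep(c("a", "b"), each = 20))
    r <- bootstrap_accuracy(X, y, n_iter = 100, k_folds = 10, gamma = 0.3,
                            delta = 0, seed = 1000 + i)
    flags[i] <- r$significant
  }
  expect_lte(mean(flags), 0.05)
})

test_that("retained component count stays within 1..64 across the search", {
  d <- gauss_features(n_per = 20, p = 64, shift = 2, n_inf = 5, seed = 16)
  opt <- optimize_regularization(d$X, d$y, gamma_grid = c(0.3, 0.7),
                                 n_delta = 8, k_folds = 5)
  expect_gte(opt$n_components, 1)
  expect_lte(opt$n_components, 64)
  expect_true(all(opt$grid$n_components >= 0 & opt$grid$n_components <= 64))
})
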