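#' Pairwise two-way classification matrix
#'
#' Runs the two-class discriminant analysis for every unordered pair of
#' genotypes. In regularized mode the shrinkage parameters are re-optimized
#' for each pair before bootstrapping; raw mode uses the unprocessed
#' amplitudes with `gamma = delta = 0` and a pseudo-inverse (flagged in the
#' output, since with 20 + 20 animals and 64 features the pooled covariance
#' is rank-deficient). Failures in one pair are reported in its row without
#' aborting the others.
#'
#' @param features Feature table: data frame with 64 amplitude columns (a
#'   `feature_matrix()` output, with or without the `fly_id` column).
#' @param labels Genotype labels, one per row.
#' @param regularized Optimize `(gamma, delta)` per pair (default TRUE).
#' @param n_iter Bootstrap iterations per pair.
#' @param k_folds Folds for bootstrap loss; `NULL` = leave-one-out.
#' @param cv_folds Folds inside the regularization search.
#' @param gamma_grid,n_delta Search grid, see [optimize_regularization()].
#' @param seed Integer seed.
#' @return Object of class `pairwise_matrix`: `table` (one row per pair with
#'   raw and regularized accuracies, bootstrap mean, significance flag and
#'   retained component count) and `reports` (named list of
#'   `classification_report`s, upper triangle only).
#' @export
pairwise_matrix <- function(features, labels, regularized = TRUE,
                            n_iter = 1000, k_folds = NULL, cv_folds = 10,
                            gamma_grid = seq(0, 1, by = 0.1), n_delta = 10,
                            seed) {
  if (missing(seed) || is.null(seed)) stop("configuration error: seed is mandatory")
  X <- .feature_block(features)
  labels <- droplevels(as.factor(labels))
  lv <- levels(labels)
  if (length(lv) < 2L) stop("degenerate-class error: need >= 2 genotypes")
  pairs <- utils::combn(lv, 2L)
  set.seed(as.integer(seed))
  pair_seeds <- sample.int(.Machine$integer.max - 1L, ncol(pairs))
  rows <- vector("list", ncol(pairs))
  reports <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sel <- labels %in% c(a, b)
    Xp <- X[sel, , drop = FALSE]
    yp <- droplevels(labels[sel])
    row <- data.frame(class_a = a, class_b = b, acc_raw = NA_real_,
                      raw_rank = NA_integer_, gamma = NA_real_, delta = NA_real_,
                      n_components = NA_integer_, boot_mean = NA_real_,
                      p_at_or_below_chance = NA_real_, significant = NA,
                      error = NA_character_)
    res <- tryCatch({
      row$acc_raw <- loo_accuracy(Xp, yp, gamma = 0, delta = 0,
                                  allow_pseudoinverse = TRUE)
      row$raw_rank <- fit_lda(Xp, yp, 0, 0, allow_pseudoinverse = TRUE)$rank
      if (regularized) {
        opt <- optimize_regularization(Xp, yp, gamma_grid = gamma_grid,
                                       n_delta = n_delta, k_folds = cv_folds)
        gm <- opt$gamma; dl <- opt$delta
      } else { gm <- 0; dl <- 0 }
      rep <- bootstrap_accuracy(Xp, yp, n_iter = n_iter, k_folds = k_folds,
                                gamma = gm, delta = dl, seed = pair_seeds[j],
                                allow_pseudoinverse = !regularized)
      row$gamma <- gm; row$delta <- dl
      row$n_components <- rep$n_components
      row$boot_mean <- mean(rep$boot_accuracies)
      row$p_at_or_below_chance <- rep$p_at_or_below_chance
      row$significant <- rep$significant
      reports[[paste(a, b, sep = " vs ")]] <- rep
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    rows[[j]] <- res
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, reports = reports, regularized = regularized),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> %d genotype pairs (%s mode)\n",
              nrow(x$table), if (x$regularized) "regularized" else "raw"))
  tab <- x$table
  tab$boot_mean <- round(tab$boot_mean, 3)
  tab$acc_raw <- round(tab$acc_raw, 3)
  print(tab[, c("class_a", "class_b", "acc_raw", "boot_mean", "n_components",
                "significant")])
  invisible(x)
}

#' Pooled two-class (PD vs non-PD) classification
#'
#' Relabels animals by a genotype-to-class map, drops excluded genotypes and
#' runs the regularized pipeline with bootstrap significance at a chance
#' level of 0.5. The default map derived from the bundled presets pools the
#' early- and late-onset parkinsonism lines against the control lines and
#' excludes the general-neurodegeneration line, giving nine genotype classes.
#'
#' @param features Feature table (64 amplitude columns).
#' @param labels Genotype labels.
#' @param class_map Named character vector mapping genotype name to pooled
#'   class (e.g. `c(ctrl_w1118 = "non-PD", pd_DJ1a = "PD", ...)`).
#' @param exclusions Genotypes to drop before pooling.
#' @param regularized Optimize `(gamma, delta)` before bootstrapping.
#' @param n_iter,k_folds,cv_folds,gamma_grid,n_delta,seed As in
#'   [pairwise_matrix()].
#' @return A `classification_report` (chance 0.5).
#' @export
pooled_binary <- function(features, labels, class_map, exclusions = character(),
                          regularized = TRUE, n_iter = 1000, k_folds = NULL,
                          cv_folds = 10, gamma_grid = seq(0, 1, by = 0.1),
                          n_delta = 10, seed) {
  if (missing(seed) || is.null(seed)) stop("configuration error: seed is mandatory")
  X <- .feature_block(features)
  labels <- as.character(labels)
  keep <- !(labels %in% exclusions)
  labels <- labels[keep]
  X <- X[keep, , drop = FALSE]
  unknown <- setdiff(unique(labels), names(class_map))
  if (length(unknown))
    stop("configuration error: no class mapping for genotype(s): ",
         paste(unknown, collapse = ", "))
  pooled <- factor(unname(class_map[labels]))
  if (nlevels(pooled) != 2L)
    stop("configuration error: class_map must yield exactly 2 non-empty pooled classes")
  if (regularized) {
    opt <- optimize_regularization(X, pooled, gamma_grid = gamma_grid,
                                   n_delta = n_delta, k_folds = cv_folds)
    gm <- opt$gamma; dl <- opt$delta
  } else { gm <- 0; dl <- 0 }
  bootstrap_accuracy(X, pooled, n_iter = n_iter, k_folds = k_folds,
                     gamma = gm, delta = dl, seed = seed,
                     allow_pseudoinverse = !regularized)
}

#' Default PD / non-PD pooling for the bundled presets
#'
#' @param specs Named list of `genotype_spec`s (default: bundled presets).
#' @return List with `class_map` (control -> "non-PD", early/late PD -> "PD")
#'   and `exclusions` (neurodegeneration lines).
#' @export
default_class_map <- function(specs = genotype_presets()) {
  cls <- vapply(specs, `[[`, "", "class_label")
  map <- ifelse(cls == "control", "non-PD",
                ifelse(cls %in% c("early_PD", "late_PD"), "PD", NA))
  names(map) <- names(specs)
  list(class_map = map[!is.na(map)],
       exclusions = names(specs)[cls == "neurodegeneration"])
}

#' All-genotype n-way classification
#'
#' Fits the multi-class discriminant once on the entire ensemble (in
#' regularized mode the shrinkage search also runs once on the ensemble) and
#' bootstraps the cross-validated accuracy; chance is 1/K. Per-class
#' bootstrap accuracies summarize which genotypes the classifier finds
#' distinctive.
#'
#' @inheritParams pooled_binary
#' @return A `classification_report` with `per_class_accuracy`.
#' @export
nway_report <- function(features, labels, regularized = TRUE, n_iter = 1000,
                        k_folds = NULL, cv_folds = 10,
                        gamma_grid = seq(0, 1, by = 0.1), n_delta = 10, seed) {
  if (missing(seed) || is.null(seed)) stop("configuration error: seed is mandatory")
  X <- .feature_block(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 3L) stop("degenerate-class error: n-way analysis needs >= 3 classes")
  if (regularized) {
    opt <- optimize_regularization(X, y, gamma_grid = gamma_grid,
                                   n_delta = n_delta, k_folds = cv_folds)
    gm <- opt$gamma; dl <- opt$delta
  } else { gm <- 0; dl <- 0 }
  bootstrap_accuracy(X, y, n_iter = n_iter, k_folds = k_folds, gamma = gm,
                     delta = dl, seed = seed, allow_pseudoinverse = !regularized)
}

# Extract the 64 amplitude columns from a feature table (tolerates the
# fly_id/genotype label columns of feature_matrix()).
.feature_block <- function(features) {
  if (is.matrix(features)) {
    X <- features
  } else {
    keep <- setdiff(names(features), c("fly_id", "genotype"))
    X <- as.matrix(features[, keep, drop = FALSE])
  }
  storage.mode(X) <- "double"
  X
}
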