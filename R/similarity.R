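#' Mean response vector per genotype
#'
#' @param features Feature table (64 amplitude columns, label columns
#'   tolerated) or numeric matrix.
#' @param labels Genotype labels, one per row.
#' @return K x 64 numeric matrix, rownames = genotype, canonical column
#'   order preserved.
#' @export
genotype_means <- function(features, labels) {
  X <- .feature_block(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("labelling error: one label per feature row required")
  if (anyNA(labels)) stop("labelling error: missing genotype label")
  g <- factor(labels, levels = unique(labels))
  rowsum(X, g) / as.vector(table(g))
}

#' Pairwise distances between genotype mean response vectors
#'
#' @param means K x 64 matrix from [genotype_means()].
#' @param metric `"euclidean"` (default) or `"correlation"`
#'   (`1 - Pearson r`).
#' @return Object of class `genotype_dist`: `labels` and the symmetric
#'   zero-diagonal matrix `d`.
#' @export
distance_matrix <- function(means, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  means <- as.matrix(means)
  if (nrow(means) < 2L) stop("invalid-input error: need K >= 2 genotypes")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(means, method = "euclidean"))
  } else {
    sds <- apply(means, 1L, stats::sd)
    if (any(sds == 0))
      stop("undefined-correlation error: constant mean vector for ",
           paste(rownames(means)[sds == 0], collapse = ", "))
    d <- 1 - stats::cor(t(means))
    d[abs(d) < 1e-15] <- 0
    diag(d) <- 0
  }
  labs <- rownames(means)
  if (is.null(labs)) labs <- paste0("g", seq_len(nrow(means)))
  dimnames(d) <- list(labs, labs)
  structure(list(labels = labs, d = d, metric = metric), class = "genotype_dist")
}

#' Two-dimensional embedding of a genotype distance matrix
#'
#' Nonmetric multidimensional scaling (Kruskal stress-1) initialized from the
#' classical (Torgerson) scaling solution and iterated until the relative
#' stress change falls below 1e-6 or 500 iterations elapse. The embedding is
#' defined only up to rotation, reflection and translation, so comparisons
#' between embeddings must follow Procrustes alignment. `K = 2` is handled in
#' closed form (two points at the exact distance).
#'
#' @param D A `genotype_dist` (or symmetric distance matrix).
#' @param dims Embedding dimension (default 2, must be < K).
#' @param maxit,tol Iteration cap and relative stress tolerance.
#' @return Object of class `embedding2d`: `coords` (K x dims, rownames =
#'   genotype), `stress` (Kruskal stress-1, fraction), `converged`.
#' @export
mds_embed <- function(D, dims = 2, maxit = 500, tol = 1e-6) {
  if (inherits(D, "genotype_dist")) { d <- D$d; labs <- D$labels }
  else { d <- as.matrix(D); labs <- rownames(d) }
  K <- nrow(d)
  if (is.null(labs)) labs <- paste0("g", seq_len(K))
  if (dims >= K && K != 2L)
    stop("invalid-input error: dims must be < number of genotypes")
  if (any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0) || any(d < 0))
    stop("invalid-input error: not a valid distance matrix")
  off <- d[upper.tri(d)]
  if (any(off <= 0))
    stop("invalid-input error: nonmetric scaling requires strictly positive ",
         "off-diagonal distances (duplicate genotype means?)")
  if (K == 2L) {
    coords <- matrix(c(-d[1, 2] / 2, 0, d[1, 2] / 2, 0), 2, byrow = TRUE)
    rownames(coords) <- labs
    return(structure(list(coords = coords, stress = 0, converged = TRUE),
                     class = "embedding2d"))
  }
  init <- stats::cmdscale(d, k = dims)
  if (ncol(init) < dims)
    init <- cbind(init, matrix(0, K, dims - ncol(init)))
  fit <- suppressWarnings(MASS::isoMDS(stats::as.dist(d), y = init, k = dims,
                                       maxit = maxit, tol = tol, trace = FALSE))
  if (fit$stress <= 1e-8) {   # exactly embeddable: nothing left to minimize
    coords <- fit$points
    rownames(coords) <- labs
    return(structure(list(coords = coords, stress = fit$stress / 100,
                          converged = TRUE), class = "embedding2d"))
  }
  # convergence check: a short continuation run must not improve the stress
  # by more than the relative tolerance
  cont <- suppressWarnings(MASS::isoMDS(stats::as.dist(d), y = fit$points,
                                        k = dims, maxit = 25, tol = tol,
                                        trace = FALSE))
  # stress is on isoMDS's percent scale; a stress below 0.01% is an
  # essentially perfect embedding regardless of the continuation's progress
  converged <- fit$stress < 0.01 ||
    (fit$stress - cont$stress) <= max(tol * fit$stress, 1e-4)
  if (!converged)
    warning("mds_embed: stress minimization did not converge within ", maxit,
            " iterations (stress ", format(fit$stress / 100, digits = 4), ")")
  coords <- cont$points
  rownames(coords) <- labs
  structure(list(coords = coords, stress = cont$stress / 100,
                 converged = converged),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %d points, stress-1 = %.4g%s\n", nrow(x$coords),
              x$stress, if (x$converged) "" else " (NOT converged)"))
  print(round(x$coords, 4))
  invisible(x)
}

# squared distance from point p to segment a-b
.pt_seg_d2 <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / L2))
  sum((p - (a + t * ab))^2)
}

# is point p inside (or on) the hull of pts (m x 2)? Degenerate hulls
# (points/segments/collinear sets) count containment on the object itself.
.in_hull <- function(p, pts, tol) {
  m <- nrow(pts)
  if (m == 1L) return(sum((p - pts[1, ])^2) <= tol^2)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  # collinear class: chull may still return >= 3 indices of zero-area ring
  area <- 0
  if (nrow(hp) >= 3L) {
    xs <- hp[, 1]; ys <- hp[, 2]
    area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  }
  if (nrow(hp) < 3L || area <= tol^2) {
    d2 <- min(vapply(seq_len(m - 1L), function(i)
      min(vapply(seq(i + 1L, m), function(j)
        .pt_seg_d2(p, pts[i, ], pts[j, ]), 0)), 0))
    return(d2 <= tol^2)
  }
  ring <- rbind(hp, hp[1, , drop = FALSE])
  isTRUE(mgcv::in.out(ring, matrix(p, 1)))
}

#' Convex-hull separation of classes in a 2-D embedding
#'
#' Computes the convex hull of each class's embedded points and reports, for
#' every point, which foreign class hulls contain it. Classes are "separated"
#' when no point lies inside a foreign hull. Degenerate hulls (one point, two
#' points, or collinear sets) are treated as points/segments; containment on
#' the segment counts as inside.
#'
#' @param embedding An `embedding2d` (or K x 2 coordinate matrix with
#'   rownames).
#' @param class_map Named character vector mapping genotype name to class.
#' @return Object of class `hull_separation`: `containment` (data frame:
#'   label, class, comma-separated foreign hulls containing the point),
#'   `separated` (logical), `pair_separated` (class x class logical matrix).
#' @export
hull_separation <- function(embedding, class_map) {
  coords <- if (inherits(embedding, "embedding2d")) embedding$coords else as.matrix(embedding)
  labs <- rownames(coords)
  if (is.null(labs)) stop("invalid-input error: coordinates must carry genotype rownames")
  unknown <- setdiff(labs, names(class_map))
  if (length(unknown))
    stop("labelling error: no class for genotype(s): ", paste(unknown, collapse = ", "))
  cls <- unname(class_map[labs])
  classes <- unique(cls)
  tol <- 1e-9 * max(1, max(abs(coords)))
  inside <- character(length(labs))
  pair_sep <- matrix(TRUE, length(classes), length(classes),
                     dimnames = list(classes, classes))
  for (i in seq_along(labs)) {
    hits <- character(0)
    for (cl in setdiff(classes, cls[i])) {
      pts <- coords[cls == cl, , drop = FALSE]
      if (.in_hull(coords[i, ], pts, tol)) {
        hits <- c(hits, cl)
        pair_sep[cls[i], cl] <- FALSE
        pair_sep[cl, cls[i]] <- FALSE
      }
    }
    inside[i] <- paste(hits, collapse = ",")
  }
  structure(list(
    containment = data.frame(label = labs, class = cls, inside_hulls = inside),
    separated = all(inside == ""),
    pair_separated = pair_sep
  ), class = "hull_separation")
}

#' @export
print.hull_separation <- function(x, ...) {
  cat("<hull_separation>", if (x$separated) "all classes separated"
      else "overlap detected", "\n")
  bad <- x$containment[x$containment$inside_hulls != "", ]
  if (nrow(bad)) print(bad)
  invisible(x)
}
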