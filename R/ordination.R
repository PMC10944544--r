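# Unconstrained and constrained ordination of dissimilarity matrices:
# principal coordinate analysis (classical metric scaling with Gower
# double-centering), post-hoc environmental vector/factor fitting with
# permutation tests, and distance-based redundancy analysis.

#' Principal coordinate analysis
#'
#' Embeds a dissimilarity matrix into orthogonal axes via Gower's
#' double-centered matrix \eqn{G = -\frac12 J D^2 J}, \eqn{J = I - 11'/n},
#' and its symmetric eigendecomposition. Coordinates are eigenvectors
#' scaled by the square roots of positive eigenvalues. Negative
#' eigenvalues (semimetric input) are reported as-is, flagged, and are
#' not corrected; axis proportions are relative to the positive inertia
#' only. Eigenvector signs are fixed so the largest-|loading| element of
#' each axis is positive.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal and
#'   nonnegative entries (e.g. [bray_curtis()])
#' @param n_axes number of axes to return coordinates for (default all
#'   positive axes)
#' @return object of class `pcoa_ordination`: `points` (n x k coordinate
#'   matrix, columns `PCoA1`, ...), `eigenvalues` (all, decreasing),
#'   `proportion` (share of positive inertia per positive axis),
#'   `negative_eigenvalues` flag
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(d < 0)) stop("negative dissimilarities")
  n <- nrow(d)
  G <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  pos <- which(ev > max(ev[1], 0) * 1e-10 & ev > 0)
  k <- if (is.null(n_axes)) length(pos) else min(n_axes, length(pos))
  pts <- matrix(0, n, k,
                dimnames = list(rownames(d),
                                if (k > 0) paste0("PCoA", seq_len(k))))
  for (j in seq_len(k)) {
    v <- eg$vectors[, pos[j]]
    if (v[which.max(abs(v))] < 0) v <- -v   # sign convention
    pts[, j] <- v * sqrt(ev[pos[j]])
  }
  structure(list(points = pts, eigenvalues = ev,
                 proportion = ev[pos] / sum(ev[pos]),
                 negative_eigenvalues = any(ev < -max(ev[1], 0) * 1e-10)),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes (PCoA1 %.1f%%, PCoA2 %.1f%%)%s\n",
              nrow(x$points), ncol(x$points),
              100 * x$proportion[1],
              if (length(x$proportion) > 1) 100 * x$proportion[2] else NA,
              if (x$negative_eigenvalues) "; negative eigenvalues present" else ""))
  invisible(x)
}

# orthonormal basis of the centered first `axes` ordination columns
.axes_basis <- function(ord, axes) {
  A <- ord$points[, seq_len(min(axes, ncol(ord$points))), drop = FALSE]
  qr.Q(qr(scale(A, scale = FALSE)))
}

# squared multiple correlation of each (centered) column of E with the
# span of Q; vectorised over permutation columns
.r2_cols <- function(Q, E) {
  Ec <- scale(E, scale = FALSE)
  colSums(crossprod(Q, Ec)^2) / colSums(Ec^2)
}

#' Fit an environmental vector onto ordination axes
#'
#' Regresses a numeric variable on the first two ordination axes;
#' reports the squared multiple correlation r2, the direction of
#' steepest increase (arrow, scaled to length \eqn{\sqrt{r^2}}), and a
#' permutation p-value from shuffling the variable across samples with
#' the +1 correction, so p is never exactly 0 and its floor is
#' 1/(n_perm + 1).
#'
#' @param ord a [pcoa()] result
#' @param env numeric vector, one value per sample, same order as the
#'   ordination
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed for the permutation stream
#' @param axes number of leading axes fitted (default 2)
#' @return one-row data frame: variable kind, r2, p, arrow coordinates
#' @export
envfit_vector <- function(ord, env, n_perm = 999, seed = 1, axes = 2) {
  stopifnot(inherits(ord, "pcoa_ordination"), length(env) == nrow(ord$points))
  if (!all(is.finite(env))) stop("env must be finite")
  if (stats::sd(env) == 0) {
    return(data.frame(kind = "vector", r2 = NA_real_, p = NA_real_,
                      arrow_x = NA_real_, arrow_y = NA_real_,
                      n_perm = n_perm))
  }
  A <- ord$points[, seq_len(min(axes, ncol(ord$points))), drop = FALSE]
  fit <- stats::lm.fit(cbind(1, A), env)
  r2 <- 1 - sum(fit$residuals^2) / sum((env - mean(env))^2)
  slopes <- fit$coefficients[-1]
  arrow <- if (sum(slopes^2) > 0) slopes / sqrt(sum(slopes^2)) * sqrt(r2) else slopes
  Q <- .axes_basis(ord, axes)
  perm <- with_seed(seed,
                    vapply(seq_len(n_perm), function(i) sample(env), env))
  r2_perm <- .r2_cols(Q, perm)
  p <- (1 + sum(r2_perm >= r2)) / (1 + n_perm)
  data.frame(kind = "vector", r2 = r2, p = p,
             arrow_x = unname(arrow[1]),
             arrow_y = if (length(arrow) > 1) unname(arrow[2]) else NA_real_,
             n_perm = n_perm)
}

#' Fit a categorical factor onto ordination axes
#'
#' Measures how much of the coordinate variance on the first two axes
#' lies between group centroids: \eqn{r^2 = 1 - SS_{within}/SS_{total}}.
#' Significance from permuting group labels (sizes fixed), +1 corrected.
#'
#' @inheritParams envfit_vector
#' @param groups factor or character vector, one label per sample
#' @return one-row data frame: kind, r2, p, plus the group centroids as
#'   an attribute `centroids`
#' @export
envfit_factor <- function(ord, groups, n_perm = 999, seed = 1, axes = 2) {
  stopifnot(inherits(ord, "pcoa_ordination"),
            length(groups) == nrow(ord$points))
  groups <- as.factor(groups)
  A <- ord$points[, seq_len(min(axes, ncol(ord$points))), drop = FALSE]
  ss_within <- function(g) {
    sum(vapply(split(seq_along(g), g), function(idx) {
      sub <- A[idx, , drop = FALSE]
      sum(scale(sub, scale = FALSE)^2)
    }, numeric(1)))
  }
  ss_tot <- sum(scale(A, scale = FALSE)^2)
  r2 <- 1 - ss_within(groups) / ss_tot
  r2_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    1 - ss_within(sample(groups)) / ss_tot, numeric(1)))
  p <- (1 + sum(r2_perm >= r2)) / (1 + n_perm)
  cent <- do.call(rbind, lapply(split(seq_along(groups), groups), function(idx)
    colMeans(A[idx, , drop = FALSE])))
  out <- data.frame(kind = "factor", r2 = r2, p = p,
                    arrow_x = NA_real_, arrow_y = NA_real_, n_perm = n_perm)
  attr(out, "centroids") <- cent
  out
}

#' Fit many environmental variables onto an ordination
#'
#' Applies [envfit_vector()] to numeric columns and [envfit_factor()] to
#' factor/character columns of a data frame, with per-variable seeds
#' derived from one master seed.
#'
#' @inheritParams envfit_vector
#' @param env_data data frame of per-sample variables
#' @return data frame, one row per variable
#' @export
envfit_all <- function(ord, env_data, n_perm = 999, seed = 1, axes = 2) {
  seeds <- derive_seeds(seed, ncol(env_data))
  rows <- lapply(seq_along(env_data), function(j) {
    v <- env_data[[j]]
    row <- if (is.numeric(v))
      envfit_vector(ord, v, n_perm = n_perm, seed = seeds[j], axes = axes)
    else
      envfit_factor(ord, v, n_perm = n_perm, seed = seeds[j], axes = axes)
    cbind(variable = names(env_data)[j], row)
  })
  do.call(rbind, rows)
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination of a dissimilarity matrix: the PCoA site
#' scores on all positive-eigenvalue axes are projected onto the column
#' space of the (centered) predictor matrix. Numeric predictors are
#' standardized to zero mean and unit variance so their effect sizes are
#' directly comparable; categorical predictors are dummy-coded. The
#' proportion explained is constrained inertia over total positive
#' inertia; negative eigenvalues are excluded from the denominator and
#' reported.
#'
#' @param d dissimilarity matrix
#' @param predictors data frame of per-sample predictors (complete
#'   cases required)
#' @param standardize standardize numeric predictors (default TRUE)
#' @return list: `constrained_inertia`, `total_inertia` (positive),
#'   `proportion`, `eigenvalues_negative_sum`, `biplot` (correlations of
#'   predictors with the first two constrained axes), `aliased` (names
#'   of dropped collinear columns)
#' @export
dbrda <- function(d, predictors, standardize = TRUE) {
  stopifnot(is.data.frame(predictors), nrow(as.matrix(d)) == nrow(predictors))
  if (anyNA(predictors)) stop("predictors must be complete-case")
  ord <- pcoa(d)
  Y <- ord$points                       # already scaled by sqrt(lambda)
  X <- stats::model.matrix(~ ., data = predictors)[, -1, drop = FALSE]
  if (standardize) {
    num <- apply(X, 2, function(col) length(unique(col)) > 2)
    X[, num] <- scale(X[, num, drop = FALSE])
  }
  X <- scale(X, scale = FALSE)
  qrx <- qr(X)
  aliased <- character(0)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[-qrx$pivot[seq_len(qrx$rank)]]
    warning(sprintf("dropping aliased predictor column(s): %s",
                    paste(aliased, collapse = ", ")), call. = FALSE)
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    qrx <- qr(X)
  }
  Qx <- qr.Q(qrx)
  proj <- crossprod(Qx, Y)              # k x m
  constrained <- sum(proj^2)            # trace(Y' H Y)
  total <- sum(ord$eigenvalues[ord$eigenvalues > 0])
  Yhat <- Qx %*% proj
  sv <- svd(Yhat)
  n_ax <- min(2, sum(sv$d > max(sv$d[1], 1e-12) * 1e-8))
  sites <- sv$u[, seq_len(n_ax), drop = FALSE] %*% diag(sv$d[seq_len(n_ax)], n_ax)
  biplot <- suppressWarnings(stats::cor(X, sites))
  colnames(biplot) <- paste0("CAP", seq_len(n_ax))
  list(constrained_inertia = constrained,
       total_inertia = total,
       proportion = constrained / total,
       eigenvalues_negative_sum = sum(ord$eigenvalues[ord$eigenvalues < 0]),
       biplot = biplot,
       aliased = aliased)
}
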