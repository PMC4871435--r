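# PCA shape space over elliptic Fourier coefficients, and inverse-Fourier
# reconstruction of outlines at arbitrary positions in that space.

#' Principal component analysis of Fourier coefficients
#'
#' Covariance-based PCA (variables centered, not standardized: all
#' coefficients share units). By default the three constant terms (a0, c0,
#' e0) are excluded from the variable set -- after alignment they encode only
#' residual location -- but their means are retained so that reconstructed
#' outlines sit at the consensus location. Eigenvector signs are fixed so
#' that each axis's largest-magnitude loading is positive, making outputs
#' deterministic across platforms.
#'
#' @param coefficients specimens x variables matrix as built by
#'   [efa_matrix()] (columns `a0, c0, e0, a1, ...`), or any numeric matrix
#'   when `drop_constants = FALSE`.
#' @param drop_constants exclude the leading `a0, c0, e0` columns from the
#'   PCA variables?
#' @return object of class `"shape_space"` with fields `center` (mean
#'   coefficient vector over the PCA variables), `constants_mean`,
#'   `eigenvalues`, `pct_variance`, `cumulative_pct`, `rotation`
#'   (orthonormal eigenvectors in columns) and `scores`.
#' @export
pca_fit <- function(coefficients, drop_constants = TRUE) {
  X <- as.matrix(coefficients)
  if (anyNA(X)) stop("missing values in the coefficient matrix")
  if (nrow(X) < 3L) stop("PCA needs at least 3 specimens")
  constants_mean <- c(a0 = 0, c0 = 0, e0 = 0)
  if (drop_constants) {
    if (ncol(X) %% 6L != 3L)
      stop("expected a coefficient matrix with leading a0, c0, e0 columns")
    constants_mean <- colMeans(X[, 1:3, drop = FALSE])
    names(constants_mean) <- c("a0", "c0", "e0")
    X <- X[, -(1:3), drop = FALSE]
  }
  if (ncol(X) < 2L) stop("PCA needs at least 2 variables")
  if (max(apply(X, 2L, stats::var)) <= 0)
    stop("degenerate coefficient matrix: all variables constant")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pr$rotation
  scores <- pr$x
  for (j in seq_len(ncol(rot))) {               # deterministic sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  eig <- pr$sdev^2
  pct <- 100 * eig / sum(eig)
  structure(list(center = pr$center, constants_mean = constants_mean,
                 eigenvalues = eig, pct_variance = pct,
                 cumulative_pct = cumsum(pct), rotation = rot,
                 scores = scores, n_specimens = nrow(X),
                 drop_constants = drop_constants),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("shape space: %d specimens, %d coefficient variables, %d axes\n",
              x$n_specimens, nrow(x$rotation), ncol(x$rotation)))
  k <- min(3L, length(x$pct_variance))
  cat("  variance explained:",
      paste(sprintf("PC%d %.2f%%", seq_len(k), x$pct_variance[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Eigenvalue table of a shape space
#'
#' @param space a [pca_fit()] result.
#' @param n_axes number of axes to report (default 15 or all, whichever is
#'   smaller).
#' @return data.frame with columns `axis`, `eigenvalue`, `pct_variance`,
#'   `cumulative_pct`.
#' @export
eigen_table <- function(space, n_axes = 15L) {
  stopifnot(inherits(space, "shape_space"))
  n <- min(n_axes, length(space$eigenvalues))
  data.frame(axis = paste0("PC", seq_len(n)),
             eigenvalue = space$eigenvalues[seq_len(n)],
             pct_variance = space$pct_variance[seq_len(n)],
             cumulative_pct = space$cumulative_pct[seq_len(n)])
}

# deviation vector in coefficient space -> reconstructed outline
reconstruct_coef <- function(space, deviation, n_points) {
  coefv <- space$center + deviation
  h <- if (space$drop_constants)
    efa_from_vector(coefv, constants_values = space$constants_mean)
  else efa_from_vector(coefv)
  efa_inverse(h, n_points)
}

#' Reconstruct an outline at a position in the shape space
#'
#' The coefficient vector `mean + score * eigenvector(axis)` is reassembled
#' into elliptic Fourier harmonics (constants taken from the stored means)
#' and passed through the inverse transform. `score = 0` returns the mean
#' shape. Since the inverse transform is linear in the coefficients,
#' reconstructions compose additively in coefficient space.
#'
#' @param space a [pca_fit()] result.
#' @param axis PC index.
#' @param score position along the axis (same units as `space$scores`); the
#'   conventional extremes are `+/- 2 * sqrt(eigenvalue)`.
#' @param n_points points on the reconstructed outline.
#' @return n_points x 3 matrix (a closed outline, for plotting in
#'   ventral/lateral/distal views).
#' @export
reconstruct_at <- function(space, axis, score, n_points = 196L) {
  stopifnot(inherits(space, "shape_space"))
  axis <- as.integer(axis)
  if (is.na(axis) || axis < 1L || axis > ncol(space$rotation))
    stop("'axis' out of range (1..", ncol(space$rotation), ")")
  reconstruct_coef(space, score * space$rotation[, axis], n_points)
}

#' @rdname reconstruct_at
#' @export
mean_shape <- function(space, n_points = 196L) {
  stopifnot(inherits(space, "shape_space"))
  reconstruct_coef(space, 0, n_points)
}

#' Project coefficient rows into an existing shape space
#'
#' @param space a [pca_fit()] result.
#' @param coefficients matrix or vector laid out as the one `space` was
#'   fitted on (constants included if the space was fitted with them
#'   dropped, they are dropped here too).
#' @return scores matrix (rows match `coefficients`).
#' @export
project_scores <- function(space, coefficients) {
  stopifnot(inherits(space, "shape_space"))
  X <- if (is.matrix(coefficients)) coefficients else matrix(coefficients, nrow = 1L)
  if (space$drop_constants && ncol(X) == length(space$center) + 3L)
    X <- X[, -(1:3), drop = FALSE]
  sweep(X, 2L, space$center) %*% space$rotation
}
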