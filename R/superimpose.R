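# Generalized Procrustes superimposition computed on the three anchor
# landmarks only, with each specimen's similarity transform propagated to its
# pseudo-landmarks, followed by orthogonal tangent-space projection of the
# full configurations.

#' Centroid size of a point configuration
#'
#' Square root of the summed squared Euclidean distances of the points to
#' their centroid -- the standard geometric-morphometric size measure. Always
#' computed on original (mm) coordinates; aligned coordinates of the fitted
#' anchor triangle have centroid size 1 by construction.
#'
#' @param points k x 3 matrix (k >= 2).
#' @return centroid size, in the units of the coordinates.
#' @export
centroid_size <- function(points) {
  m <- as_point_matrix(points, "points")
  if (nrow(m) < 2L) stop("centroid size needs at least 2 points")
  cs <- sqrt(sum(sweep(m, 2L, colMeans(m))^2))
  if (cs <= .Machine$double.eps * nrow(m))
    stop("zero centroid size: all points coincident")
  cs
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# optimal proper rotation Q (right multiplication of row-point matrices)
# minimizing || A Q - B ||_F; reflections excluded.
procrustes_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Similarity transform
#'
#' Maps points by `x -> scale * rotation %*% (x - translation)` (column-vector
#' convention). The rotation is a proper orthogonal 3 x 3 matrix
#' (determinant +1: reflections are excluded because dorsal/ventral chirality
#' of a tool is meaningful).
#'
#' @param translation length-3 vector.
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param scale positive scalar.
#' @return object of class `"similarity_transform"`.
#' @export
similarity_transform <- function(translation = c(0, 0, 0),
                                 rotation = diag(3), scale = 1) {
  stopifnot(length(translation) == 3L, is.matrix(rotation),
            all(dim(rotation) == 3L), length(scale) == 1L)
  if (scale <= 0) stop("'scale' must be positive")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("'rotation' must be proper orthogonal (det +1)")
  structure(list(translation = as.numeric(translation),
                 rotation = rotation, scale = as.numeric(scale)),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#'
#' @param tf a [similarity_transform()].
#' @param points k x 3 matrix.
#' @return transformed k x 3 matrix.
#' @export
apply_transform <- function(tf, points) {
  stopifnot(inherits(tf, "similarity_transform"))
  m <- as_point_matrix(points, "points")
  out <- tf$scale * (sweep(m, 2L, tf$translation) %*% t(tf$rotation))
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Invert a similarity transform
#'
#' @param tf a [similarity_transform()].
#' @return the inverse transform, such that composing the two is the identity.
#' @export
inverse_transform <- function(tf) {
  stopifnot(inherits(tf, "similarity_transform"))
  # y = s R (x - t)  =>  x = (1/s) R^T y + t = (1/s) R^T (y - (-s R t))
  similarity_transform(translation = -tf$scale * as.numeric(tf$rotation %*% tf$translation),
                       rotation = t(tf$rotation), scale = 1 / tf$scale)
}

anchor_check <- function(anchors, id) {
  n <- cross3(anchors[2L, ] - anchors[1L, ], anchors[3L, ] - anchors[1L, ])
  scale2 <- sum((anchors - matrix(colMeans(anchors), 3L, 3L, byrow = TRUE))^2)
  if (sqrt(sum(n^2)) <= 1e-10 * scale2)
    stop("degenerate (collinear) anchor triangle for specimen '", id, "'")
}

# rotation putting a centered consensus triangle into the canonical pose:
# L1 on +y, triangle plane = x-y plane, L2 at positive x.
canonical_gauge <- function(M) {
  yhat <- M[1L, ] / sqrt(sum(M[1L, ]^2))
  n <- cross3(M[2L, ] - M[1L, ], M[3L, ] - M[1L, ])
  zhat <- n / sqrt(sum(n^2))
  xhat <- cross3(yhat, zhat)
  if (sum(M[2L, ] * xhat) < 0) { zhat <- -zhat; xhat <- -xhat }
  rbind(xhat, yhat, zhat, deparse.level = 0L)
}

#' Generalized Procrustes fit on the three anchor landmarks
#'
#' Iteratively superimposes the anchor triangles of all specimens: each
#' triangle is centered on its centroid, scaled (by default to unit anchor
#' centroid size), rotated onto the running consensus by orthogonal Procrustes
#' with reflections excluded, and the consensus is re-estimated until the root
#' mean square change of the consensus coordinates falls below `tol`. The 196
#' pseudo-landmarks never influence the fit; the per-specimen similarity
#' transforms are returned so that they can be propagated to the full
#' configurations with [align_outlines()].
#'
#' After convergence the arbitrary global rotation is removed by a canonical
#' gauge: L1 on the +y axis, triangle plane spanning x-y, L2 at positive x
#' (tip up, ventral face frontal).
#'
#' @param outlines an [outline_set()] (>= 2 specimens).
#' @param tol convergence tolerance on the consensus coordinates.
#' @param max_iter maximum number of iterations.
#' @param scale_ref `"anchors"` scales each specimen by the centroid size of
#'   its anchor triangle (standard Procrustes on the fitted subset, the
#'   default); `"full"` scales by the centroid size of the full 199-point
#'   configuration instead.
#' @return object of class `"gpa_fit"`: consensus anchor triangle,
#'   per-specimen transforms, iteration count and per-iteration objective.
#' @export
gpa_anchors <- function(outlines, tol = 1e-10, max_iter = 100L,
                        scale_ref = c("anchors", "full")) {
  stopifnot(inherits(outlines, "outline_set"))
  scale_ref <- match.arg(scale_ref)
  if (length(outlines) < 2L) stop("at least 2 specimens are required")
  ids <- names(outlines)
  mu <- lapply(outlines, function(o) colMeans(o$anchors))
  B <- vector("list", length(outlines))
  s <- numeric(length(outlines))
  for (i in seq_along(outlines)) {
    o <- outlines[[i]]
    anchor_check(o$anchors, ids[i])
    centered <- sweep(o$anchors, 2L, mu[[i]])
    s[i] <- 1 / switch(scale_ref,
                       anchors = centroid_size(o$anchors),
                       full    = centroid_size(full_config(o)))
    B[[i]] <- centered * s[i]
  }
  M <- B[[1L]]
  M <- sweep(M, 2L, colMeans(M)); M <- M / centroid_size(M)
  objective <- numeric(0L)
  Q <- NULL
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    Q <- lapply(B, procrustes_rotation, B = M)
    C <- Map(function(b, q) b %*% q, B, Q)
    Mn <- Reduce(`+`, C) / length(C)
    Mn <- sweep(Mn, 2L, colMeans(Mn)); Mn <- Mn / centroid_size(Mn)
    objective <- c(objective,
                   sum(vapply(C, function(cm) sum((cm - Mn)^2), numeric(1L))))
    delta <- sqrt(mean((Mn - M)^2))
    M <- Mn
    iters <- it
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("Procrustes fit did not converge in %d iterations (last change %.3g)",
                 max_iter, delta))
  G <- canonical_gauge(M)
  M <- M %*% t(G)
  transforms <- vector("list", length(outlines))
  for (i in seq_along(outlines)) {
    transforms[[i]] <- similarity_transform(
      translation = mu[[i]],
      rotation = G %*% t(Q[[i]]),
      scale = s[i])
  }
  names(transforms) <- ids
  structure(list(consensus_anchors = M, transforms = transforms,
                 iterations = iters, objective = objective,
                 scale_ref = scale_ref, ids = ids),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("anchor-landmark Procrustes fit: %d specimens, converged in %d iterations (scale ref: %s)\n",
              length(x$transforms), x$iterations, x$scale_ref))
  invisible(x)
}

#' Propagate Procrustes transforms to full configurations
#'
#' Applies each specimen's similarity transform (fitted on the three anchors)
#' to its full 3 + k point configuration, yielding dimensionless aligned
#' shape coordinates in the canonical pose.
#'
#' @param fit a [gpa_anchors()] fit.
#' @param outlines the `outline_set` the fit was computed on.
#' @return object of class `"aligned_set"`: a list of (3 + k) x 3 matrices
#'   (anchors first), plus the full-configuration consensus.
#' @export
align_outlines <- function(fit, outlines) {
  stopifnot(inherits(fit, "gpa_fit"), inherits(outlines, "outline_set"))
  if (!identical(names(outlines), fit$ids))
    stop("outline set does not match the specimens of the Procrustes fit")
  configs <- Map(function(tf, o) apply_transform(tf, full_config(o)),
                 fit$transforms, outlines)
  consensus <- Reduce(`+`, configs) / length(configs)
  structure(list(configs = configs, consensus = consensus,
                 n_anchors = 3L, ids = fit$ids, tangent = FALSE),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned_set: %d specimens x %d points%s\n", length(x$configs),
              nrow(x$consensus), if (isTRUE(x$tangent)) " (tangent projected)" else ""))
  invisible(x)
}

config_vectors <- function(configs) {
  do.call(rbind, lapply(configs, function(m) as.vector(t(m))))
}

vector_config <- function(v) {
  matrix(v, ncol = 3L, byrow = TRUE, dimnames = list(NULL, c("x", "y", "z")))
}

#' Project aligned configurations into the tangent space at the consensus
#'
#' Each configuration, flattened to a 3(3 + k) vector v, is orthogonally
#' projected onto the tangent space of the pre-shape sphere at the
#' unit-normalized full consensus m: `v -> v - (v . m) m + m` with `|m| = 1`
#' (Kendall tangent coordinates; the tangent point itself is fixed). This
#' linearizes the curved shape space so that Euclidean multivariate
#' statistics apply; for configurations close to the consensus the
#' displacement is second-order small.
#'
#' @param aligned an [align_outlines()] result.
#' @return an `aligned_set` with projected configurations; the consensus is
#'   replaced by the unit-normalized tangent point.
#' @export
tangent_project <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_set"))
  m <- as.vector(t(aligned$consensus))
  nm <- sqrt(sum(m^2))
  if (nm <= .Machine$double.eps) stop("degenerate (zero) consensus configuration")
  mhat <- m / nm
  V <- config_vectors(aligned$configs)
  proj <- V - (V %*% mhat) %*% t(mhat) +
    matrix(mhat, nrow(V), length(mhat), byrow = TRUE)
  configs <- lapply(seq_len(nrow(proj)), function(i) vector_config(proj[i, ]))
  names(configs) <- aligned$ids
  structure(list(configs = configs, consensus = vector_config(mhat),
                 n_anchors = aligned$n_anchors, ids = aligned$ids,
                 tangent = TRUE),
            class = "aligned_set")
}
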