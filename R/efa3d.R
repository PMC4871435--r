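# Elliptic Fourier analysis of closed 3D outlines.
#
# Each coordinate of the closed curve is expanded independently as a truncated
# Fourier series in the arc parameter t on [0, T):
#   x(t) = a0 + sum_n a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T)
#   y(t) = c0 + sum_n c_n cos(.) + d_n sin(.)
#   z(t) = e0 + sum_n e_n cos(.) + f_n sin(.)
# The third dimension simply adds one constant (e0) and two coefficients
# (e_n, f_n) per harmonic to the classical 2D formulation. No normalization by
# the first ellipse is performed anywhere: position, orientation and scale are
# removed beforehand by the anchor-landmark Procrustes superimposition, so the
# coefficients deliberately retain orientation information.

#' Construct an elliptic Fourier coefficient object
#'
#' @param constants length-3 vector `(a0, c0, e0)` of mean offsets of x, y, z.
#' @param coef N x 6 matrix with columns `a, b, c, d, e, f`: cosine and sine
#'   coefficients of x, y and z for harmonics 1..N.
#' @param perimeter total parameter length T (mm for raw contours,
#'   dimensionless after alignment); kept for reference only.
#' @param method which forward estimator produced the coefficients.
#' @return object of class `"efa"`.
#' @export
efa_harmonics <- function(constants, coef, perimeter = NA_real_,
                          method = NA_character_) {
  constants <- as.numeric(constants)
  coef <- as.matrix(coef)
  stopifnot(length(constants) == 3L, ncol(coef) == 6L, nrow(coef) >= 1L)
  if (anyNA(constants) || anyNA(coef) || any(!is.finite(coef)))
    stop("non-finite Fourier coefficients")
  dimnames(coef) <- list(paste0("h", seq_len(nrow(coef))),
                         c("a", "b", "c", "d", "e", "f"))
  names(constants) <- c("a0", "c0", "e0")
  structure(list(constants = constants, coef = coef,
                 n_harmonics = nrow(coef), perimeter = perimeter,
                 method = method),
            class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("3D elliptic Fourier coefficients: %d harmonics (+3 constants), method '%s'\n",
              x$n_harmonics, x$method))
  invisible(x)
}

#' Forward 3D elliptic Fourier transform of a closed contour
#'
#' Two estimators are offered:
#'
#' * `"trapezoid"` (default): the classical chord-length parameterized
#'   formulation. The closed polygon is integrated exactly (trapezoidal
#'   accumulation over chords), so unequally spaced points are handled
#'   correctly. Being an exact integral of the piecewise-linear interpolant,
#'   it attenuates harmonic n of a smooth curve by a factor
#'   `sinc(pi n / k)^2` (about 1.2 percent at n = 12 for k = 196 points).
#' * `"projection"`: least-squares projection of the sampled coordinates on
#'   the truncated Fourier basis at uniform parameter spacing, i.e. the
#'   points are treated as equally spaced samples of the curve (the
#'   pipeline's case after resampling). This is the discrete Fourier
#'   transform: it recovers band-limited curves exactly and is exactly
#'   inverted by [efa_inverse()] at the band limit `2N + 1 <= k`.
#'
#' The starting point of the parameterization is the first contour point
#' (landmark 1); the traversal direction is that of the input. Reversing the
#' traversal negates all sine coefficients.
#'
#' @param contour k x 3 matrix of ordered closed-contour points.
#' @param n_harmonics number of harmonics N (>= 1). A warning is issued when
#'   k < 2N + 1 (above the Nyquist limit of the sampling).
#' @param method forward estimator, see Details.
#' @return an [efa_harmonics()] object.
#' @export
efa_forward <- function(contour, n_harmonics = 12L,
                        method = c("trapezoid", "projection")) {
  method <- match.arg(method)
  N <- as.integer(n_harmonics)
  if (is.na(N) || N < 1L) stop("'n_harmonics' must be a positive integer")
  m <- as_point_matrix(contour, "contour")
  if (nrow(m) < 3L) stop("a closed contour needs at least 3 points")
  m <- drop_zero_chords(m)
  k <- nrow(m)
  if (k < 2L * N + 1L)
    warning(sprintf("%d points cannot resolve %d harmonics (Nyquist limit %d)",
                    k, N, (k - 1L) %/% 2L))
  d <- chord_lengths(m)
  tt <- c(0, cumsum(d))
  per <- tt[k + 1L]
  phi <- 2 * pi * tt / per                      # length k + 1, phi[k+1] = 2 pi
  nvec <- seq_len(N)
  if (method == "trapezoid") {
    D <- rbind(m[-1L, , drop = FALSE], m[1L, , drop = FALSE]) - m   # k x 3
    v <- D / d                                  # velocity on each chord
    Cs <- cos(outer(nvec, phi))                 # N x (k+1)
    Sn <- sin(outer(nvec, phi))
    dC <- Cs[, -1L, drop = FALSE] - Cs[, -(k + 1L), drop = FALSE]   # N x k
    dS <- Sn[, -1L, drop = FALSE] - Sn[, -(k + 1L), drop = FALSE]
    fac <- per / (2 * pi^2 * nvec^2)
    cosco <- fac * (dC %*% v)                   # N x 3: a_n, c_n, e_n
    sinco <- fac * (dS %*% v)                   # N x 3: b_n, d_n, f_n
    constants <- colSums(d * (m + rbind(m[-1L, , drop = FALSE], m[1L, , drop = FALSE])) / 2) / per
  } else {
    # the points are taken as samples at uniform parameter spacing (the
    # pipeline's case after equal-arc resampling); discrete orthogonality
    # then makes efa_inverse an exact right inverse at the band limit
    th <- 2 * pi * (seq_len(k) - 1L) / k
    X <- cbind(1, cos(outer(th, nvec)), sin(outer(th, nvec)))
    keep <- sqrt(colSums(X^2)) > 1e-9 * sqrt(k)
    co <- matrix(0, ncol(X), 3L)
    fit <- stats::lm.fit(X[, keep, drop = FALSE], m)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    co[keep, ] <- cf
    constants <- co[1L, ]
    cosco <- co[1L + nvec, , drop = FALSE]
    sinco <- co[1L + N + nvec, , drop = FALSE]
  }
  coef <- cbind(a = cosco[, 1L], b = sinco[, 1L],
                c = cosco[, 2L], d = sinco[, 2L],
                e = cosco[, 3L], f = sinco[, 3L])
  efa_harmonics(constants, coef, perimeter = per, method = method)
}

#' Inverse 3D elliptic Fourier transform
#'
#' Evaluates the truncated Fourier series at `n_points` equally spaced
#' parameter values on [0, T), returning the reconstructed closed outline.
#'
#' @param h an [efa_harmonics()] object (or coefficient vector, see
#'   [efa_from_vector()]).
#' @param n_points number of points to evaluate (>= 3).
#' @return n_points x 3 matrix.
#' @export
efa_inverse <- function(h, n_points = 196L) {
  stopifnot(inherits(h, "efa"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 3L) stop("'n_points' must be >= 3")
  th <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  nvec <- seq_len(h$n_harmonics)
  Cs <- cos(outer(th, nvec))
  Sn <- sin(outer(th, nvec))
  out <- cbind(
    x = h$constants[1L] + Cs %*% h$coef[, "a"] + Sn %*% h$coef[, "b"],
    y = h$constants[2L] + Cs %*% h$coef[, "c"] + Sn %*% h$coef[, "d"],
    z = h$constants[3L] + Cs %*% h$coef[, "e"] + Sn %*% h$coef[, "f"])
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Harmonic power table
#'
#' Power of harmonic n is `(a_n^2 + b_n^2 + c_n^2 + d_n^2 + e_n^2 + f_n^2)/2`;
#' the cumulative fraction is relative to the total over the computed
#' harmonics (so it reaches 1 at the last one).
#'
#' @param h an [efa_harmonics()] object.
#' @return data.frame with columns `harmonic`, `power`,
#'   `cumulative_fraction`.
#' @export
harmonic_power <- function(h) {
  stopifnot(inherits(h, "efa"))
  p <- rowSums(h$coef^2) / 2
  tot <- sum(p)
  if (tot <= 0) stop("degenerate coefficients: zero total harmonic power")
  data.frame(harmonic = seq_along(p), power = unname(p),
             cumulative_fraction = unname(cumsum(p) / tot))
}

#' Smallest harmonic count reaching a cumulative power threshold
#'
#' Returns the smallest N such that every specimen's cumulative power
#' fraction at harmonic N is at least `threshold`. This is advisory: the
#' analysis default of 12 harmonics can always be overridden.
#'
#' @param powers a single [harmonic_power()] table or a list of them
#'   (one per specimen).
#' @param threshold cumulative power fraction in (0, 1].
#' @param quiet suppress the per-specimen attainment message.
#' @return integer harmonic count.
#' @export
choose_harmonics <- function(powers, threshold = 0.99, quiet = FALSE) {
  if (!is.list(powers) || is.data.frame(powers)) powers <- list(powers)
  if (!(threshold > 0 && threshold <= 1)) stop("'threshold' must be in (0, 1]")
  tol <- 1e-12   # guard against cumulative rounding at threshold = 1
  perN <- vapply(powers, function(p) {
    i <- which(p$cumulative_fraction >= threshold - tol)
    if (!length(i))
      stop("threshold ", threshold, " unreachable within ", nrow(p),
           " computed harmonics; compute more harmonics (denser contours)")
    min(i)
  }, integer(1L))
  if (!quiet)
    message(sprintf("threshold %.3g reached at harmonic %d (per-specimen range %d..%d)",
                    threshold, max(perN), min(perN), max(perN)))
  as.integer(max(perN))
}

# ---- coefficient vectors and matrices ---------------------------------------

#' Flatten / rebuild elliptic Fourier coefficients
#'
#' The flat layout is `a0, c0, e0, a1, b1, c1, d1, e1, f1, ..., fN` (constants
#' first when `constants = TRUE`), matching the coefficient-matrix column
#' order written by the pipeline.
#'
#' @param h an [efa_harmonics()] object.
#' @param constants include the three constant terms?
#' @return named numeric vector.
#' @export
efa_coef_vector <- function(h, constants = TRUE) {
  stopifnot(inherits(h, "efa"))
  v <- as.vector(t(h$coef))
  names(v) <- paste0(rep(c("a", "b", "c", "d", "e", "f"), h$n_harmonics),
                     rep(seq_len(h$n_harmonics), each = 6L))
  if (constants) v <- c(h$constants, v)
  v
}

#' @rdname efa_coef_vector
#' @param v flat coefficient vector.
#' @param constants_values constants to use when `v` carries none.
#' @export
efa_from_vector <- function(v, constants_values = NULL) {
  v <- as.numeric(v)
  if (is.null(constants_values)) {
    if (length(v) %% 6L != 3L)
      stop("coefficient vector of length ", length(v), " is not 3 + 6N")
    constants_values <- v[1:3]
    v <- v[-(1:3)]
  } else if (length(v) %% 6L != 0L)
    stop("coefficient vector of length ", length(v), " is not 6N")
  coef <- matrix(v, ncol = 6L, byrow = TRUE)
  efa_harmonics(constants_values, coef)
}

# insert anchor points into a closed contour at the perimeter-minimizing edge
insert_anchors <- function(contour, anchors) {
  m <- contour
  for (r in 2:3) {
    p <- anchors[r, ]
    nxt <- rbind(m[-1L, , drop = FALSE], m[1L, , drop = FALSE])
    extra <- sqrt(rowSums(sweep(m, 2L, p)^2)) +
      sqrt(rowSums(sweep(nxt, 2L, p)^2)) - chord_lengths(m)
    i <- which.min(extra)
    m <- if (i == nrow(m)) rbind(m, p) else
      rbind(m[seq_len(i), , drop = FALSE], p,
            m[(i + 1L):nrow(m), , drop = FALSE])
  }
  m
}

#' Elliptic Fourier coefficient matrix of an aligned assemblage
#'
#' Runs [efa_forward()] on every aligned, tangent-projected configuration and
#' stacks the flat coefficient vectors into a specimens x (3 + 6N) matrix.
#' By default the Fourier input is the 196 pseudo-landmarks only: anchors L2
#' and L3 already drove the alignment and inserting them would break equal
#' spacing. With `include_anchors = TRUE` they are inserted into the curve at
#' their perimeter-minimizing positions (the chord-length parameterization
#' remains valid for the resulting unequal spacing).
#'
#' @param aligned an [align_outlines()] / [tangent_project()] result.
#' @param n_harmonics harmonics to compute.
#' @param include_anchors interleave L2/L3 into the sampled curve?
#' @param method forward estimator, see [efa_forward()].
#' @return numeric matrix, one row per specimen, columns
#'   `a0, c0, e0, a1, b1, ..., fN`.
#' @export
efa_matrix <- function(aligned, n_harmonics = 12L, include_anchors = FALSE,
                       method = c("trapezoid", "projection")) {
  stopifnot(inherits(aligned, "aligned_set"))
  method <- match.arg(method)
  na <- aligned$n_anchors
  rows <- lapply(aligned$configs, function(cfg) {
    contour <- cfg[-seq_len(na), , drop = FALSE]
    if (include_anchors)
      contour <- insert_anchors(contour, cfg[seq_len(na), , drop = FALSE])
    efa_coef_vector(efa_forward(contour, n_harmonics, method = method))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- aligned$ids
  out
}
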