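# Equal-arc-length resampling of closed 3D contours.
#
# Digitized pseudo-landmarks are rarely exactly equally spaced; all analyses
# assume equal spacing along the closed curve, so ingestion always re-applies
# resampling (idempotent when spacing is already equal).

chord_lengths <- function(m) {
  nxt <- rbind(m[-1L, , drop = FALSE], m[1L, , drop = FALSE])
  sqrt(rowSums((nxt - m)^2))
}

# drop points creating zero-length chords (consecutive duplicates, including
# a duplicate of the first point at the end of the row)
drop_zero_chords <- function(m, quiet = TRUE) {
  repeat {
    d <- chord_lengths(m)
    if (!any(d == 0)) return(m)
    if (!quiet) message("dropping ", sum(d == 0), " duplicated contour point(s)")
    drop <- which(d == 0)
    # removing p[i+1] removes the zero chord i; wrap for the closing chord
    idx <- ifelse(drop == nrow(m), 1L, drop + 1L)
    if (length(idx) >= nrow(m)) stop("degenerate outline: all points coincident")
    m <- m[-idx, , drop = FALSE]
    if (nrow(m) < 3L) stop("degenerate outline: fewer than 3 distinct points")
  }
}

#' Perimeter of a closed 3D polygon
#'
#' Sum of Euclidean chord lengths along the ordered points, including the
#' implicit closing chord from the last point back to the first.
#'
#' @param contour k x 3 matrix of ordered points (k >= 3).
#' @return perimeter in the coordinate units (mm).
#' @export
outline_perimeter <- function(contour) {
  m <- as_point_matrix(contour, "contour")
  if (nrow(m) < 3L) stop("a closed contour needs at least 3 points")
  per <- sum(chord_lengths(m))
  if (per <= 0) stop("degenerate outline: all points coincident")
  per
}

#' Resample a closed contour to n equally spaced points
#'
#' The closed piecewise-linear curve through the input points is traversed
#' from its first point in the original direction, and points are placed by
#' linear interpolation at arc positions `i * perimeter / n`, i = 0..n-1.
#' The first output point therefore equals the first input point exactly, and
#' all n chords (including the closing one) have length `perimeter / n`.
#' Consecutive duplicate points are dropped before resampling.
#'
#' @param contour k x 3 matrix of ordered points.
#' @param n number of output points (>= 3).
#' @return n x 3 matrix of equally spaced points.
#' @export
arc_length_resample <- function(contour, n = 196L) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("'n' must be an integer >= 3")
  m <- as_point_matrix(contour, "contour")
  if (nrow(m) < 3L) stop("a closed contour needs at least 3 points")
  m <- drop_zero_chords(m)
  d <- chord_lengths(m)
  tt <- c(0, cumsum(d))                # arc position of each vertex, closed
  per <- tt[length(tt)]
  closed <- rbind(m, m[1L, , drop = FALSE])
  s <- (seq_len(n) - 1L) * per / n
  out <- vapply(1:3, function(j) stats::approx(tt, closed[, j], xout = s)$y,
                numeric(n))
  out[1L, ] <- m[1L, ]                 # exact, not interpolated
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Resample the contour of an outline (or of every outline in a set)
#'
#' Applies [arc_length_resample()] to the contour, keeping the three anchor
#' landmarks untouched as metadata: equal spacing and anchor coincidence are
#' mutually exclusive in general, so L2 and L3 are carried alongside rather
#' than forced onto resampled points.
#'
#' @param x an `outline` or `outline_set`.
#' @param n number of pseudo-landmarks (default 196).
#' @return object of the same class with resampled contours.
#' @export
resample_outline <- function(x, n = 196L) {
  if (inherits(x, "outline_set"))
    return(outline_set(lapply(x, resample_outline, n = n)))
  stopifnot(inherits(x, "outline"))
  x$contour <- arc_length_resample(x$contour, n)
  x$anchors[1L, ] <- x$contour[1L, ]
  x
}
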