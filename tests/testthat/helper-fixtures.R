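# shared geometric fixtures, all built in code

# closed planar circle of radius r, sampled at uniform angle
make_circle <- function(n = 200L, r = 1, z = 0) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = r * cos(t), y = r * sin(t), z = z)
}

# planar ellipse sampled at uniform parameter (a single-harmonic curve)
make_ellipse <- function(n = 200L, A = 3, B = 1.8) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = A * cos(t), y = B * sin(t), z = 0)
}

unit_square <- function() {
  cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = c(0, 0, 0, 0))
}

# random proper rotation
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

random_similarity <- function(max_shift = 50) {
  similarity_transform(translation = stats::rnorm(3L, sd = max_shift),
                       rotation = random_rotation(),
                       scale = stats::runif(1L, 0.3, 3))
}

transform_outline <- function(o, tf) {
  o$contour <- apply_transform(tf, o$contour)
  o$anchors <- apply_transform(tf, o$anchors)
  o
}

# small assemblage for module tests (cheap: 96-point contours)
small_assemblage <- function(n = 10L, seed = 42L, n_points = 96L, ...) {
  generate_assemblage(assemblage_config(n, seed = seed, n_points = n_points, ...))
}

# a smooth closed 3D test contour, equally spaced
smooth_contour <- function(n = 196L) {
  t <- 2 * pi * (seq_len(512L) - 1L) / 512L
  m <- cbind(x = cos(t) + 0.15 * cos(2 * t),
             y = 1.4 * sin(t) - 0.1 * sin(3 * t),
             z = 0.2 * sin(2 * t))
  arc_length_resample(m, n)
}
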