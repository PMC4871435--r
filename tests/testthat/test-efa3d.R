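# forward / inverse 3D elliptic Fourier analysis and harmonic power

test_that("a uniformly sampled ellipse is recovered as a single harmonic", {
  ell <- make_ellipse(1e4L, A = 3, B = 1.8)
  h <- efa_forward(ell, 5L, method = "projection")
  expect_equal(unname(h$coef[1L, c("a", "d")]), c(3, 1.8), tolerance = 1e-9)
  expect_lt(max(abs(h$coef[1L, c("b", "c")])), 1e-9)
  expect_lt(max(abs(h$coef[, c("e", "f")])), 1e-6)     # flat curve: no z signal
  pw <- harmonic_power(h)
  expect_lt(1 - pw$cumulative_fraction[1L], 1e-8)      # higher harmonics empty
  # on a constant-speed curve (circle) the chord-length trapezoid estimator
  # agrees with the projection up to its sinc^2 quadrature attenuation
  circ <- make_circle(1e4L, r = 2)
  hk <- efa_forward(circ, 3L, method = "trapezoid")
  expect_equal(unname(hk$coef[1L, c("a", "d")]), c(2, 2), tolerance = 1e-6)
  # on an eccentric ellipse the two parameterizations genuinely differ
  hke <- efa_forward(ell, 5L, method = "trapezoid")
  expect_gt(abs(hke$coef[1L, "a"] - 3), 0.01)
})

test_that("coefficients transform equivariantly under similarity transforms", {
  ctr <- smooth_contour(128L)
  h <- efa_forward(ctr, 8L)
  set.seed(4)
  tf <- random_similarity()
  h2 <- efa_forward(apply_transform(tf, ctr), 8L)
  # rotation mixes the per-harmonic (cos; sin) coordinate triplets linearly,
  # scale multiplies everything, translation only moves the constants
  cos_t <- tf$scale * h$coef[, c("a", "c", "e")] %*% t(tf$rotation)
  sin_t <- tf$scale * h$coef[, c("b", "d", "f")] %*% t(tf$rotation)
  expect_equal(unname(h2$coef[, c("a", "c", "e")]), unname(cos_t), tolerance = 1e-10)
  expect_equal(unname(h2$coef[, c("b", "d", "f")]), unname(sin_t), tolerance = 1e-10)
  const_t <- tf$scale * (h$constants - tf$translation) %*% t(tf$rotation)
  expect_equal(unname(h2$constants), as.vector(const_t), tolerance = 1e-10)
})

test_that("constants-only harmonics reconstruct a constant point", {
  h <- efa_harmonics(c(1.5, -2, 0.25), matrix(0, 3L, 6L))
  pts <- efa_inverse(h, 10L)
  expect_equal(pts, matrix(rep(c(1.5, -2, 0.25), each = 10L), 10L),
               ignore_attr = TRUE)
})

test_that("forward-inverse round trip is the identity at the band limit", {
  set.seed(10)
  coef <- matrix(stats::rnorm(12L * 6L, sd = 0.3) / rep(1:12, 6L)^1.5, 12L)
  h0 <- efa_harmonics(c(0.1, -0.2, 0.05), coef)
  pts <- efa_inverse(h0, 196L)
  h1 <- efa_forward(pts, 12L, method = "projection")
  expect_equal(h1$coef, h0$coef, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(h1$constants, h0$constants, tolerance = 1e-12, ignore_attr = TRUE)
  # and once more through the loop
  h2 <- efa_forward(efa_inverse(h1, 196L), 12L, method = "projection")
  expect_equal(h2$coef, h0$coef, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("reconstruction error is monotone in N and vanishes at Nyquist", {
  k <- 196L
  ctr <- smooth_contour(k)
  errs <- suppressWarnings(vapply(c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 98L),
    function(N) {
      h <- efa_forward(ctr, N, method = "projection")
      max(abs(efa_inverse(h, k) - ctr))
    }, numeric(1L)))
  expect_true(all(diff(errs) <= 1e-10))
  expect_lt(errs[length(errs)], 1e-8)
})

test_that("reversing the traversal direction negates the sine coefficients", {
  set.seed(12)
  for (rep in 1:3) {
    poly <- cbind(stats::rnorm(15L), stats::rnorm(15L), stats::rnorm(15L))
    fwd <- efa_forward(poly, 6L)
    bwd <- efa_forward(poly[c(1L, 15:2), ], 6L)
    expect_equal(bwd$coef[, c("a", "c", "e")], fwd$coef[, c("a", "c", "e")],
                 tolerance = 1e-12)
    expect_equal(bwd$coef[, c("b", "d", "f")], -fwd$coef[, c("b", "d", "f")],
                 tolerance = 1e-12)
    expect_equal(bwd$constants, fwd$constants, tolerance = 1e-12)
  }
})

test_that("harmonic power matches brute force and is scale invariant", {
  set.seed(20)
  coef <- matrix(stats::rnorm(42L), 7L)
  h <- efa_harmonics(c(0, 0, 0), coef)
  pw <- harmonic_power(h)
  brute <- apply(coef, 1L, function(r) sum(r^2) / 2)
  expect_equal(pw$power, unname(brute))
  expect_equal(pw$cumulative_fraction, cumsum(brute) / sum(brute))
  expect_equal(pw$cumulative_fraction[7L], 1)
  h2 <- efa_harmonics(c(0, 0, 0), 2 * coef)
  expect_equal(harmonic_power(h2)$cumulative_fraction, pw$cumulative_fraction)
})

test_that("Parseval: sample variance equals total harmonic power (full band)", {
  k <- 195L                                  # odd count: no Nyquist split
  ctr <- smooth_contour(k)
  h <- suppressWarnings(efa_forward(ctr, 97L, method = "projection"))
  total_power <- sum(rowSums(h$coef^2)) / 2
  sig_energy <- sum(sweep(ctr, 2L, colMeans(ctr))^2) / k
  expect_equal(total_power, sig_energy, tolerance = 1e-10)
})

test_that("harmonic-count selection honours thresholds monotonically", {
  ell <- make_ellipse(256L)
  pw_ell <- harmonic_power(efa_forward(ell, 20L, method = "projection"))
  expect_identical(choose_harmonics(pw_ell, 1.0, quiet = TRUE), 1L)

  a <- small_assemblage(n = 5L, seed = 17L)
  sc <- lithomorph:::shape_scores(a$outlines, n_points = 96L, n_harmonics = 40L)
  pws <- lapply(seq_len(nrow(sc$coef)), function(i)
    harmonic_power(efa_from_vector(sc$coef[i, ])))
  ns <- vapply(c(0.5, 0.9, 0.99, 0.999),
               function(th) choose_harmonics(pws, th, quiet = TRUE), integer(1L))
  expect_true(all(diff(ns) >= 0L))
  expect_error(choose_harmonics(data.frame(harmonic = 1L, power = 1,
                                           cumulative_fraction = 0.8), 0.99,
                                quiet = TRUE),
               "unreachable")
})

test_that("degenerate inputs and Nyquist violations are reported", {
  expect_error(efa_forward(matrix(3, 8L, 3L), 4L), "degenerate")
  expect_error(efa_forward(unit_square(), 0L), "positive integer")
  expect_warning(efa_forward(unit_square(), 4L), "Nyquist")
  expect_error(harmonic_power(efa_harmonics(c(1, 1, 1), matrix(0, 2L, 6L))),
               "zero total")
})
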