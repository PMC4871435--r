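# MANOVA, discriminant analysis, allometry and size tests

test_that("Pillai degrees of freedom reproduce the closed form for all designs", {
  expect_identical(pillai_df(9, 3, 37), c(num = 18, den = 54))
  expect_identical(pillai_df(5, 3, 37), c(num = 10, den = 62))
  expect_identical(pillai_df(15, 2, 37), c(num = 15, den = 21))
  # and agree with the F-approximation dfs computed by the MANOVA itself
  set.seed(1)
  for (des in list(c(k = 9, g = 3), c(k = 5, g = 3), c(k = 15, g = 2))) {
    Y <- matrix(stats::rnorm(37 * des["k"]), 37)
    f <- factor(rep(seq_len(des["g"]), length.out = 37))
    t <- manova_pillai(Y, f)
    expect_identical(c(num = t$df_num, den = t$df_den),
                     pillai_df(des[["k"]], des[["g"]], 37))
  }
})

test_that("Pillai F equals the Hotelling-Lawley F for two groups", {
  set.seed(7)
  for (rep in 1:5) {
    Y <- matrix(stats::rnorm(30 * 6), 30)
    f <- factor(rep(c("a", "b"), c(16, 14)))
    fit <- stats::manova(Y ~ f)
    Fp <- summary(fit, test = "Pillai")$stats[1L, "approx F"]
    Fh <- summary(fit, test = "Hotelling-Lawley")$stats[1L, "approx F"]
    expect_equal(Fp, Fh, tolerance = 1e-10)
    expect_equal(manova_pillai(Y, f)$F_value, Fp)
  }
})

test_that("Pillai's trace is invariant under rotations of the variable space", {
  set.seed(9)
  Y <- matrix(stats::rnorm(25 * 8), 25)
  f <- factor(rep(c("a", "b", "c"), length.out = 25))
  V0 <- manova_pillai(Y, f)$statistic
  for (rep in 1:3) {
    Q <- qr.Q(qr(matrix(stats::rnorm(64), 8)))
    expect_equal(manova_pillai(Y %*% Q, f)$statistic, V0, tolerance = 1e-10)
  }
})

test_that("MANOVA type-I error is near nominal and it detects real effects", {
  set.seed(123)
  pv <- replicate(2000L, {
    Y <- matrix(stats::rnorm(37 * 9), 37)
    f <- factor(sample(rep(c("a", "b"), c(20, 17))))
    manova_pillai(Y, f)$p_value
  })
  expect_gt(mean(pv < 0.05), 0.03)
  expect_lt(mean(pv < 0.05), 0.07)
  # strong separation is detected
  Y <- matrix(stats::rnorm(37 * 9), 37)
  f <- factor(rep(c("a", "b"), c(20, 17)))
  Y[f == "b", 1L] <- Y[f == "b", 1L] + 4
  expect_lt(manova_pillai(Y, f)$p_value, 1e-6)
  expect_error(manova_pillai(Y, factor(rep("a", 37))), "at least 2")
  expect_error(manova_pillai(matrix(rnorm(50 * 9), 50)[1:10, ],
                             factor(rep(c("a", "b"), 5)), k = 9), "insufficient")
})

test_that("discriminant axes separate separable clouds and match Pillai", {
  set.seed(21)
  Y <- rbind(matrix(stats::rnorm(60, 0), 20), matrix(stats::rnorm(60, 8), 20))
  f <- factor(rep(c("a", "b"), each = 20))
  d <- lda_fit(Y, f)
  expect_identical(ncol(d$loadings), 1L)               # g = 2: single axis
  expect_gt(min(d$df_scores[f == "b", 1L]), max(d$df_scores[f == "a", 1L]))

  # canonical identity: Pillai V = sum of canonical r^2 from the eigenproblem
  Y3 <- matrix(stats::rnorm(33 * 5), 33)
  f3 <- factor(rep(c("a", "b", "c"), each = 11))
  Y3[f3 == "b", 1L] <- Y3[f3 == "b", 1L] + 1.5
  V <- manova_pillai(Y3, f3)$statistic
  W <- matrix(0, 5, 5); B <- matrix(0, 5, 5); gm <- colMeans(Y3)
  for (l in levels(f3)) {
    Yl <- Y3[f3 == l, ]
    W <- W + crossprod(scale(Yl, scale = FALSE))
    B <- B + nrow(Yl) * tcrossprod(colMeans(Yl) - gm)
  }
  ev <- sort(Re(eigen(solve(W) %*% B, only.values = TRUE)$values),
             decreasing = TRUE)[1:2]
  expect_equal(sum(ev / (1 + ev)), V, tolerance = 1e-10)
})

test_that("discriminant extreme shapes round-trip and degenerate to the mean", {
  a <- small_assemblage(n = 14L, seed = 8L)
  sc <- lithomorph:::shape_scores(a$outlines, n_points = 96L)
  f <- droplevels(a$factors$action)
  d <- lda_fit(sc$space$scores, f, k = 4L)
  ext <- df_extreme_shapes(d, sc$space, axis = 1L, sd_mult = 2, n_points = 96L)
  # re-extract coefficients, project to PC space, compute the DF score
  h <- efa_forward(ext$positive, 12L, method = "projection")
  pc <- project_scores(sc$space, efa_coef_vector(h))
  df_score <- sum(pc[seq_len(d$k)] * d$loadings[, 1L])
  expect_equal(df_score, ext$df_scores[2L], tolerance = 1e-8)

  dz <- d; dz$loadings[, 1L] <- 0
  extz <- df_extreme_shapes(dz, sc$space, axis = 1L, n_points = 96L)
  expect_equal(extz$positive, mean_shape(sc$space, 96L))
})

test_that("size-shape regression holds its size under the null and has power", {
  set.seed(31)
  pv <- replicate(2000L, {
    Y <- matrix(stats::rnorm(37 * 5), 37)
    size <- exp(stats::rnorm(37, mean = 5, sd = 0.3))
    size_shape_regression(Y, size, transform = "log")$p_value
  })
  expect_gte(mean(pv >= 0.05), 0.93)
  pow <- replicate(500L, {
    size <- exp(stats::rnorm(37, mean = 5, sd = 0.3))
    Y <- matrix(stats::rnorm(37 * 5), 37)
    Y[, 1L] <- Y[, 1L] + 3 * scale(log(size))
    size_shape_regression(Y, size, transform = "log")$p_value
  })
  expect_gt(mean(pow < 0.05), 0.99)
  # df bookkeeping: df1 = k, df2 = N - k - 1
  Y <- matrix(stats::rnorm(37 * 9), 37)
  t <- size_shape_regression(Y, exp(stats::rnorm(37)), k = 9L)
  expect_identical(c(t$df_num, t$df_den), c(9, 27))
  expect_error(size_shape_regression(Y, rep(2, 37)), "constant")
  expect_error(size_shape_regression(Y, c(rep(1, 36), -1)), "positive")
})

test_that("size-volume correlation is exact for a cubic law and dies under permutation", {
  set.seed(41)
  cs <- stats::runif(37, 100, 400)
  exact <- size_volume_correlation(cs, cs^3)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_lt(exact$p_value, 1e-10)
  expect_identical(nrow(exact$variants), 3L)
  vol <- (cs + stats::rnorm(37, sd = 10))^3
  perm <- replicate(1000L, size_volume_correlation(cs, sample(vol))$r_squared)
  expect_lt(mean(perm), 0.1)
})

test_that("size-by-factor ANOVA holds its size and detects shifted means", {
  set.seed(51)
  pv <- replicate(2000L, {
    size <- stats::rnorm(37, 270, 77)
    f <- factor(rep(c("T", "L", "P"), c(13, 14, 10)))
    size_by_factor_anova(size, f)$p_value
  })
  expect_gt(mean(pv < 0.05), 0.03)
  expect_lt(mean(pv < 0.05), 0.07)
  pow <- replicate(500L, {
    f <- factor(rep(c("T", "L", "P"), c(13, 14, 10)))
    size <- stats::rnorm(37, 270, 77) + (as.integer(f) - 2) * 3 * 77
    size_by_factor_anova(size, f)$p_value
  })
  expect_gt(mean(pow < 0.05), 0.99)
  expect_error(size_by_factor_anova(1:5, factor(c("a", "a", "a", "a", "b"))),
               "at least 2 members")
})
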